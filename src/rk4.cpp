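#include <Rcpp.h>
using namespace Rcpp;

// One Metropolis chain over gene-to-edge assignments and per-edge positive
// scale factors. Each state's residual is the trajectory objective with the
// rate of edge e replaced by max(0, scale_e * E(gene_e, t)), where E is the
// gene-expression matrix pre-interpolated at the RK4 stage times. Proposals
// reassign one edge's gene within the candidate set or perturb one scale by
// a log-normal step; the temperature is set from a pilot of the first
// proposal deltas so a typical uphill move is accepted with prob ~ 0.4.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
double metropolis_chain(NumericMatrix Estage, IntegerVector genes,
                        IntegerVector assign0, NumericVector scales0,
                        NumericMatrix Sinit, IntegerVector eparent,
                        IntegerVector echild, NumericMatrix X,
                        NumericVector x0, NumericVector h, int n_sub,
                        int root, double b1, int samples, double scale_sd,
                        double accept_target) {
  const int n = x0.size(), nE = eparent.size(), nsteps = h.size();
  const int nout = nsteps / n_sub + 1;
  std::vector<int> assign(assign0.begin(), assign0.end());
  std::vector<double> scales(scales0.begin(), scales0.end());
  std::vector<double> x(n), k1(n), k2(n), k3(n), k4(n), xt(n);

  auto deriv = [&](int stage, const std::vector<int> &as,
                   const std::vector<double> &sc,
                   const std::vector<double> &xx, std::vector<double> &dd) {
    std::fill(dd.begin(), dd.end(), 0.0);
    dd[root] += b1;
    for (int e = 0; e < nE; ++e) {
      double k = sc[e] * Estage(as[e], stage);
      if (k < 0) k = 0;
      const double f = k * xx[eparent[e]];
      dd[eparent[e]] -= f;
      if (echild[e] >= 0) dd[echild[e]] += f;
    }
  };
  auto residual = [&](const std::vector<int> &as,
                      const std::vector<double> &sc) {
    for (int i = 0; i < n; ++i) x[i] = x0[i];
    double rss = 0.0;
    for (int i = 0; i < n; ++i) {
      const double d = x[i] - X(i, 0);
      rss += d * d;
    }
    int oc = 1;
    for (int s = 0; s < nsteps; ++s) {
      const double hs = h[s];
      deriv(3 * s, as, sc, x, k1);
      for (int i = 0; i < n; ++i) xt[i] = x[i] + 0.5 * hs * k1[i];
      deriv(3 * s + 1, as, sc, xt, k2);
      for (int i = 0; i < n; ++i) xt[i] = x[i] + 0.5 * hs * k2[i];
      deriv(3 * s + 1, as, sc, xt, k3);
      for (int i = 0; i < n; ++i) xt[i] = x[i] + hs * k3[i];
      deriv(3 * s + 2, as, sc, xt, k4);
      for (int i = 0; i < n; ++i)
        x[i] += hs / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if ((s + 1) % n_sub == 0) {
        for (int i = 0; i < n; ++i) {
          const double d = x[i] - X(i, oc);
          rss += d * d;
        }
        ++oc;
      }
    }
    return std::isfinite(rss) ? rss : R_PosInf;
  };

  double res = residual(assign, scales);
  double best = res;
  std::vector<double> pilot;
  double temp = -1.0;
  const int ng = genes.size();
  for (int s = 0; s < samples; ++s) {
    std::vector<int> a2 = assign;
    std::vector<double> s2 = scales;
    const int e = (int)(unif_rand() * nE);
    if (unif_rand() < 0.5) {
      a2[e] = genes[(int)(unif_rand() * ng)];
      // a fresh gene needs a magnitude-matched scale or the proposal is
      // dead on arrival
      s2[e] = Sinit(a2[e], e);
    } else {
      s2[e] *= std::exp(norm_rand() * scale_sd);
    }
    const double r2 = residual(a2, s2);
    const double d = r2 - res;
    if (temp < 0) {
      if (std::isfinite(d)) pilot.push_back(std::fabs(d));
      if ((int)pilot.size() >= 20) {
        std::nth_element(pilot.begin(), pilot.begin() + pilot.size() / 2,
                         pilot.end());
        double med = pilot[pilot.size() / 2];
        if (med < 1e-12) med = 1e-12;
        temp = med / (-std::log(accept_target));
      }
    }
    double tacc = temp;
    if (tacc < 0) {
      double med = pilot.empty() ? 1e-12 : pilot[pilot.size() / 2];
      if (med < 1e-12) med = 1e-12;
      tacc = med / (-std::log(accept_target));
    }
    if (d <= 0 || unif_rand() < std::exp(-d / tacc)) {
      assign.swap(a2);
      scales.swap(s2);
      res = r2;
    }
    if (res < best) best = res;
  }
  return best;
}

// Fixed-step classical RK4 for the linear mass-balance system
//   xdot_i = b1 * [i == root] - sum_{e: parent=i} k_e(t) x_i + sum_{e: child=i} k_e(t) x_parent(e)
// Per-edge rates are supplied pre-evaluated at the three RK4 stage times of
// every step (columns of Kst: 3 per step, rows = edges). A child index of -1
// marks a decay edge whose flux leaves the observed system.
//
// The path is returned at x0 plus every n_sub-th step endpoint, i.e. at the
// caller's output grid when each output interval was split into n_sub steps.
// [[Rcpp::export]]
NumericMatrix rk4_lin_path(NumericVector x0, IntegerVector eparent,
                           IntegerVector echild, NumericMatrix Kst,
                           NumericVector h, int n_sub, int root, double b1) {
  const int n = x0.size(), nE = eparent.size(), nsteps = h.size();
  const int nout = nsteps / n_sub + 1;
  NumericMatrix out(n, nout);
  std::vector<double> x(n), k1(n), k2(n), k3(n), k4(n), xt(n);
  for (int i = 0; i < n; ++i) { x[i] = x0[i]; out(i, 0) = x0[i]; }

  auto deriv = [&](const double *kc, const std::vector<double> &xx,
                   std::vector<double> &dd) {
    std::fill(dd.begin(), dd.end(), 0.0);
    dd[root] += b1;
    for (int e = 0; e < nE; ++e) {
      const double f = kc[e] * xx[eparent[e]];
      dd[eparent[e]] -= f;
      if (echild[e] >= 0) dd[echild[e]] += f;
    }
  };

  int oc = 1;
  for (int s = 0; s < nsteps; ++s) {
    const double hs = h[s];
    const double *ka = nE ? &Kst(0, 3 * s) : (const double *)nullptr;
    const double *kb = nE ? &Kst(0, 3 * s + 1) : (const double *)nullptr;
    const double *kc = nE ? &Kst(0, 3 * s + 2) : (const double *)nullptr;
    deriv(ka, x, k1);
    for (int i = 0; i < n; ++i) xt[i] = x[i] + 0.5 * hs * k1[i];
    deriv(kb, xt, k2);
    for (int i = 0; i < n; ++i) xt[i] = x[i] + 0.5 * hs * k2[i];
    deriv(kb, xt, k3);
    for (int i = 0; i < n; ++i) xt[i] = x[i] + hs * k3[i];
    deriv(kc, xt, k4);
    for (int i = 0; i < n; ++i)
      x[i] += hs / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    if ((s + 1) % n_sub == 0) {
      for (int i = 0; i < n; ++i) out(i, oc) = x[i];
      ++oc;
    }
  }
  return out;
}
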