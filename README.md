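# kinetree

Time-varying catalytic rate estimation in tree-structured metabolic
networks, for systems biologists modelling small pathways — such as the
quercetin glycosylation pathway in tomato seedlings that motivates the
bundled examples — from metabolite concentration time series, with an
optional gene-expression layer for pre-selecting candidate enzymes.

## The model

A pathway is a directed graph of metabolites with first-order conversions
and a constant influx `b1` at the root:

    dX_i/dt = - sum_j k_ij(t) X_i + sum_j k_ji(t) X_j + b_i,
    k_ij(t) = alpha_ij t^2 + beta_ij t + gamma_ij >= 0,

i.e. `dX/dt = A(t) X + b` with zero column sums of `A`. On a rooted tree
there are exactly as many parameters (one influx + one rate per edge) as
observed states; exchanging states and parameters turns the mass-balance
equations at one time point into an upper-triangular linear system, so the
time-varying rates are locally structurally identifiable and can be solved
point-wise. Three estimators are provided:

1. **Point-wise solve** — P-spline derivatives, exact triangular solve per
   time point, quadratic polynomial through the point-wise rate estimates;
2. **Direct quadratic least squares** — the rate polynomials substituted
   into the derivative-matching objective, solved jointly under
   non-negativity constraints;
3. **Trajectory matching** — ODE integration inside a multi-start
   Nelder–Mead simplex search on the summed distance to the measurements.

Around the estimators: a synthetic-data generator for benchmark studies
(random trees/cyclic networks, ±10% multiplicative noise), structural and
practical identifiability diagnostics (profile likelihood, residual
Hessian spectrum), and a correlation-based candidate-gene ranking with a
Metropolis-substitution validation.

## Worked example

```r
library(kinetree)

sim <- simulate_pathway(sim_spec(seed = 3, noise_level = 0))  # 7-node tree
fit <- fit_kinetics(sim$network, sim$clean, scheme = "2")
summary(fit)
#> Kinetic rate fit, scheme 2
#> Influx b1 = 1.0034
#> Rate polynomials k(t) = alpha t^2 + beta t + gamma:
#>             alpha      beta    gamma
#> X1->X2 -0.0105740  0.068292 0.795480
#> X2->X3  0.0108980 -0.035010 0.556580
#> X2->X4  0.0080031 -0.087259 0.821050
#> X1->X5  0.0019872 -0.069581 0.541720
#> X3->X6 -0.0137200  0.098815 0.471470
#> X3->X7 -0.0073744  0.119610 0.038205
#> Derivative-matching residual: 0.68325
#> Trajectory residual: 0.48064
```

`b1` is the influx into the root (concentration per day); each row is one
edge's quadratic rate curve (per day at `t = 0` for `gamma`, with `beta`
and `alpha` the linear and quadratic trends). The derivative-matching
residual is the Frobenius norm of the mismatch between spline-estimated
derivatives and the model right-hand side; the trajectory residual is the
summed squared distance between the integrated model and the data.
Compare to the generating truth with `sim$rates`, plot data, fitted
trajectories and rate curves with `plot(fit)`, and probe the fit with
`profile_likelihood(fit, "X1->X2.gamma")` and `sensitivity_spectrum(fit)`.

With an expression table on the same time grid:

```r
expr <- read_expression("expression.tsv")       # genes x times
rk <- rank_genes(fit, expr)                     # best-edge correlations
mv <- mcmc_validate(fit, sim$clean, expr, rk)   # top-10 vs ranks 11-20
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/kinetree.R simulate --nodes 7 --noise 0.1 --seed 42 --out d/
Rscript inst/cli/kinetree.R fit --network d/network.json --data d/noisy.tsv \
    --scheme 2 --out fit.json
```

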