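# ---- ODE trajectory engines ------------------------------------------------
# Two routes to X(t): deSolve's adaptive lsoda (accurate, user-facing) and a
# compiled fixed-step RK4 kernel (fast, used inside optimisation loops where
# ~1e5 integrations of the small linear system are needed).

# 0-based edge index arrays for the compiled kernel; decay terms become
# pseudo-edges with child -1.
.edge_index <- function(network) {
  pos <- stats::setNames(seq_along(network$nodes) - 1L, network$nodes)
  ed <- network$edges
  parent <- as.integer(pos[ed$parent])
  child <- as.integer(pos[ed$child])
  if (length(network$decay)) {
    parent <- c(parent, as.integer(pos[network$decay]))
    child <- c(child, rep(-1L, length(network$decay)))
  }
  list(parent = parent, child = child, root = as.integer(pos[[network$influx]]))
}

# RK4 stage grid: each output interval split into n_sub uniform steps; the
# three stage times (left, mid, right) of every step, flattened column-wise.
.stage_grid <- function(times, n_sub) {
  m <- length(times)
  h <- rep(diff(times) / n_sub, each = n_sub)
  left <- rep(times[-m], each = n_sub) +
    (rep(seq_len(n_sub), m - 1L) - 1L) * h
  stage <- as.vector(rbind(left, left + h / 2, left + h))
  list(h = h, stage = stage)
}

# Fast path: rates as a rate_set (evaluated analytically at stage times) or
# as a matrix of tabulated values at `times` (linearly interpolated).
.fast_trajectories <- function(network, rates, x0, times, n_sub = 8L) {
  sg <- .stage_grid(times, n_sub)
  if (inherits(rates, "rateset")) {
    K <- rate_curves(network, rates, sg$stage)
    b1 <- rates$b1
  } else {
    K <- t(vapply(seq_len(nrow(rates$K)), function(e)
      stats::approx(times, rates$K[e, ], xout = sg$stage, rule = 2L)$y,
      numeric(length(sg$stage))))
    b1 <- rates$b1
  }
  if (!nrow(K)) K <- matrix(0, 0L, length(sg$stage))
  idx <- .edge_index(network)
  out <- rk4_lin_path(as.numeric(x0[network$nodes]), idx$parent, idx$child,
                      K, sg$h, as.integer(n_sub), idx$root, b1)
  dimnames(out) <- list(network$nodes, NULL)
  out
}

#' Solve the mass-balance ODE for given rates
#'
#' Integrates \eqn{\dot X = A(t) X + b} from `x0` and returns the solution
#' at the requested times. The default engine is deSolve's adaptive `lsoda`
#' (rtol 1e-8, atol 1e-10, retried at tighter tolerances on failure); the
#' `"rk4"` engine is a compiled fixed-step integrator suitable for the tight
#' loops of optimisation and sampling.
#'
#' @param network a [metnet()] object.
#' @param rates a [rate_set()] object.
#' @param x0 initial concentrations (named, or in network node order).
#' @param times increasing output times.
#' @param engine `"lsoda"` (default) or `"rk4"`.
#' @param n_sub RK4 steps per output interval (rk4 engine).
#' @return matrix nodes x times of concentrations.
#' @export
model_trajectories <- function(network, rates, x0, times,
                               engine = c("lsoda", "rk4"), n_sub = 8L) {
  engine <- match.arg(engine)
  stopifnot(all(diff(times) > 0) || length(times) == 1L)
  if (is.null(names(x0))) names(x0) <- network$nodes
  if (engine == "rk4")
    return(.fast_trajectories(network, rates, x0, times, n_sub))
  idx <- .edge_index(network)
  ids <- c(edge_ids(network),
           if (length(network$decay)) paste0("decay:", network$decay))
  rhs <- function(t, x, p) {
    k <- rate_curves(network, rates, t)[, 1L]
    dx <- numeric(length(x))
    dx[idx$root + 1L] <- rates$b1
    for (e in seq_along(idx$parent)) {
      f <- k[e] * x[idx$parent[e] + 1L]
      dx[idx$parent[e] + 1L] <- dx[idx$parent[e] + 1L] - f
      if (idx$child[e] >= 0L)
        dx[idx$child[e] + 1L] <- dx[idx$child[e] + 1L] + f
    }
    list(dx)
  }
  sol <- try(deSolve::ode(y = as.numeric(x0[network$nodes]), times = times,
                          func = rhs, parms = NULL, method = "lsoda",
                          rtol = 1e-8, atol = 1e-10), silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(times)) {
    sol <- deSolve::ode(y = as.numeric(x0[network$nodes]), times = times,
                        func = rhs, parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    if (nrow(sol) < length(times)) stop("ODE integration failed")
  }
  out <- t(unname(sol[, -1L, drop = FALSE]))
  dimnames(out) <- list(network$nodes, NULL)
  out
}

#' Frobenius norm of a matrix
#'
#' Square root of the sum of squared entries, the norm used both in the
#' derivative-matching objective and to measure parameter-recovery error.
#'
#' @param M numeric matrix (or vector).
#' @return non-negative scalar.
#' @export
frobenius_norm <- function(M) sqrt(sum(as.numeric(M)^2))

# Trajectory-matching objective: sum over time points of the (squared, by
# default) Euclidean distance between model solution and measurements.
.traj_objective <- function(path, X, norm = c("l2_squared", "l2")) {
  norm <- match.arg(norm)
  if (!all(is.finite(path))) return(Inf)
  d2 <- colSums((path - X)^2)
  if (norm == "l2_squared") sum(d2) else sum(sqrt(d2))
}
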