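# ---- Estimation of constant and time-varying catalytic rates ---------------

# Expanded parameter names for a network: influx first, then per-edge
# quadratic coefficients in the triangular ordering, then decay constants.
.theta_names <- function(network, scheme) {
  po <- param_order(network)
  ids <- po[!(po %in% "b1") & !grepl("^decay:", po)]
  dn <- po[grepl("^decay:", po)]
  if (scheme == "constant") c("b1", ids, dn)
  else c("b1", as.vector(t(outer(ids, c(".alpha", ".beta", ".gamma"),
                                 paste0))), dn)
}

.theta_to_rateset <- function(network, theta, scheme) {
  po <- param_order(network)
  ids <- po[!(po %in% "b1") & !grepl("^decay:", po)]
  rates <- list()
  for (id in ids) {
    rates[[id]] <- if (scheme == "constant") unname(theta[[id]])
    else unname(c(theta[[paste0(id, ".alpha")]],
                  theta[[paste0(id, ".beta")]],
                  theta[[paste0(id, ".gamma")]]))
  }
  decay <- list()
  for (v in network$decay)
    decay[[v]] <- unname(theta[[paste0("decay:", v)]])
  rate_set(rates, b1 = unname(theta[["b1"]]), decay = decay)
}

# Design matrix of the derivative-matching problem: rows are (time, node)
# equations, columns the expanded parameter vector. Linear in theta because
# the mass-balance right-hand side is linear in every rate coefficient.
.gradient_design <- function(network, X, times, scheme) {
  nodes <- network$nodes
  n <- length(nodes)
  m <- length(times)
  pars <- .theta_names(network, scheme)
  G <- matrix(0, n * m, length(pars), dimnames = list(NULL, pars))
  row0 <- (seq_len(m) - 1L) * n
  pos <- stats::setNames(seq_len(n), nodes)
  G[row0 + pos[[network$influx]], "b1"] <- 1
  ed <- network$edges
  ids <- edge_ids(network)
  for (e in seq_len(nrow(ed))) {
    p <- pos[[ed$parent[e]]]; ch <- pos[[ed$child[e]]]
    xv <- X[ed$parent[e], ]
    cols <- if (scheme == "constant") stats::setNames(list(rep(1, m)), ids[e])
    else list(times^2, times, rep(1, m))
    nms <- if (scheme == "constant") ids[e]
    else paste0(ids[e], c(".alpha", ".beta", ".gamma"))
    for (j in seq_along(nms)) {
      v <- cols[[j]] * xv
      G[row0 + p, nms[j]] <- G[row0 + p, nms[j]] - v
      G[row0 + ch, nms[j]] <- G[row0 + ch, nms[j]] + v
    }
  }
  for (v in network$decay)
    G[row0 + pos[[v]], paste0("decay:", v)] <- -X[v, ]
  G
}

# Linear inequality constraints K(t_k) >= 0 (plus b1 >= 0, decay >= 0) on the
# expanded parameter vector: each row of C is one constraint C theta >= 0.
.nonneg_constraints <- function(network, times, scheme) {
  pars <- .theta_names(network, scheme)
  ids <- param_order(network)
  ids <- ids[!(ids %in% "b1") & !grepl("^decay:", ids)]
  rows <- list()
  add <- function(v) rows[[length(rows) + 1L]] <<- v
  z <- stats::setNames(numeric(length(pars)), pars)
  v <- z; v[["b1"]] <- 1; add(v)
  for (id in ids) {
    if (scheme == "constant") { v <- z; v[[id]] <- 1; add(v) }
    else for (tk in times) {
      v <- z
      v[[paste0(id, ".alpha")]] <- tk^2
      v[[paste0(id, ".beta")]] <- tk
      v[[paste0(id, ".gamma")]] <- 1
      add(v)
    }
  }
  for (d in grep("^decay:", pars, value = TRUE)) { v <- z; v[[d]] <- 1; add(v) }
  do.call(rbind, rows)
}

# Least squares min ||G theta - y||^2 subject to C theta >= 0, by exact
# unconstrained solve when feasible, else a quadratic-penalty BFGS ladder
# with analytic gradients.
.constrained_ls <- function(G, y, C, fixed = NULL) {
  pars <- colnames(G)
  if (!is.null(fixed)) {
    free <- setdiff(pars, names(fixed))
    off <- if (length(fixed)) G[, names(fixed), drop = FALSE] %*% fixed else 0
    Gf <- G[, free, drop = FALSE]
    yf <- y - drop(off)
    Cf <- C[, free, drop = FALSE]
    coff <- drop(C[, names(fixed), drop = FALSE] %*% fixed)
    inner <- .constrained_ls_core(Gf, yf, Cf, coff)
    theta <- stats::setNames(numeric(length(pars)), pars)
    theta[names(fixed)] <- fixed
    theta[free] <- inner$theta
    return(list(theta = theta, rss = inner$rss, converged = inner$converged))
  }
  .constrained_ls_core(G, y, C, 0)
}

.constrained_ls_core <- function(G, y, C, coff) {
  th0 <- tryCatch(qr.solve(qr(G, LAPACK = TRUE), y),
                  error = function(e) {
                    sv <- svd(G)
                    d <- ifelse(sv$d > 1e-10 * max(sv$d), 1 / sv$d, 0)
                    drop(sv$v %*% (d * crossprod(sv$u, y)))
                  })
  th0 <- stats::setNames(drop(th0), colnames(G))
  tol <- 1e-9 * max(1, max(abs(th0)))
  cons <- function(th) drop(C %*% th) + coff
  if (!nrow(C) || min(cons(th0)) >= -tol)
    return(list(theta = th0, rss = sum((drop(G %*% th0) - y)^2),
                converged = TRUE))
  GtG <- crossprod(G); Gty <- crossprod(G, y)
  th <- th0
  scale0 <- max(1, sum(y^2))
  conv <- FALSE
  for (mu in scale0 * c(1e2, 1e4, 1e6)) {
    fn <- function(th) {
      v <- pmin(0, cons(th))
      sum((drop(G %*% th) - y)^2) + mu * sum(v^2)
    }
    gr <- function(th) {
      v <- pmin(0, cons(th))
      drop(2 * (GtG %*% th - Gty)) + 2 * mu * drop(crossprod(C, v))
    }
    o <- stats::optim(th, fn, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
    th <- o$par
    conv <- o$convergence == 0
  }
  list(theta = stats::setNames(th, colnames(G)),
       rss = sum((drop(G %*% th) - y)^2), converged = conv)
}

# Box-constrained (all parameters >= 0) least squares for the constant-rate
# scheme, via L-BFGS-B with analytic gradient.
.nonneg_box_ls <- function(G, y) {
  GtG <- crossprod(G); Gty <- crossprod(G, y)
  fn <- function(th) sum((drop(G %*% th) - y)^2)
  gr <- function(th) drop(2 * (GtG %*% th - Gty))
  th0 <- pmax(0, tryCatch(qr.solve(G, y), error = function(e)
    rep(0.1, ncol(G))))
  o <- stats::optim(th0, fn, gr, method = "L-BFGS-B",
                    lower = rep(0, ncol(G)),
                    control = list(maxit = 1000, factr = 1e4))
  list(theta = stats::setNames(o$par, colnames(G)), rss = o$value,
       converged = o$convergence == 0)
}

.resolve_deriv <- function(data, deriv, smoother) {
  if (!is.null(deriv)) return(deriv)
  do.call(derivatives_at,
          c(list(data = data), smoother))
}

# ---- Scheme 1: point-wise triangular solve + polynomial smoothing ----------
.fit_scheme1 <- function(network, data, deriv, clip = c("zero", "none"),
                         poly_degree = 2L, use_smoothed = FALSE) {
  clip <- match.arg(clip)
  vt <- validate_tree(network)
  tree <- vt$is_tree
  times <- deriv$times
  pars <- param_order(network)
  P <- matrix(NA_real_, length(times), length(pars),
              dimnames = list(NULL, pars))
  masked <- logical(length(times))
  for (k in seq_along(times)) {
    tk <- times[k]
    j <- match(TRUE, abs(data$times - tk) < 1e-12)
    xk <- if (!is.na(j) && !use_smoothed) data$X[, j]
    else if (!is.null(deriv$Xs)) deriv$Xs[, k]
    else stop("no concentration values available at solve time ", tk)
    names(xk) <- data$labels
    B <- tryCatch(pointwise_design_matrix(network, xk,
                                          require_tree = FALSE),
                  error = function(e) e)
    if (inherits(B, "error")) { masked[k] <- TRUE; next }
    xd <- deriv$Xdot[rownames(B), k]
    th <- if (tree) backsolve(B, xd)
    else { # least-squares point-wise solve on non-tree networks
      sv <- svd(B)
      d <- ifelse(sv$d > 1e-10 * max(sv$d), 1 / sv$d, 0)
      drop(sv$v %*% (d * crossprod(sv$u, xd)))
    }
    P[k, ] <- th
  }
  if (any(masked))
    warning(sum(masked), " time point(s) masked (singular point-wise design)")
  ok <- !masked
  if (sum(ok) < 1L)
    stop("no usable time points for the point-wise solve")
  if (sum(ok) < poly_degree + 1L) {
    poly_degree <- sum(ok) - 1L
    warning("only ", sum(ok), " usable time point(s): reducing the ",
            "polynomial degree to ", poly_degree)
  }
  Praw <- P
  if (clip == "zero") P[ok, ] <- pmax(P[ok, ], 0)
  # constrained quadratic fit through the point-wise estimates per rate,
  # keeping the fitted polynomial non-negative at the measurement times
  tt <- times[ok]
  pow <- min(poly_degree, 2L):0L
  basis <- vapply(pow, function(q) tt^q, numeric(length(tt)))
  basis <- matrix(basis, ncol = length(pow),
                  dimnames = list(NULL, c("a", "b", "g")[3L - pow]))
  Cb <- vapply(pow, function(q) data$times^q, numeric(length(data$times)))
  Cb <- matrix(Cb, ncol = length(pow), dimnames = dimnames(basis))
  theta <- c(b1 = max(0, mean(P[ok, "b1"])))
  for (id in pars[-1L]) {
    if (grepl("^decay:", id)) {
      theta[[id]] <- max(0, mean(P[ok, id]))
    } else {
      fitc <- .constrained_ls_core(basis, P[ok, id], Cb, 0)
      co <- c(a = 0, b = 0, g = 0)
      co[colnames(basis)] <- fitc$theta[colnames(basis)]
      theta[[paste0(id, ".alpha")]] <- co[["a"]]
      theta[[paste0(id, ".beta")]] <- co[["b"]]
      theta[[paste0(id, ".gamma")]] <- co[["g"]]
    }
  }
  list(theta = theta, pointwise = data.frame(time = times, Praw,
                                             check.names = FALSE),
       masked = masked)
}

# ---- Scheme 2 / constant: derivative-matching least squares ----------------
.fit_gradient_ls <- function(network, data, deriv, scheme) {
  times <- deriv$times
  keep <- match(round(times, 12), round(data$times, 12))
  if (anyNA(keep))
    stop("derivative estimates must be evaluated at measurement times")
  X <- data$X[network$nodes, keep, drop = FALSE]
  Xd <- deriv$Xdot[network$nodes, , drop = FALSE]
  G <- .gradient_design(network, X, times, scheme)
  y <- as.vector(Xd)  # column-major: node within time, matching row blocks
  C <- .nonneg_constraints(network, times, scheme)
  if (scheme == "constant") .nonneg_box_ls(G, y)
  else .constrained_ls(G, y, C)
}

# ---- Scheme 3: trajectory matching by simplex search -----------------------
.scheme3_objective <- function(network, data, norm, n_sub = 4L) {
  times <- data$times
  X <- data$X[network$nodes, , drop = FALSE]
  x0 <- X[, 1L]
  scale0 <- max(1, sum(X^2))
  sg <- .stage_grid(times, n_sub)
  Vst <- rbind(sg$stage^2, sg$stage, 1)
  Vdat <- rbind(times^2, times, 1)
  idx <- .edge_index(network)
  po <- param_order(network)
  ids <- po[!(po %in% "b1") & !grepl("^decay:", po)]
  nE <- length(ids)
  nd <- length(network$decay)
  n_sub <- as.integer(n_sub)
  # theta layout: b1, then (alpha, beta, gamma) per edge in triangular
  # (param_order) order, then decay; the integrator wants rate rows in the
  # network's edge-row order
  co_idx <- matrix(1L + seq_len(3L * nE), nrow = nE, byrow = TRUE)
  co_idx <- co_idx[match(edge_ids(network), ids), , drop = FALSE]
  d_idx <- if (nd) 1L + 3L * nE + seq_len(nd) else integer()
  function(theta) {
    A <- matrix(theta[co_idx], nE, 3L)
    Kst <- A %*% Vst
    Kdat <- A %*% Vdat
    b1 <- theta[[1L]]
    if (nd) {
      Kst <- rbind(Kst, matrix(theta[d_idx], nd, ncol(Kst)))
      Kdat <- rbind(Kdat, matrix(theta[d_idx], nd, ncol(Kdat)))
    }
    path <- rk4_lin_path(x0, idx$parent, idx$child, Kst, sg$h, n_sub,
                         idx$root, b1)
    viol2 <- sum(pmin(0, Kdat)^2) + min(0, b1)^2
    .traj_objective(path, X, norm) + 1e4 * scale0 * viol2
  }
}

.fit_scheme3 <- function(network, data, norm, start = NULL, restarts = 5L,
                         seed = NULL, maxit = 2500L, rounds = 8L) {
  if (!is.null(seed)) set.seed(seed)
  pars <- .theta_names(network, "2")
  obj <- .scheme3_objective(network, data, norm)
  po <- param_order(network)
  ids <- po[!(po %in% "b1") & !grepl("^decay:", po)]
  dn <- po[grepl("^decay:", po)]
  # the simplex searches rate values at three time anchors per edge (a
  # well-conditioned, box-like parameterisation of the same quadratics);
  # raw t^2 coefficients make default simplex steps enormous in rate space
  tt <- data$times
  anchors <- c(tt[1L], mean(range(tt)), tt[length(tt)])
  V <- cbind(anchors^2, anchors, 1)
  Vi <- solve(V)
  to_theta <- function(phi) {
    th <- stats::setNames(numeric(length(pars)), pars)
    th["b1"] <- phi[1L]
    for (e in seq_along(ids))
      th[paste0(ids[e], c(".alpha", ".beta", ".gamma"))] <-
        drop(Vi %*% phi[1L + (e - 1L) * 3L + 1:3])
    if (length(dn)) th[dn] <- phi[1L + 3L * length(ids) + seq_along(dn)]
    th
  }
  to_phi <- function(th) {
    phi <- th[["b1"]]
    for (e in seq_along(ids)) {
      co <- th[paste0(ids[e], c(".alpha", ".beta", ".gamma"))]
      phi <- c(phi, drop(V %*% co))
    }
    c(phi, th[dn])
  }
  obj_phi <- function(phi) obj(to_theta(phi))
  np <- 1L + 3L * length(ids) + length(dn)
  starts <- list()
  if (!is.null(start)) starts <- list(to_phi(start[pars]))
  nrand <- max(0L, restarts - length(starts))
  for (i in seq_len(nrand))
    starts <- c(starts, list(c(
      exp(stats::runif(1, log(0.2), log(3))),
      exp(stats::runif(3L * length(ids), log(0.05), log(2))),
      rep(0.01, length(dn)))))
  # iterated simplex: re-initialising at the incumbent escapes stagnation
  run_nm <- function(phi) {
    o <- list(par = phi, value = obj_phi(phi), convergence = 0L)
    for (r in seq_len(rounds)) {
      o2 <- stats::optim(o$par, obj_phi, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = 1e-12))
      if (o2$value >= o$value * (1 - 1e-8)) { o <- o2; break }
      o <- o2
    }
    o
  }
  best <- NULL
  vals <- numeric(0)
  init_vals <- numeric(0)
  for (phi in starts) {
    phi[!is.finite(phi)] <- 0
    init_vals <- c(init_vals, obj_phi(phi))
    o <- run_nm(phi)
    vals <- c(vals, o$value)
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(theta = to_theta(best$par), value = best$value,
       start_values = vals, initial_values = init_vals,
       converged = best$convergence %in% c(0L, 1L))
}

#' Fit time-varying (or constant) catalytic rates to a network
#'
#' The central fitting function. Given a network topology and a metabolite
#' concentration time series it estimates the influx \eqn{b_1} and one
#' catalytic rate per edge, either constant or quadratic in time
#' (\eqn{k_{ij}(t) = \alpha t^2 + \beta t + \gamma}), under the constraint
#' that every rate is non-negative at the measurement times.
#'
#' Four schemes are available:
#' \describe{
#'   \item{`"1"`}{Point-wise solve. P-splines are fitted per metabolite;
#'     at each time the mass-balance equations, which are linear in the
#'     parameters, are solved exactly — on a tree the system is upper
#'     triangular and uniquely solvable whenever all concentrations are
#'     nonzero. A quadratic polynomial is then fitted through each rate's
#'     point-wise series (negative point-wise values floored first, see
#'     `clip`). On non-tree networks a least-squares point-wise solve is
#'     used instead and uniqueness is lost.}
#'   \item{`"2"`}{Direct quadratic-rate least squares: the rate polynomials
#'     are substituted into the derivative-matching objective
#'     \eqn{\sum_k \|\dot X(t_k) - \tilde A(t_k)\tilde X(t_k)\|^2} and all
#'     coefficients are estimated jointly (a linear problem, solved exactly
#'     when the non-negativity constraints are inactive).}
#'   \item{`"3"`}{Trajectory matching: the ODE is integrated for candidate
#'     parameters and the summed distance between solution and measurements
#'     is minimised by Nelder–Mead simplex search with multiple starts
#'     (one informed start from scheme 2 plus random restarts).}
#'   \item{`"constant"`}{Time-invariant rates by non-negative least squares
#'     on the derivative-matching objective.}
#' }
#'
#' @param network a [metnet()] object.
#' @param data a [ts_data()] object; row labels must cover the network
#'   nodes.
#' @param scheme `"1"`, `"2"`, `"3"` or `"constant"`.
#' @param deriv optional precomputed [derivatives_at()] /
#'   [finite_difference_derivatives()] estimate; default fits P-splines
#'   with `smoother` settings.
#' @param smoother list of arguments for [derivatives_at()] (e.g.
#'   `list(penalty = "auto")`).
#' @param allowed_edges optional character vector of edge ids to keep; all
#'   other edges are excluded from the model (their rates fixed at zero).
#' @param objective_norm `"l2_squared"` (default) or `"l2"` for the
#'   trajectory objective of scheme 3 and of [trajectory_residual()].
#' @param clip scheme 1 treatment of negative point-wise estimates:
#'   `"zero"` (floor, default) or `"none"`.
#' @param restarts number of scheme-3 simplex starts (default 5).
#' @param seed optional seed for the scheme-3 random restarts.
#' @param start optional scheme-3 initial parameter vector (named as
#'   `coef()` of a scheme-2 fit).
#' @param control list of advanced settings (`maxit` for scheme 3,
#'   `use_smoothed` for scheme 1).
#' @return an object of class `"kinfit"`; see [coef.kinfit()],
#'   [predict.kinfit()], [summary.kinfit()].
#' @examples
#' net <- example_tree7()
#' sim <- simulate_pathway(sim_spec(seed = 1, noise_level = 0))
#' fit <- fit_kinetics(sim$network, sim$clean, scheme = "2")
#' coef(fit)[1:4]
#' @export
fit_kinetics <- function(network, data,
                         scheme = c("2", "1", "3", "constant"),
                         deriv = NULL, smoother = list(penalty = "auto"),
                         allowed_edges = NULL,
                         objective_norm = c("l2_squared", "l2"),
                         clip = c("zero", "none"), restarts = 5L,
                         seed = NULL, start = NULL, control = list()) {
  scheme <- match.arg(as.character(scheme), c("2", "1", "3", "constant"))
  objective_norm <- match.arg(objective_norm)
  clip <- match.arg(clip)
  stopifnot(inherits(network, "metnet"), inherits(data, "ts_data"))
  if (!is.null(allowed_edges)) {
    keep <- edge_ids(network) %in% allowed_edges
    network <- metnet(network$edges[keep, , drop = FALSE],
                      nodes = network$nodes, influx = network$influx,
                      decay = network$decay)
  }
  if (!all(network$nodes %in% data$labels))
    stop("data rows do not cover the network nodes")
  dataN <- ts_data(data$times, data$X[network$nodes, , drop = FALSE],
                   network$nodes)
  diagnostics <- list()
  pointwise <- NULL
  if (scheme == "3") {
    f <- .fit_scheme3(network, dataN, objective_norm, start = start,
                      restarts = restarts, seed = seed,
                      maxit = if (!is.null(control$maxit)) control$maxit
                      else 2500L,
                      rounds = if (!is.null(control$rounds)) control$rounds
                      else 8L)
    theta <- f$theta
    diagnostics <- list(converged = f$converged,
                        start_values = f$start_values,
                        initial_values = f$initial_values,
                        objective = f$value)
  } else if (scheme == "1") {
    dv <- .resolve_deriv(dataN, deriv, smoother)
    f <- .fit_scheme1(network, dataN, dv, clip = clip,
                      use_smoothed = isTRUE(control$use_smoothed))
    theta <- f$theta
    pointwise <- f$pointwise
    diagnostics <- list(masked = sum(f$masked), converged = TRUE)
    deriv <- dv
  } else {
    dv <- .resolve_deriv(dataN, deriv, smoother)
    f <- .fit_gradient_ls(network, dataN, dv, scheme)
    theta <- f$theta
    diagnostics <- list(converged = f$converged, rss = f$rss)
    deriv <- dv
  }
  pn <- .theta_names(network, if (scheme == "constant") "constant" else "2")
  theta <- theta[pn]
  names(theta) <- pn
  rates <- .theta_to_rateset(network, theta,
                             if (scheme == "constant") "constant" else "2")
  fitted <- tryCatch(
    model_trajectories(network, rates, dataN$X[, 1L], dataN$times),
    error = function(e) matrix(NA_real_, length(network$nodes),
                               length(dataN$times)))
  res <- structure(list(
    call = match.call(), scheme = scheme, network = network,
    coefficients = theta, rates = rates, pointwise = pointwise,
    data = dataN, deriv = deriv, fitted = fitted,
    objective_norm = objective_norm, diagnostics = diagnostics),
    class = "kinfit")
  res$residual <- .scheme_residual(res)
  res$trajectory_residual <- trajectory_residual(res)
  res
}

# Scheme-native residual: derivative-matching Frobenius norm for schemes
# 1/2/constant, trajectory objective for scheme 3.
.scheme_residual <- function(fit) {
  if (fit$scheme == "3") {
    if (!is.null(fit$diagnostics$objective)) return(fit$diagnostics$objective)
    return(trajectory_residual(fit))
  }
  dv <- fit$deriv
  if (is.null(dv)) return(NA_real_)
  keep <- match(round(dv$times, 12), round(fit$data$times, 12))
  if (anyNA(keep)) return(NA_real_)
  tot <- 0
  for (k in seq_along(dv$times)) {
    sm <- .system_matrix_clipped(fit$network, fit$rates, dv$times[k])
    pred <- drop(sm$A %*% fit$data$X[, keep[k]]) + sm$b
    tot <- tot + sum((dv$Xdot[fit$network$nodes, k] - pred)^2)
  }
  sqrt(tot)
}

# system matrix with rates floored at zero (guards tiny negative dips of the
# fitted polynomials between constrained time points)
.system_matrix_clipped <- function(network, rates, t) {
  K <- pmax(rate_curves(network, rates, t)[, 1L, drop = FALSE], 0)
  n <- length(network$nodes)
  A <- matrix(0, n, n, dimnames = list(network$nodes, network$nodes))
  ed <- network$edges
  for (r in seq_len(nrow(ed))) {
    k <- K[r, 1L]
    A[ed$child[r], ed$parent[r]] <- A[ed$child[r], ed$parent[r]] + k
    A[ed$parent[r], ed$parent[r]] <- A[ed$parent[r], ed$parent[r]] - k
  }
  for (v in network$decay)
    A[v, v] <- A[v, v] - K[paste0("decay:", v), 1L]
  b <- stats::setNames(numeric(n), network$nodes)
  b[network$influx] <- rates$b1
  list(A = A, b = b)
}

#' Trajectory-matching residual of a fit
#'
#' Integrates the fitted model from the first measurement and returns the
#' summed (squared, by default) Euclidean distance to the data — the
#' objective used to compare candidate network topologies.
#'
#' @param fit a [fit_kinetics()] object.
#' @param norm `"l2_squared"` or `"l2"`; defaults to the fit's setting.
#' @return non-negative scalar.
#' @export
trajectory_residual <- function(fit, norm = NULL) {
  if (is.null(norm)) norm <- fit$objective_norm
  if (anyNA(fit$fitted)) return(Inf)
  .traj_objective(fit$fitted, fit$data$X, norm)
}

#' Constant-rate estimation with edge exclusion
#'
#' Convenience wrapper for `fit_kinetics(scheme = "constant")`: minimises
#' the Frobenius norm of the derivative mismatch over all rates jointly,
#' with excluded edges fixed at zero and every rate constrained
#' non-negative.
#'
#' @inheritParams fit_kinetics
#' @return a `"kinfit"` object.
#' @export
estimate_constant_rates <- function(network, data, deriv = NULL,
                                    allowed_edges = NULL, ...) {
  fit_kinetics(network, data, scheme = "constant", deriv = deriv,
               allowed_edges = allowed_edges, ...)
}

#' Select the best-fitting candidate network
#'
#' Fits every candidate topology to the data and returns the one with the
#' smallest trajectory-matching residual, together with the full residual
#' table — step 1 of the candidate-gene selection workflow.
#'
#' @param candidates list of [metnet()] objects sharing node labels with
#'   the data.
#' @param data a [ts_data()] object.
#' @param scheme estimation scheme passed to [fit_kinetics()].
#' @param ... further arguments for [fit_kinetics()].
#' @return list with `best` (network), `best_fit` (`"kinfit"`), `fits`
#'   (all fits) and `table` (data frame of residuals).
#' @export
select_best_network <- function(candidates, data, scheme = "2", ...) {
  stopifnot(length(candidates) >= 1L)
  fits <- lapply(candidates, function(net)
    tryCatch(fit_kinetics(net, data, scheme = scheme, ...),
             error = function(e) e))
  resid <- vapply(fits, function(f)
    if (inherits(f, "kinfit")) trajectory_residual(f) else Inf, numeric(1L))
  tab <- data.frame(candidate = seq_along(candidates),
                    n_edges = vapply(candidates, function(n) nrow(n$edges), 0L),
                    trajectory_residual = resid)
  best <- which.min(resid)
  list(best = candidates[[best]], best_fit = fits[[best]], fits = fits,
       table = tab, best_index = best)
}
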