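# ---- Structural and practical identifiability, sensitivity -----------------

#' Structural identifiability report for a network
#'
#' A balanced tree has exactly as many parameters (one influx plus one rate
#' per edge) as observed states, and the point-wise design matrix is upper
#' triangular under the breadth-first ordering — a certificate of local
#' structural identifiability. Non-tree networks are flagged with the
#' offending undirected cycle; networks with unconstrained decay are
#' flagged because the implicit sink unbalances the parameter count.
#'
#' @param network a [metnet()] object.
#' @return list of class `"structural_report"` with `identifiable`
#'   (logical), `order` (triangular ordering certificate when
#'   identifiable), `cycle`, `reason`.
#' @export
structural_identifiability <- function(network) {
  vt <- validate_tree(network)
  structure(list(identifiable = vt$is_tree, order = vt$order,
                 cycle = vt$cycle, reason = vt$reason),
            class = "structural_report")
}

#' @export
print.structural_report <- function(x, ...) {
  if (x$identifiable) {
    cat("Structurally identifiable: tree topology, triangular ordering\n  ",
        paste(x$order, collapse = " < "), "\n")
  } else {
    cat("Not certified structurally identifiable:", x$reason, "\n")
    if (!is.null(x$cycle))
      cat("  cycle:", paste(x$cycle, collapse = " - "), "\n")
  }
  invisible(x)
}

# Re-optimised residual with one coordinate fixed. Schemes "2"/"constant"
# refit by (constrained) linear least squares; scheme "3" by simplex search
# restarted from the joint optimum.
.profile_refit <- function(fit, parameter, value) {
  scheme <- if (fit$scheme %in% c("2", "1")) "2" else fit$scheme
  if (scheme %in% c("2", "constant")) {
    dv <- fit$deriv
    keep <- match(round(dv$times, 12), round(fit$data$times, 12))
    X <- fit$data$X[fit$network$nodes, keep, drop = FALSE]
    G <- .gradient_design(fit$network, X, dv$times, scheme)
    y <- as.vector(dv$Xdot[fit$network$nodes, , drop = FALSE])
    C <- .nonneg_constraints(fit$network, dv$times, scheme)
    fx <- stats::setNames(value, parameter)
    r <- .constrained_ls(G, y, C, fixed = fx)
    list(residual = sqrt(r$rss), theta = r$theta, ok = r$converged)
  } else {
    obj <- .scheme3_objective(fit$network, fit$data, fit$objective_norm)
    pars <- names(fit$coefficients)
    free <- setdiff(pars, parameter)
    th0 <- fit$coefficients[free]
    f <- function(v) {
      th <- stats::setNames(numeric(length(pars)), pars)
      th[free] <- v; th[parameter] <- value
      obj(th)
    }
    o <- stats::optim(th0, f, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
    list(residual = o$value, theta = o$par, ok = o$convergence %in% 0:1)
  }
}

# residual of the joint optimum on the same scale as .profile_refit
.profile_base_residual <- function(fit) {
  if (fit$scheme %in% c("1", "2", "constant")) fit$residual
  else fit$trajectory_residual
}

#' Profile likelihood of one parameter
#'
#' Fixes the parameter on a grid around its estimate and re-optimises all
#' other parameters at each grid point. A parameter is flagged practically
#' identifiable when the profiled residual rises on both sides of the
#' optimum by at least `threshold` times the optimum residual (with an
#' absolute floor of `1e-8` for near-zero optima); a flat profile signals
#' loss of practical identifiability, as happens when a product is allowed
#' to decay without constraint.
#'
#' @param fit a [fit_kinetics()] object (schemes "2", "constant" refit in
#'   closed form; scheme "3" re-optimises by simplex search).
#' @param parameter coefficient name as in `coef(fit)`, e.g.
#'   `"X1->X2.gamma"` or `"decay:X4"`.
#' @param grid optional explicit grid of fixed values. The default grid has
#'   11 points with half-width `span` times the coefficient's leverage
#'   scale: at least `span * |estimate|`, but never less than the change
#'   that moves the rate curve by `span` times the typical rate magnitude
#'   (a coefficient of \eqn{t^q} is probed on the scale
#'   \eqn{\bar k / \overline{t^q}}). This keeps the profile meaningful for
#'   coefficients whose estimate is small.
#' @param npoints grid size when `grid` is NULL.
#' @param span relative half-width of the default grid (default 0.5).
#' @param threshold relative residual rise required on both sides
#'   (default 0.05).
#' @return object of class `"profile_curve"`: `parameter`, `grid`,
#'   `residuals`, `estimate`, `base_residual`, `identifiable`, `rise`.
#' @export
profile_likelihood <- function(fit, parameter, grid = NULL, npoints = 11L,
                               span = 0.5, threshold = 0.05) {
  stopifnot(inherits(fit, "kinfit"))
  if (!(parameter %in% names(fit$coefficients)))
    stop("unknown parameter: ", parameter)
  est <- fit$coefficients[[parameter]]
  if (is.null(grid)) {
    tt <- fit$data$times
    q <- if (grepl("\\.alpha$", parameter)) 2L
    else if (grepl("\\.beta$", parameter)) 1L else 0L
    K <- rate_curves(fit$network, fit$rates, tt)
    kbar <- max(mean(abs(K)), 1e-6)
    lever <- kbar / mean(abs(tt)^q)
    half <- span * max(abs(est), lever)
    grid <- est + seq(-half, half, length.out = npoints)
  }
  base <- .profile_base_residual(fit)
  prof <- vapply(grid, function(v) {
    r <- tryCatch(.profile_refit(fit, parameter, v),
                  error = function(e) list(residual = NA_real_))
    r$residual
  }, numeric(1L))
  thr <- max(threshold * base, 1e-8)
  left <- prof[grid < est]; right <- prof[grid > est]
  rise_left <- if (length(left)) max(left, na.rm = TRUE) - min(c(prof, base), na.rm = TRUE) else 0
  rise_right <- if (length(right)) max(right, na.rm = TRUE) - min(c(prof, base), na.rm = TRUE) else 0
  structure(list(parameter = parameter, grid = grid, residuals = prof,
                 estimate = est, base_residual = base,
                 rise = c(left = rise_left, right = rise_right),
                 threshold = thr,
                 identifiable = min(rise_left, rise_right) >= thr),
            class = "profile_curve")
}

#' @export
print.profile_curve <- function(x, ...) {
  cat("Profile of", x$parameter, "around", signif(x$estimate, 4), "—",
      if (x$identifiable) "identifiable" else "FLAT (not identifiable)",
      "\n  rise left/right:", signif(x$rise[1L], 3), "/",
      signif(x$rise[2L], 3), " threshold:", signif(x$threshold, 3), "\n")
  invisible(x)
}

#' @export
plot.profile_curve <- function(x, ...) {
  graphics::plot(x$grid, x$residuals, type = "b", pch = 16,
                 xlab = x$parameter, ylab = "profiled residual", ...)
  graphics::abline(v = x$estimate, lty = 2)
  invisible(x)
}

# Symmetrised numerical Hessian by central differences with relative steps.
.num_hessian <- function(fn, th, step = 1e-4) {
  p <- length(th)
  h <- pmax(abs(th) * step, step * 1e-2)
  if (any(h <= 0)) stop("finite-difference step underflow")
  H <- matrix(0, p, p, dimnames = list(names(th), names(th)))
  f0 <- fn(th)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        tp <- th; tp[i] <- th[i] + h[i]
        tm <- th; tm[i] <- th[i] - h[i]
        H[i, i] <- (fn(tp) - 2 * f0 + fn(tm)) / h[i]^2
      } else {
        tpp <- th; tpp[i] <- th[i] + h[i]; tpp[j] <- th[j] + h[j]
        tpm <- th; tpm[i] <- th[i] + h[i]; tpm[j] <- th[j] - h[j]
        tmp <- th; tmp[i] <- th[i] - h[i]; tmp[j] <- th[j] + h[j]
        tmm <- th; tmm[i] <- th[i] - h[i]; tmm[j] <- th[j] - h[j]
        H[i, j] <- H[j, i] <-
          (fn(tpp) - fn(tpm) - fn(tmp) + fn(tmm)) / (4 * h[i] * h[j])
      }
    }
  }
  (H + t(H)) / 2
}

#' Residual Hessian spectrum (sloppiness / sensitivity analysis)
#'
#' Numerical Hessian of the trajectory-matching residual with respect to
#' the parameters, by central differences with a relative step, then
#' symmetrised and eigendecomposed. Time-varying rates are handled by
#' differentiating the residual that already sums over measurement times,
#' i.e. a time-average of the point-wise sensitivities. Eigenvalue spreads
#' of many orders of magnitude are the signature of sloppy models;
#' eigenvectors of the smallest eigenvalues point at ill-determined
#' parameter combinations — typically rates out of nodes whose measured
#' concentrations are close to zero.
#'
#' @param fit a [fit_kinetics()] object.
#' @param data optional [ts_data()] (defaults to the fitted data).
#' @param step relative finite-difference step (default 1e-4).
#' @return object of class `"sensitivity_spectrum"`: `hessian`,
#'   `eigenvalues` (descending), `eigenvectors` (columns), `parameters`.
#' @export
sensitivity_spectrum <- function(fit, data = NULL, step = 1e-4) {
  stopifnot(inherits(fit, "kinfit"))
  if (is.null(data)) data <- fit$data
  data <- ts_data(data$times, data$X[fit$network$nodes, , drop = FALSE],
                  fit$network$nodes)
  X <- data$X
  x0 <- X[, 1L]
  obj <- function(theta) {
    names(theta) <- names(fit$coefficients)
    rs <- .theta_to_rateset(fit$network, theta,
                            if (fit$scheme == "constant") "constant" else "2")
    path <- .fast_trajectories(fit$network, rs, x0, data$times, n_sub = 6L)
    .traj_objective(path, X, fit$objective_norm)
  }
  H <- .num_hessian(obj, fit$coefficients, step)
  eg <- eigen(H, symmetric = TRUE)
  structure(list(hessian = H, eigenvalues = eg$values,
                 eigenvectors = eg$vectors,
                 parameters = names(fit$coefficients)),
            class = "sensitivity_spectrum")
}

#' @export
print.sensitivity_spectrum <- function(x, ...) {
  ev <- x$eigenvalues
  cat("Residual Hessian spectrum over", length(ev), "parameters\n")
  cat("  eigenvalue range:", signif(min(ev), 3), "to", signif(max(ev), 3),
      "\n")
  v <- x$eigenvectors[, length(ev)]
  top <- order(abs(v), decreasing = TRUE)[1:min(3, length(v))]
  cat("  softest direction loads on:",
      paste(x$parameters[top], collapse = ", "), "\n")
  invisible(x)
}
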