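# ---- S3 methods for "kinfit" -----------------------------------------------

#' @export
print.kinfit <- function(x, ...) {
  cat("Kinetic rate fit (scheme ", x$scheme, ")\n", sep = "")
  cat("  network: ", length(x$network$nodes), " nodes, ",
      nrow(x$network$edges), " edges; data: ", length(x$data$times),
      " time points\n", sep = "")
  cat("  b1 =", signif(x$coefficients[["b1"]], 4), "\n")
  cat("  residual =", signif(x$residual, 4),
      " trajectory residual =", signif(x$trajectory_residual, 4), "\n")
  invisible(x)
}

#' Summary of a kinetic rate fit
#'
#' @param object a [fit_kinetics()] object.
#' @param ... unused.
#' @return object of class `"summary.kinfit"`: a per-edge coefficient table
#'   plus residuals and diagnostics.
#' @export
summary.kinfit <- function(object, ...) {
  ids <- edge_ids(object$network)
  rows <- lapply(ids, function(id) {
    r <- object$rates$rates[[id]]
    if (length(r) == 1L) c(alpha = 0, beta = 0, gamma = r)
    else c(alpha = r[1L], beta = r[2L], gamma = r[3L])
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- ids
  structure(list(scheme = object$scheme, coefficients = tab,
                 b1 = object$coefficients[["b1"]],
                 decay = object$rates$decay,
                 residual = object$residual,
                 trajectory_residual = object$trajectory_residual,
                 diagnostics = object$diagnostics),
            class = "summary.kinfit")
}

#' @export
print.summary.kinfit <- function(x, ...) {
  cat("Kinetic rate fit, scheme", x$scheme, "\n")
  cat("Influx b1 =", signif(x$b1, 5), "\n")
  cat("Rate polynomials k(t) = alpha t^2 + beta t + gamma:\n")
  print(signif(x$coefficients, 5))
  if (length(x$decay)) {
    cat("Decay rates:\n"); print(unlist(x$decay))
  }
  cat("Derivative-matching residual:", signif(x$residual, 5), "\n")
  cat("Trajectory residual:", signif(x$trajectory_residual, 5), "\n")
  invisible(x)
}

#' @export
coef.kinfit <- function(object, ...) object$coefficients

#' @export
fitted.kinfit <- function(object, ...) object$fitted

#' @export
residuals.kinfit <- function(object, ...) object$data$X - object$fitted

#' Predict trajectories or rate curves from a fit
#'
#' @param object a [fit_kinetics()] object.
#' @param times evaluation times (default the measurement times).
#' @param what `"trajectories"` (model solution from the first measurement)
#'   or `"rates"` (the fitted rate curves).
#' @param ... unused.
#' @return matrix nodes x times, or rates x times.
#' @export
predict.kinfit <- function(object, times = NULL,
                           what = c("trajectories", "rates"), ...) {
  what <- match.arg(what)
  if (is.null(times)) times <- object$data$times
  if (what == "rates")
    return(rate_curves(object$network, object$rates, times))
  t0 <- object$data$times[1L]
  if (times[1L] < t0) stop("prediction starts at the first measurement time")
  grid <- unique(c(t0, times))
  out <- model_trajectories(object$network, object$rates,
                            object$data$X[, 1L], grid)
  out[, match(times, grid), drop = FALSE]
}

#' Simulate new datasets from a fitted model
#'
#' Integrates the fitted model and adds multiplicative uniform noise,
#' mirroring the generator used in the benchmark study.
#'
#' @param object a [fit_kinetics()] object.
#' @param nsim number of datasets.
#' @param seed optional RNG seed.
#' @param noise_level half-width of the relative uniform noise
#'   (default 0.10).
#' @param ... unused.
#' @return list of [ts_data()] objects.
#' @export
simulate.kinfit <- function(object, nsim = 1, seed = NULL,
                            noise_level = 0.10, ...) {
  if (!is.null(seed)) set.seed(seed)
  clean <- model_trajectories(object$network, object$rates,
                              object$data$X[, 1L], object$data$times)
  lapply(seq_len(nsim), function(i) {
    u <- matrix(stats::runif(length(clean), -noise_level, noise_level),
                nrow(clean))
    ts_data(object$data$times, clean * (1 + u), object$network$nodes)
  })
}

#' Plot a kinetic rate fit
#'
#' Two panels: measured concentrations (points) with fitted trajectories
#' (lines), and the fitted rate curves over the observation window.
#'
#' @param x a [fit_kinetics()] object.
#' @param which `1` (trajectories), `2` (rate curves) or `1:2`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.kinfit <- function(x, which = 1:2, ...) {
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old))
  if (length(which) > 1L) graphics::par(mfrow = c(1, length(which)))
  tt <- seq(x$data$times[1L], x$data$times[length(x$data$times)],
            length.out = 60L)
  cols <- grDevices::hcl.colors(length(x$network$nodes), "Dark 3")
  if (1 %in% which) {
    path <- predict(x, tt)
    graphics::matplot(x$data$times, t(x$data$X), pch = 16, col = cols,
                      xlab = "time", ylab = "concentration",
                      main = "data and fitted trajectories", ...)
    graphics::matlines(tt, t(path), lty = 1, col = cols)
  }
  if (2 %in% which) {
    K <- predict(x, tt, what = "rates")
    kc <- grDevices::hcl.colors(max(1L, nrow(K)), "Dynamic")
    graphics::matplot(tt, t(K), type = "l", lty = 1, col = kc,
                      xlab = "time", ylab = "catalytic rate k(t)",
                      main = "fitted rate curves", ...)
    graphics::legend("topleft", legend = rownames(K), col = kc, lty = 1,
                     cex = 0.7, bty = "n")
  }
  invisible(x)
}
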