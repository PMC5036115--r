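#' Concentration time-series container
#'
#' @param times strictly increasing numeric vector of measurement times
#'   (units are whatever the experiment used; days in the motivating data).
#' @param X numeric matrix, nodes x times, of concentrations.
#' @param labels node identifiers aligning rows to a network's nodes;
#'   defaults to `rownames(X)`.
#' @return object of class `"ts_data"` with fields `times`, `X`, `labels`.
#' @export
ts_data <- function(times, X, labels = rownames(X)) {
  X <- as.matrix(X)
  if (is.null(labels)) labels <- paste0("X", seq_len(nrow(X)))
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate row labels")
  if (length(labels) != nrow(X)) stop("labels do not match rows of X")
  if (length(times) != ncol(X)) stop("times do not match columns of X")
  if (length(times) < 2L) stop("at least two time points are required")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!all(is.finite(X))) stop("concentrations must be finite (no missing cells)")
  rownames(X) <- labels
  structure(list(times = as.numeric(times), X = X, labels = labels),
            class = "ts_data")
}

#' @export
print.ts_data <- function(x, ...) {
  cat("Time series:", nrow(x$X), "metabolites at", length(x$times),
      "time points on [", x$times[1L], ",", x$times[length(x$times)], "]\n")
  invisible(x)
}

#' Forward finite-difference derivative estimates
#'
#' Differences consecutive columns of the concentration matrix,
#' \eqn{\dot X \approx (X_{j+1} - X_j) / \Delta t_j}, giving estimates at the
#' left endpoint of each interval (exact for affine series). Non-equidistant
#' grids use the per-interval step.
#'
#' @param data a [ts_data()] object (m >= 2 time points).
#' @return object of class `"deriv_estimate"`: `times` (the m-1 left
#'   endpoints), `Xdot` (n x (m-1)), `method = "finite_difference"`.
#' @export
finite_difference_derivatives <- function(data) {
  stopifnot(inherits(data, "ts_data"))
  m <- length(data$times)
  dt <- diff(data$times)
  Xd <- (data$X[, -1L, drop = FALSE] - data$X[, -m, drop = FALSE]) /
    rep(dt, each = nrow(data$X))
  structure(list(times = data$times[-m], Xdot = Xd,
                 method = "finite_difference", smoothers = NULL),
            class = "deriv_estimate")
}

# Knot vector: data points as knots with boundary padding. For the cubic
# basis the two knots next to the boundary are dropped (not-a-knot end
# conditions), which removes the spurious boundary degrees of freedom and
# keeps the interpolation limit fourth-order accurate; at the reduced
# degrees used for very short series all data points stay knots.
.pspline_knots <- function(t, degree) {
  m <- length(t)
  h1 <- t[2L] - t[1L]
  hm <- t[m] - t[m - 1L]
  inner <- if (degree >= 3L && m >= 4L) t[-c(2L, m - 1L)] else t
  c(t[1L] - h1 * (degree:1), inner, t[m] + hm * (1:degree))
}

#' Fit a penalised B-spline (P-spline) to one series
#'
#' Cubic B-splines with a knot at every data point, fitted by penalised
#' least squares with a difference penalty of order `diff_order` on the
#' basis coefficients: minimise
#' \eqn{\sum_j (y_j - f(t_j))^2 + \lambda \sum (\Delta^d c)^2}. Small
#' \eqn{\lambda} approaches the interpolating spline, large \eqn{\lambda}
#' with a second-order penalty approaches the straight-line least-squares
#' fit. With fewer than 4 points the basis degree is reduced (quadratic at
#' m = 3, linear at m = 2) with a warning.
#'
#' @param t numeric vector of times (strictly increasing).
#' @param y numeric vector of observations.
#' @param penalty non-negative smoothing parameter \eqn{\lambda}, or
#'   `"auto"` for leave-one-out cross-validation over a log-spaced grid
#'   `10^seq(-4, 4)` (deterministic given the data).
#' @param degree B-spline degree (default cubic, reduced for short series).
#' @param diff_order order of the coefficient difference penalty (default 2).
#' @return object of class `"pspline"`; evaluate with [predict.pspline()].
#' @export
fit_pspline <- function(t, y, penalty = "auto", degree = 3L, diff_order = 2L) {
  m <- length(t)
  stopifnot(m == length(y), m >= 2L, all(diff(t) > 0))
  if (m < degree + 1L) {
    degree <- m - 1L
    warning("only ", m, " points: reducing P-spline degree to ", degree)
  }
  diff_order <- min(diff_order, m + degree - 2L)
  knots <- .pspline_knots(t, degree)
  B <- splines::splineDesign(knots, t, ord = degree + 1L)
  nb <- ncol(B)
  # difference penalty as divided differences over the Greville abscissae,
  # so its null space is exactly the low-order polynomials in t even on
  # non-uniform knot grids
  xi <- vapply(seq_len(nb), function(i) mean(knots[i + seq_len(degree)]),
               numeric(1L))
  D <- diag(nb)
  for (d in seq_len(min(diff_order, nb - 1L)))
    D <- diff(D) / (xi[(1L + d):nb] - xi[1:(nb - d)])
  P <- crossprod(D)
  BtB <- crossprod(B)
  # tiny ridge (relative to the basis Gram matrix only, so the large-lambda
  # limit is untouched) keeps the solve well-posed at lambda -> 0
  rdg <- 1e-10 * mean(diag(BtB))
  ridge <- rdg * diag(nb)
  # augmented QR least squares: numerically stable even at extreme lambda
  fit_at <- function(lam) {
    Aug <- rbind(B, sqrt(lam) * D, sqrt(rdg) * diag(nb))
    qr.solve(Aug, c(y, numeric(nrow(D) + nb)))
  }
  if (identical(penalty, "auto")) {
    grid <- 10^seq(-4, 4, length.out = 25L)
    press <- vapply(grid, function(lam) {
      H <- B %*% solve(BtB + lam * P + ridge, t(B))
      r <- (y - drop(H %*% y)) / pmax(1 - diag(H), 1e-8)
      mean(r^2)
    }, numeric(1L))
    lambda <- grid[which.min(press)]
  } else {
    if (!is.numeric(penalty) || penalty < 0) stop("penalty must be >= 0")
    lambda <- penalty
  }
  co <- drop(fit_at(lambda))
  structure(list(knots = knots, degree = degree, coef = co, lambda = lambda,
                 range = range(t)),
            class = "pspline")
}

#' Evaluate a fitted P-spline or its derivative
#'
#' @param object a [fit_pspline()] object.
#' @param newt evaluation times within the fitted range.
#' @param deriv derivative order (0 = curve, 1 = first derivative).
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.pspline <- function(object, newt, deriv = 0L, ...) {
  B <- splines::splineDesign(object$knots, newt, ord = object$degree + 1L,
                             derivs = rep(deriv, length(newt)))
  drop(B %*% object$coef)
}

#' Derivative matrix of all series by a chosen smoother
#'
#' Fits the chosen smoother to every row of the data and evaluates first
#' derivatives (P-spline path) at the requested grid, by default the
#' measurement times. The P-spline path also records the smoothed
#' concentration values at the same grid (field `Xs`), used when the
#' point-wise solve is run on a denser grid than the measurements.
#'
#' @param data a [ts_data()] object.
#' @param method `"pspline"` (default) or `"finite_difference"`.
#' @param penalty P-spline smoothing parameter or `"auto"`.
#' @param at evaluation times (default the measurement times); finite
#'   differences ignore this and use interval left endpoints.
#' @return object of class `"deriv_estimate"` with `times`, `Xdot`,
#'   `method`, `smoothers` (list of [fit_pspline()] objects) and `Xs`.
#' @export
derivatives_at <- function(data, method = c("pspline", "finite_difference"),
                           penalty = "auto", at = NULL) {
  method <- match.arg(method)
  if (method == "finite_difference") return(finite_difference_derivatives(data))
  if (is.null(at)) at <- data$times
  sm <- lapply(seq_len(nrow(data$X)), function(i)
    fit_pspline(data$times, data$X[i, ], penalty = penalty))
  names(sm) <- data$labels
  Xd <- t(vapply(sm, function(s) predict(s, at, deriv = 1L),
                 numeric(length(at))))
  Xs <- t(vapply(sm, function(s) predict(s, at), numeric(length(at))))
  rownames(Xd) <- rownames(Xs) <- data$labels
  structure(list(times = at, Xdot = Xd, method = "pspline",
                 smoothers = sm, Xs = Xs),
            class = "deriv_estimate")
}

#' Read a delimited concentration time-series file
#'
#' Dialect: first column node identifier, header row of numeric time
#' values, cells are concentrations. Columns are sorted by time (with a
#' warning when the file was unordered).
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return a [ts_data()] object.
#' @export
read_timeseries <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, colClasses = "character")
  labels <- df[[1L]]
  if (anyDuplicated(labels)) stop("duplicate node labels in ", path)
  times <- suppressWarnings(as.numeric(names(df)[-1L]))
  if (anyNA(times)) stop("header must contain numeric time values")
  X <- suppressWarnings(apply(as.matrix(df[, -1L, drop = FALSE]), 2L,
                              as.numeric))
  X <- matrix(X, nrow = length(labels))
  if (anyNA(X)) stop("non-numeric concentration cell(s) in ", path)
  if (anyDuplicated(times)) stop("duplicate time points in ", path)
  o <- order(times)
  if (any(o != seq_along(times))) {
    warning("time columns were unordered; sorting by time")
    times <- times[o]; X <- X[, o, drop = FALSE]
  }
  rownames(X) <- labels
  ts_data(times, X, labels)
}

#' Write a concentration time series in the package dialect
#'
#' @param data a [ts_data()] object.
#' @param path output path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(data, path, sep = "\t") {
  df <- data.frame(id = data$labels, data$X, check.names = FALSE)
  names(df) <- c("id", format(data$times, digits = 17, trim = TRUE))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
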