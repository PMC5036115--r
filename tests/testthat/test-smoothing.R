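test_that("finite differences are exact on constant and affine series", {
  tt <- c(0, 1, 2, 3)
  X <- rbind(rep(5, 4), 2 * tt + 1)
  d <- finite_difference_derivatives(ts_data(tt, X, c("a", "b")))
  expect_equal(d$times, c(0, 1, 2))
  expect_equal(unname(d$Xdot[1, ]), rep(0, 3))
  expect_equal(unname(d$Xdot[2, ]), rep(2, 3))
})

test_that("forward differences of t^2 give 2t + h at left endpoints", {
  h <- 0.25
  tt <- seq(0, 2, by = h)
  X <- matrix(tt^2, 1)
  d <- finite_difference_derivatives(ts_data(tt, X, "q"))
  # ((t+h)^2 - t^2)/h = 2t + h, the closed-form forward-difference value
  expect_equal(unname(d$Xdot[1, ]), 2 * tt[-length(tt)] + h)
})

test_that("non-equidistant grids use the per-interval step", {
  tt <- c(0, 0.5, 2, 3.5)
  X <- matrix(tt^2, 1)
  d <- finite_difference_derivatives(ts_data(tt, X, "q"))
  expect_equal(unname(d$Xdot[1, ]), 2 * tt[-4] + diff(tt))
})

test_that("an unpenalised rich P-spline interpolates the data", {
  set.seed(2)
  tt <- seq(0, 10, length.out = 12)
  y <- sin(tt) + 0.3 * tt
  ps <- fit_pspline(tt, y, penalty = 0)
  expect_lt(max(abs(predict(ps, tt) - y)), 1e-8)
})

test_that("a huge second-order penalty approaches the straight-line fit", {
  set.seed(3)
  tt <- seq(0, 5, length.out = 15)
  y <- 2 + 0.7 * tt + rnorm(15, 0, 0.3)
  ps <- fit_pspline(tt, y, penalty = 1e12)
  line <- lm(y ~ tt)
  expect_equal(predict(ps, tt), unname(fitted(line)), tolerance = 1e-4)
  slope <- coef(line)[[2]]
  expect_equal(unname(predict(ps, tt, deriv = 1)), rep(slope, 15),
               tolerance = 1e-3)
})

test_that("P-spline derivatives recover a cubic polynomial's derivative", {
  tt <- seq(0, 6, length.out = 20)
  y <- 0.5 * tt^3 - 2 * tt^2 + tt + 4
  dtrue <- 1.5 * tt^2 - 4 * tt + 1
  ps <- fit_pspline(tt, y, penalty = 1e-8)
  err <- max(abs(predict(ps, tt, deriv = 1) - dtrue))
  expect_lt(err, 0.01 * diff(range(dtrue)))
})

test_that("P-spline fitting is linear in the data for fixed penalty", {
  set.seed(8)
  tt <- seq(0, 4, length.out = 10)
  x <- rnorm(10); y <- rnorm(10)
  a <- 1.7; b <- -0.6
  f <- function(v) predict(fit_pspline(tt, v, penalty = 0.5), tt)
  expect_equal(f(a * x + b * y), a * f(x) + b * f(y), tolerance = 1e-9)
})

test_that("short series reduce the basis degree with a warning", {
  expect_warning(ps3 <- fit_pspline(c(1, 2, 3), c(1, 4, 9), penalty = 0),
                 "degree")
  expect_equal(ps3$degree, 2L)
  expect_warning(ps2 <- fit_pspline(c(1, 2), c(1, 2), penalty = 0), "degree")
  expect_equal(ps2$degree, 1L)
  expect_equal(predict(ps2, 1.5), 1.5, tolerance = 1e-8)
})

test_that("negative penalties are rejected", {
  expect_error(fit_pspline(1:5, 1:5, penalty = -1), "penalty")
})

test_that("spline derivatives of linear series equal the slope everywhere", {
  tt <- seq(0, 9, length.out = 10)
  dat <- ts_data(tt, rbind(3 * tt + 2, -1.5 * tt + 10), c("a", "b"))
  dv <- derivatives_at(dat, penalty = "auto")
  expect_equal(unname(dv$Xdot[1, ]), rep(3, 10), tolerance = 1e-6)
  expect_equal(unname(dv$Xdot[2, ]), rep(-1.5, 10), tolerance = 1e-6)
})

test_that("spline and finite-difference derivatives agree to O(dt) on dense data", {
  for (m in c(40, 80)) {
    tt <- seq(0, 2 * pi, length.out = m)
    h <- tt[2] - tt[1]
    dat <- ts_data(tt, matrix(sin(tt), 1), "s")
    dv <- derivatives_at(dat, penalty = 1e-8)
    fd <- finite_difference_derivatives(dat)
    common <- seq_len(m - 1)
    # forward differences are O(h); the spline is much closer to cos(t)
    expect_lt(max(abs(dv$Xdot[1, common] - cos(tt[common]))), h)
    expect_lt(max(abs(fd$Xdot[1, ] - cos(fd$times))), h)
  }
})

test_that("spline derivative matrix approximates the exact rates' derivatives", {
  sim <- noiseless_sim(seed = 11)
  dv <- derivatives_at(sim$clean)
  Dt <- sim$deriv_exact$Xdot
  expect_lt(sqrt(mean((dv$Xdot - Dt)^2)) / sqrt(mean(Dt^2)), 0.02)
})

test_that("time-series files round-trip and are canonicalised", {
  tt <- c(5, 6, 7, 8, 9)
  X <- matrix(runif(35, 0.1, 2), 7,
              dimnames = list(paste0("X", 1:7), NULL))
  dat <- ts_data(tt, X)
  f <- tempfile(fileext = ".tsv")
  write_timeseries(dat, f)
  dat2 <- read_timeseries(f)
  expect_equal(dat2$times, dat$times)
  expect_equal(dat2$X, dat$X)
  # shuffled time columns are sorted with a warning
  df <- read.table(f, sep = "\t", header = TRUE, check.names = FALSE)
  shuf <- c(1, 4, 2, 3, 5, 6)
  write.table(df[, shuf], f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(dat3 <- read_timeseries(f), "unordered")
  expect_equal(dat3$X, dat$X)
})

test_that("malformed time-series files are rejected", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("id\t1\t2", "a\t1\t2", "a\t3\t4"), f)
  expect_error(read_timeseries(f), "duplicate")
  writeLines(c("id\t1\t2", "a\t1\tzz"), f)
  expect_error(read_timeseries(f), "non-numeric")
  writeLines(c("id\t1\t1", "a\t1\t2"), f)
  expect_error(read_timeseries(f), "duplicate time")
})

test_that("the bundled synthetic five-point series feeds the point-wise scheme", {
  f <- system.file("extdata", "tomato_like_synthetic.tsv",
                   package = "kinetree")
  dat <- read_timeseries(f)
  expect_equal(dim(dat$X), c(7L, 5L))
  expect_equal(dat$times, 5:9)
  fit <- fit_kinetics(tree7(), dat, scheme = "1")
  expect_s3_class(fit, "kinfit")
  K <- predict(fit, what = "rates")
  expect_true(all(K >= -1e-9))
})
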