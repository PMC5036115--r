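test_that("standardisation gives zero mean, unit variance, and is idempotent", {
  z <- standardize(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(rep(2, 5)), "zero-variance")
})

test_that("a planted gene matching a rate curve ranks first", {
  sim <- noiseless_sim(seed = 3)
  fit <- fit_kinetics(sim$network, sim$clean, scheme = "2",
                      deriv = sim$deriv_exact)
  tt <- sim$spec$times
  K <- rate_curves(sim$network, fit$rates, tt)
  set.seed(1)
  e1 <- K[1, ] + rnorm(length(tt), 0, 1e-3 * sd(K[1, ]))
  decoys <- t(replicate(20, spline(seq(0, 10, length.out = 5), rnorm(5),
                                   xout = tt)$y))
  E <- rbind(match1 = e1, neg1 = -K[1, ], decoys)
  rownames(E)[3:22] <- paste0("d", 1:20)
  rk <- rank_genes(fit, expr_table(tt, E))
  expect_equal(rk$ranking$gene[1], "match1")
  expect_gt(rk$ranking$score[1], 0.99)
  # the negated curve has correlation -1 with its edge and lands last among
  # all genes on that edge under signed scoring
  expect_equal(rk$correlations["neg1", rownames(K)[1]], -1, tolerance = 1e-9)
  expect_equal(which.min(rk$correlations[, rownames(K)[1]]),
               c(neg1 = 2L))
})

test_that("zero-variance genes are excluded with a flag", {
  sim <- noiseless_sim(seed = 3)
  fit <- fit_kinetics(sim$network, sim$clean, scheme = "2")
  tt <- sim$spec$times
  E <- rbind(flat = rep(1, length(tt)), ok = seq_along(tt))
  rk <- rank_genes(fit, expr_table(tt, E))
  expect_equal(rk$excluded, "flat")
  expect_false("flat" %in% rk$ranking$gene)
})

test_that("ranking is invariant under affine transforms of gene series", {
  sim <- noiseless_sim(seed = 3)
  fit <- fit_kinetics(sim$network, sim$clean, scheme = "2")
  tt <- sim$spec$times
  set.seed(4)
  E <- matrix(rnorm(5 * length(tt)), 5,
              dimnames = list(paste0("g", 1:5), NULL))
  rk1 <- rank_genes(fit, expr_table(tt, E))
  rk2 <- rank_genes(fit, expr_table(tt, 3.7 * E - 2))
  expect_equal(rk1$ranking, rk2$ranking, tolerance = 1e-10)
})

test_that("synthetic panels plant perfect matches at zero noise and are seeded", {
  sim <- noiseless_sim(seed = 3)
  tt <- sim$spec$times
  ex0 <- synthesize_expression(sim$network, sim$rates, tt, n_decoys = 10,
                               noise = 0, seed = 9)
  for (id in edge_ids(sim$network)) {
    g <- paste0("GT_", gsub("->", "_", id))
    k <- eval_rate(sim$rates$rates[[id]], tt)
    expect_equal(abs(cor(ex0$E[g, ], k)), 1, tolerance = 1e-9)
  }
  ex1 <- synthesize_expression(sim$network, sim$rates, tt, n_decoys = 10,
                               noise = 0.05, seed = 9)
  ex2 <- synthesize_expression(sim$network, sim$rates, tt, n_decoys = 10,
                               noise = 0.05, seed = 9)
  expect_identical(ex1$E, ex2$E)
})

test_that("decoy correlations with rate curves are centred and planted genes dominate", {
  sim <- noiseless_sim(seed = 3)
  fit <- fit_kinetics(sim$network, sim$clean, scheme = "2",
                      deriv = sim$deriv_exact)
  tt <- sim$spec$times
  ex <- synthesize_expression(sim$network, sim$rates, tt, n_decoys = 300,
                              noise = 0.05, seed = 2)
  rk <- rank_genes(fit, ex)
  dc <- rk$correlations[grep("^decoy", rownames(rk$correlations)), ]
  expect_lt(abs(mean(dc)), 0.15)
  planted <- attr(ex, "planted")
  expect_true(all(planted %in% rk$ranking$gene[1:10]))
})

test_that("expression tables round-trip through files", {
  tt <- 5:9
  E <- matrix(runif(15, 0.5, 2), 3, dimnames = list(c("a", "b", "c"), NULL))
  ex <- expr_table(tt, E)
  f <- tempfile(fileext = ".tsv")
  write_expression(ex, f)
  ex2 <- read_expression(f)
  expect_equal(ex2$genes, ex$genes)
  expect_equal(ex2$E, ex$E)
})

test_that("identical gene sets give a null MCMC comparison", {
  sim <- simulate_pathway(sim_spec_tomato(seed = 3, noise_level = 0.05))
  fit <- fit_kinetics(sim$network, sim$noisy, scheme = "2")
  ex <- synthesize_expression(sim$network, sim$rates, sim$spec$times,
                              n_decoys = 30, noise = 0.05, seed = 1)
  rk <- rank_genes(fit, ex)
  ps <- vapply(1:4, function(s) {
    mv <- mcmc_validate(fit, sim$noisy, ex, rk, setA = 1:10, setB = 1:10,
                        iterations = 8, samples = 40, seed = s)
    mv$mean_test$p.value
  }, numeric(1))
  # same set twice: no systematic difference, so mostly non-significant
  expect_gte(sum(ps > 0.05), 3L)
})

test_that("overlapping but different sets are rejected", {
  sim <- simulate_pathway(sim_spec_tomato(seed = 3, noise_level = 0.05))
  fit <- fit_kinetics(sim$network, sim$noisy, scheme = "2")
  ex <- synthesize_expression(sim$network, sim$rates, sim$spec$times,
                              n_decoys = 30, noise = 0.05, seed = 1)
  rk <- rank_genes(fit, ex)
  expect_error(mcmc_validate(fit, sim$noisy, ex, rk, setA = 1:10,
                             setB = 5:14), "disjoint")
  expect_error(mcmc_validate(fit, sim$noisy, ex, rk, setA = 1:3,
                             setB = 4:6), "cover")
})

test_that("an oracle panel of the true enzyme curves reaches the noise floor", {
  sp <- sim_spec_tomato(seed = 6, noise_level = 0)
  sim <- simulate_pathway(sp)
  fit <- fit_kinetics(sim$network, sim$clean, scheme = "2")
  # expression identical to the true rate curves, no decoys
  ex <- synthesize_expression(sim$network, sim$rates, sp$times,
                              n_decoys = 0, noise = 0, seed = 1,
                              standardized = FALSE)
  rk <- rank_genes(fit, ex)
  mv <- mcmc_validate(fit, sim$clean, ex, rk, setA = 1:6, setB = 1:6,
                      iterations = 6, samples = 60, seed = 1)
  # the substituted models keep the fit's influx estimate, so the
  # attainable floor is the true-rate model driven by that influx
  rs_b1fit <- sim$rates
  rs_b1fit$b1 <- max(0, coef(fit)[["b1"]])
  oracle_path <- model_trajectories(sim$network, rs_b1fit,
                                    sim$clean$X[, 1], sp$times)
  floor_res <- sum(colSums((oracle_path - sim$clean$X)^2))
  expect_lt(min(mv$residA), 2 * floor_res + 0.05)
})

test_that("MCMC validation is reproducible under a fixed seed", {
  sim <- simulate_pathway(sim_spec_tomato(seed = 3, noise_level = 0.05))
  fit <- fit_kinetics(sim$network, sim$noisy, scheme = "2")
  ex <- synthesize_expression(sim$network, sim$rates, sim$spec$times,
                              n_decoys = 30, noise = 0.05, seed = 1)
  rk <- rank_genes(fit, ex)
  m1 <- mcmc_validate(fit, sim$noisy, ex, rk, iterations = 5, samples = 30,
                      seed = 7)
  m2 <- mcmc_validate(fit, sim$noisy, ex, rk, iterations = 5, samples = 30,
                      seed = 7)
  expect_identical(m1$residA, m2$residA)
  expect_identical(m1$residB, m2$residB)
})
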