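test_that("empirical p-values use the add-one estimator with ties extreme", {
  expect_equal(empirical_pvalue(0, rep(1, 99), "upper"), 1)
  expect_equal(empirical_pvalue(2, rep(1, 99), "upper"), 1 / 100)
  expect_equal(empirical_pvalue(1, rep(1, 50), "upper"), 1)   # tie rule
  expect_equal(empirical_pvalue(5, rnorm(999) * 0.1, "upper"), 1 / 1000)
  expect_equal(empirical_pvalue(-3, c(-4, 2, 0.5), "two_sided_abs"), 2 / 4)
  expect_error(empirical_pvalue(1, numeric(0)), "non-empty")
})

test_that("bootstrap runs are bit-identical under a fixed seed", {
  sim <- simulate_gxe(n = 120, p = 10, q1 = 1, q2 = 0, s = 0, c = 0,
                      seed = 61)
  fit <- tlp_glm(sim$Z, sim$y, penalty = "oracle",
                 oracle_support = sim$oracle_support,
                 unpenalized = sim$unpenalized)
  b1 <- parametric_bootstrap(sim$y, sim$Z, sim$X, fit, B = 80, seed = 5)
  b2 <- parametric_bootstrap(sim$y, sim$Z, sim$X, fit, B = 80, seed = 5)
  expect_identical(b1$statistics, b2$statistics)
  expect_identical(b1$p_aispu, b2$p_aispu)
  # all p-values live in [1/(B+1), 1]
  expect_true(all(b1$pvalues_per_gamma >= 1 / 81 &
                    b1$pvalues_per_gamma <= 1))
  expect_gte(b1$p_aispu, 1 / 81)
})

test_that("bootstrap p-values are close to uniform under a gaussian null", {
  # small-p regime where the bootstrap is the recommended route; the null
  # model is refit on every replicate
  reps <- 150; B <- 99
  pv <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_linear(n = 80, p = 10, q = 5, s = 0, c = 0,
                           seed = 700 + r)
    fit <- tlp_glm(sim$Z, sim$y, family = "gaussian", penalty = "full")
    bt <- parametric_bootstrap(sim$y, sim$Z, sim$X, fit, gamma = c(1, 2, Inf),
                               B = B, seed = 800 + r)
    pv[r] <- bt$p_aispu
  }
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(pv <= 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / reps) + 1 / B)
})

test_that("gaussian and bootstrap moment backends agree on psi and omega", {
  sim <- simulate_gxe(n = 300, p = 6, q1 = 1, q2 = 0, s = 0, c = 0,
                      seed = 71)
  ft_g <- aispu(sim$y, sim$Z, sim$X, penalty = "oracle",
                oracle_support = sim$oracle_support,
                unpenalized = sim$unpenalized, gamma = c(1, 2),
                moment_backend = "gaussian", bandwidth = 5, seed = 2)
  ft_b <- aispu(sim$y, sim$Z, sim$X, penalty = "oracle",
                oracle_support = sim$oracle_support,
                unpenalized = sim$unpenalized, gamma = c(1, 2),
                moment_backend = "bootstrap", B = 400, seed = 2)
  # psi(2): relative agreement within bootstrap Monte-Carlo error
  expect_equal(unname(ft_b$moments$psi[["2"]] / ft_g$moments$psi[["2"]]), 1,
               tolerance = 0.2)
  expect_equal(unname(ft_b$moments$omega[["2"]] / ft_g$moments$omega[["2"]]),
               1, tolerance = 0.25)
  expect_equal(unname(ft_b$moments$omega[["1"]] / ft_g$moments$omega[["1"]]),
               1, tolerance = 0.25)
})

test_that("refitting per replicate changes the null spread when it should", {
  sim <- simulate_gxe(n = 200, p = 8, q1 = 1, q2 = 0, s = 0, c = 0,
                      seed = 81)
  fit <- tlp_glm(sim$Z, sim$y, penalty = "oracle",
                 oracle_support = sim$oracle_support,
                 unpenalized = sim$unpenalized)
  b_refit <- parametric_bootstrap(sim$y, sim$Z, sim$X, fit, B = 150,
                                  seed = 9, refit = "coefficients")
  b_fixed <- parametric_bootstrap(sim$y, sim$Z, sim$X, fit, B = 150,
                                  seed = 9, refit = "none")
  expect_identical(b_refit$observed, b_fixed$observed)
  # identical outcome draws but different null fits per replicate
  expect_false(identical(b_refit$statistics, b_fixed$statistics))
})
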