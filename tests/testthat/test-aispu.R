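test_that("the adaptive test returns a coherent result object", {
  sim <- simulate_gxe(n = 250, p = 20, q1 = 1, q2 = 0, s = 0, c = 0,
                      seed = 91)
  ft <- aispu(sim$y, sim$Z, sim$X, penalty = "oracle",
              oracle_support = sim$oracle_support,
              unpenalized = sim$unpenalized, seed = 1)
  expect_s3_class(ft, "aispu")
  expect_equal(ft$per_gamma$gamma, c(1:6, Inf))
  expect_true(all(ft$per_gamma$p >= 0 & ft$per_gamma$p <= 1))
  expect_equal(ft$p_min, min(ft$p_O, ft$p_E, ft$p_inf))
  expect_equal(ft$p_aispu, 1 - (1 - ft$p_min)^3)
  expect_output(print(ft), "aiSPU p-value")
  # restricting to a single even power collapses to that group
  ft2 <- aispu(sim$y, sim$Z, sim$X, penalty = "oracle",
               oracle_support = sim$oracle_support,
               unpenalized = sim$unpenalized, gamma = 2, seed = 1)
  expect_equal(ft2$p_aispu, ft2$p_E)
})

test_that("asymptotic and bootstrap routes agree on the observed statistics", {
  sim <- simulate_gxe(n = 200, p = 10, q1 = 1, q2 = 0, s = 0, c = 0,
                      seed = 92)
  fit <- tlp_glm(sim$Z, sim$y, penalty = "oracle",
                 oracle_support = sim$oracle_support,
                 unpenalized = sim$unpenalized)
  fa <- aispu(sim$y, sim$Z, sim$X, null_fit = fit, method = "asymptotic",
              seed = 3)
  fb <- aispu(sim$y, sim$Z, sim$X, null_fit = fit, method = "bootstrap",
              B = 50, seed = 3)
  # finite-power statistics are route-independent; the maximum statistic is
  # standardized by the efficient-score variance on the asymptotic route
  # and by the raw score variance on the (rank-based) bootstrap route
  fin <- is.finite(fa$per_gamma$gamma)
  expect_equal(fa$per_gamma$L[fin], fb$per_gamma$L[fin], tolerance = 1e-12)
})

test_that("a fitted null can be passed in and reused", {
  sim <- simulate_gxe(n = 150, p = 8, q1 = 1, q2 = 0, s = 0, c = 0,
                      seed = 93)
  fit <- tlp_glm(sim$Z, sim$y, penalty = "full")
  ft <- aispu(sim$y, sim$Z, sim$X, null_fit = fit, seed = 2)
  expect_identical(ft$null_fit, fit)
})

test_that("results serialize to JSON with the covariance metadata", {
  sim <- simulate_gxe(n = 150, p = 8, q1 = 1, q2 = 0, s = 0, c = 0,
                      seed = 94)
  ft <- aispu(sim$y, sim$Z, sim$X, penalty = "oracle",
              oracle_support = sim$oracle_support,
              unpenalized = sim$unpenalized, seed = 4)
  path <- tempfile(fileext = ".json")
  write_aispu_json(ft, path)
  got <- jsonlite::read_json(path)
  expect_equal(got$p_aispu, ft$p_aispu, tolerance = 1e-12)
  expect_equal(got$sigma$method, "banded")
  expect_equal(length(got$per_gamma), nrow(ft$per_gamma))
  unlink(path)
})

test_that("tlp_glm method surface behaves like a model object", {
  sim <- simulate_gxe(n = 200, p = 10, q1 = 1, q2 = 0, s = 0, c = 0,
                      seed = 95)
  fit <- tlp_glm(sim$Z, sim$y, penalty = "tlp",
                 unpenalized = sim$unpenalized, seed = 5)
  expect_length(coef(fit), ncol(sim$Z))
  expect_length(fitted(fit), 200)
  expect_true(all(fitted(fit) > 0 & fitted(fit) < 1))
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, sim$Z, type = "link"),
               drop(sim$Z %*% coef(fit)), tolerance = 1e-12)
  Y <- simulate(fit, nsim = 3, seed = 6)
  expect_equal(dim(Y), c(200L, 3L))
  expect_true(all(Y %in% 0:1))
  expect_identical(Y, simulate(fit, nsim = 3, seed = 6))
  expect_output(print(fit), "penalty = tlp")
  expect_gt(deviance(fit), 0)
})

test_that("input validation catches malformed problems", {
  sim <- simulate_gxe(n = 100, p = 6, q1 = 1, q2 = 0, s = 0, c = 0,
                      seed = 96)
  expect_error(aispu(sim$y[-1], sim$Z, sim$X), "conform")
  expect_error(tlp_glm(sim$Z, c(sim$y[-1], 2)), "0/1")
  expect_error(tlp_glm(sim$Z, sim$y, unpenalized = 0L), "unpenalized")
  expect_error(tlp_glm(sim$Z, sim$y, unpenalized = 2L),
               "constant columns")
  expect_error(tlp_glm(sim$Z, sim$y, penalty = "oracle"), "oracle_support")
})
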