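test_that("tlp_penalty matches its definition and rejects bad thresholds", {
  expect_equal(tlp_penalty(0.5, 1), 0.5)
  expect_equal(tlp_penalty(-3, 2), 2)
  expect_equal(tlp_penalty(0, 0.1), 0)
  # even in x, non-decreasing in |x|, constant beyond tau
  x <- seq(-3, 3, by = 0.1)
  expect_equal(tlp_penalty(x, 0.7), tlp_penalty(-x, 0.7))
  expect_true(all(diff(tlp_penalty(abs(x), 0.7)[order(abs(x))]) >= -1e-12))
  expect_equal(tlp_penalty(c(0.8, 1.5, 100), 0.7), rep(0.7, 3))
  expect_error(tlp_penalty(1, 0), "tau")
  expect_error(tlp_penalty(1, -1), "tau")
})

test_that("gaussian TLP fit beats an exhaustive lattice search", {
  # q = 2 penalized coefficients on a unit-scale design: compare the DC
  # solution against brute-force minimization of the penalized objective
  # over a fine 2-D lattice (the intercept is profiled out exactly)
  n <- 80
  Z <- unit_scale_design(n, 3, seed = 42)
  y <- aispu:::with_seed_(43, drop(Z %*% c(0.2, 0.8, -0.3)) + rnorm(n))
  lambda <- 0.3; tau <- 0.5
  fit <- tlp_glm(Z, y, family = "gaussian", penalty = "tlp",
                 lambda = lambda, tau = tau)
  b <- coef(fit)

  grid <- seq(-1.5, 1.5, by = 1e-3)
  z1 <- Z[, 2]; z2 <- Z[, 3]
  # profile objective: intercept = mean residual for any (b1, b2)
  cross1 <- mean(y * z1); cross2 <- mean(y * z2); c12 <- mean(z1 * z2)
  my <- mean(y)
  # 0.5*mean((yc - b1 z1 - b2 z2)^2) expanded (columns are unit-scale)
  const <- 0.5 * mean((y - my)^2)
  obj_grid <- function(b1, b2) {
    const - b1 * cross1 - b2 * cross2 +
      0.5 * (b1^2 + b2^2) + b1 * b2 * c12 +
      lambda * (pmin(abs(b1), tau) + pmin(abs(b2), tau))
  }
  best <- Inf; arg <- c(NA, NA)
  for (b2 in grid) {
    v <- obj_grid(grid, b2)
    i <- which.min(v)
    if (v[i] < best) { best <- v[i]; arg <- c(grid[i], b2) }
  }
  fit_obj <- tlp_objective_gaussian(Z, y, b, lambda, tau, penalized = 2:3)
  # the solver should be at least as good as the lattice optimum (up to
  # lattice resolution) and close to it in location
  expect_lt(fit_obj, best + 1e-5)
  expect_equal(unname(b[2:3]), arg, tolerance = 5e-3)
})

test_that("TLP with a huge threshold reduces to the Lasso", {
  # TLP(x, tau) = |x| once tau exceeds every |coefficient|: the DC solution
  # must match glmnet's Lasso at the same lambda (gaussian, exact scale)
  n <- 120; q <- 21
  Z <- unit_scale_design(n, q, seed = 7)
  theta <- c(0.3, 1, -1, 0.5, rep(0, q - 4))
  y <- aispu:::with_seed_(8, drop(Z %*% theta) + rnorm(n))
  lambda <- 0.15
  fit <- tlp_glm(Z, y, family = "gaussian", penalty = "tlp",
                 lambda = lambda, tau = 1e6)
  g <- glmnet::glmnet(Z[, -1], y, standardize = FALSE, intercept = TRUE,
                      lambda = lambda * c(4, 2, 1), thresh = 1e-12)
  bg <- c(g$a0[3], as.matrix(g$beta)[, 3])
  expect_equal(unname(coef(fit)), unname(bg), tolerance = 1e-6)
})

test_that("the full-MLE variant equals ordinary least squares", {
  n <- 60; q <- 5
  Z <- unit_scale_design(n, q, seed = 3)
  y <- aispu:::with_seed_(4, drop(Z %*% c(1, 0.5, 0, -0.2, 0.1)) + rnorm(n))
  fit <- tlp_glm(Z, y, family = "gaussian", penalty = "full")
  expect_equal(unname(coef(fit)), unname(coef(lm(y ~ Z - 1))),
               tolerance = 1e-8)
  # q >= n is refused
  expect_error(tlp_glm(unit_scale_design(10, 12, 1), rnorm(10),
                       family = "gaussian", penalty = "full"),
               "fewer coefficients")
})

test_that("DC iterations never increase the penalized objective", {
  for (seed in 1:4) {
    sim <- simulate_gxe(n = 150, p = 30, q1 = 2, q2 = 1, s = 0.1, c = 1,
                        seed = seed)
    fit <- tlp_glm(sim$Z, sim$y, penalty = "tlp",
                   unpenalized = sim$unpenalized,
                   lambda = 0.05, tau = 0.1)
    expect_true(all(diff(fit$objective) <= 1e-8))
  }
  # gaussian family as well
  sim <- simulate_linear(n = 100, p = 20, q = 30, s = 0.1, c = 0.5, seed = 9)
  fit <- tlp_glm(sim$Z, sim$y, family = "gaussian", penalty = "tlp",
                 lambda = 0.08, tau = 0.2)
  expect_true(all(diff(fit$objective) <= 1e-8))
})

test_that("unpenalized coefficients are never thresholded to zero", {
  # enormous lambda kills every penalized coefficient but the intercept and
  # declared covariates survive
  sim <- simulate_gxe(n = 300, p = 20, q1 = 2, q2 = 0, s = 0, c = 0,
                      seed = 5)
  fit <- tlp_glm(sim$Z, sim$y, penalty = "tlp", unpenalized = 1:4,
                 lambda = 5, tau = 0.5)
  expect_true(all(coef(fit)[5:24] == 0))
  expect_true(all(coef(fit)[c(1, 4)] != 0))   # intercept and exposure
})

test_that("cross-validation honors singleton grids, seeds and ties", {
  sim <- simulate_linear(n = 120, p = 10, q = 15, s = 0, c = 0, seed = 21)
  f1 <- tlp_glm(sim$Z, sim$y, family = "gaussian", penalty = "tlp",
                lambda_grid = 0.2, tau_grid = 0.1, seed = 1)
  expect_equal(f1$tuning$lambda, 0.2)
  expect_equal(f1$tuning$tau, 0.1)
  f2 <- tlp_glm(sim$Z, sim$y, family = "gaussian", penalty = "tlp", seed = 77)
  f3 <- tlp_glm(sim$Z, sim$y, family = "gaussian", penalty = "tlp", seed = 77)
  expect_identical(f2$tuning, f3$tuning)
  expect_identical(coef(f2), coef(f3))
})

test_that("cross-validated TLP recovers a sparse gaussian support", {
  # 2 true nonzero nuisance effects of 0.4 among 50: the selected model
  # should contain the true support in nearly every replicate
  reps <- 40
  hit <- 0L
  for (r in seq_len(reps)) {
    n <- 400; q <- 51
    Z <- unit_scale_design(n, q, seed = 1000 + r)
    theta <- c(0.2, 0.4, 0.4, rep(0, q - 3))
    y <- aispu:::with_seed_(2000 + r, drop(Z %*% theta) + rnorm(n))
    fit <- tlp_glm(Z, y, family = "gaussian", penalty = "tlp",
                   seed = 3000 + r)
    if (all(c(2L, 3L) %in% fit$support)) hit <- hit + 1L
  }
  expect_gte(hit / reps, 0.95)
})

test_that("TLP reconstructs the oracle support on the case-control design", {
  # 2000 cases + 2000 controls with +/-0.4 genetic main effects, tuned by
  # the selection-consistent BIC rule: the selected support should coincide
  # with the oracle support in at least 90% of replicates.  (Deviance
  # cross-validation is prediction-optimal and systematically overselects,
  # so it cannot exhibit this reconstruction property.)
  reps <- 30
  hit <- 0L
  for (r in seq_len(reps)) {
    sim <- simulate_gxe(n = 4000, p = 25, q1 = 2, q2 = 2, s = 0, c = 0,
                        seed = 500 + r)
    fit <- tlp_glm(sim$Z, sim$y, penalty = "tlp", cv_rule = "bic",
                   unpenalized = sim$unpenalized, seed = 600 + r)
    if (identical(sort(fit$support), sort(sim$oracle_support))) hit <- hit + 1L
  }
  expect_gte(hit / reps, 0.9)
})

test_that("null_mean applies the canonical inverse link", {
  Z <- matrix(c(1, 1, 1, 0, 1, 2), 3, 2)
  expect_equal(null_mean(Z, c(0, 0), "binomial"), rep(0.5, 3))
  expect_equal(null_mean(Z, c(0, 0), "gaussian"), rep(0, 3))
  expect_equal(null_mean(matrix(1, 1, 1), log(0.4 / 0.6), "binomial"), 0.4)
})
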