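test_that("Gaussian cross moments obey symmetry and the Isserlis identity", {
  expect_equal(gaussian_cross_moment(3, 2, 1, 1, 0.4), 0)   # odd total order
  expect_equal(gaussian_cross_moment(1, 1, 2, 3, 0.7), 0.7) # covariance
  expect_equal(gaussian_cross_moment(2, 2, 1, 1, 0.5), 1.5) # s11 s22 + 2 s12^2
  expect_equal(gaussian_cross_moment(2, 0, 2, 1, 0), 2)     # marginal moment
  expect_equal(gaussian_cross_moment(4, 0, 1.5, 1, 0), 3 * 1.5^2)
  expect_error(gaussian_cross_moment(2, 2, 1, 1, 1.5), "positive semidefinite")
})

test_that("Gaussian cross moments match brute-force simulation", {
  s11 <- 1.3; s22 <- 0.8; s12 <- -0.5
  n <- 2e6
  draws <- aispu:::with_seed_(99, {
    z1 <- rnorm(n, 0, sqrt(s11))
    z2 <- s12 / s11 * z1 + rnorm(n, 0, sqrt(s22 - s12^2 / s11))
    cbind(z1, z2)
  })
  for (st in list(c(2, 2), c(1, 3), c(4, 2))) {
    x <- draws[, 1]^st[1] * draws[, 2]^st[2]
    mc <- mean(x); se <- sd(x) / sqrt(n)
    expect_lt(abs(gaussian_cross_moment(st[1], st[2], s11, s22, s12) - mc),
              3 * se)
  }
})

test_that("null moments under an identity covariance have closed forms", {
  p <- 40; n <- 100
  sig <- sigma_from_matrix(diag(p))
  mom <- null_moments(sig, n, 1:4)
  expect_equal(unname(mom$psi[["1"]]), 0)
  expect_equal(unname(mom$psi[["3"]]), 0)
  expect_equal(unname(mom$psi[["2"]]), p / n)
  expect_equal(unname(mom$psi[["4"]]), 3 * p / n^2)
  expect_equal(unname(mom$omega[["2"]]), sqrt(2 * p / n^2))
  expect_equal(unname(mom$omega[["1"]]), sqrt(p / n))
  # corr(L(1), L(3)) = 3 / sqrt(15); odd-even cross correlations vanish
  expect_equal(mom$R["1", "3"], 3 / sqrt(15))
  expect_equal(mom$R["1", "2"], 0)
  expect_equal(mom$R["3", "4"], 0)
  expect_equal(diag(mom$R), rep(1, 4), ignore_attr = TRUE)
})

test_that("null moments agree with Monte-Carlo moments under correlation", {
  # random dense covariance, p = 6: simulate Ubar ~ N(0, Sigma/n) and
  # compare simulated means/sds/correlations of L(gamma) with the exact
  # working-model moments
  p <- 6; n <- 40; nrep <- 1e5
  A <- aispu:::with_seed_(5, matrix(rnorm(p * p), p))
  S <- crossprod(A) / p + diag(p) * 0.5
  sig <- sigma_from_matrix(S)
  gammas <- 1:4
  mom <- null_moments(sig, n, gammas)
  U <- aispu:::with_seed_(6, matrix(rnorm(nrep * p), nrep) %*%
                               chol(S / n))
  L <- sapply(gammas, function(g) rowSums(U^g))
  for (i in seq_along(gammas)) {
    se_m <- sd(L[, i]) / sqrt(nrep)
    expect_lt(abs(mean(L[, i]) - mom$psi[i]), 4 * se_m)
    expect_lt(abs(sd(L[, i]) / mom$omega[i] - 1), 0.02)
  }
  # correlations within parity groups
  expect_lt(abs(cor(L[, 1], L[, 3]) - mom$R[1, 3]), 0.02)
  expect_lt(abs(cor(L[, 2], L[, 4]) - mom$R[2, 4]), 0.02)
  expect_lt(abs(cor(L[, 1], L[, 2]) - 0), 0.02)
})

test_that("standardized statistics are invariant to rescaling the scores", {
  # multiplying every score component by c > 0 rescales L, psi and omega
  # coherently, leaving the z-scores unchanged
  sim <- simulate_gxe(n = 150, p = 12, q1 = 1, q2 = 0, s = 0, c = 0,
                      seed = 31)
  fit <- tlp_glm(sim$Z, sim$y, penalty = "oracle",
                 oracle_support = sim$oracle_support,
                 unpenalized = sim$unpenalized)
  for (cc in c(1, sqrt(nrow(sim$X)))) {
    sc <- score_matrix(sim$y, cc * sim$X, fit$fitted)
    sig <- estimate_sigma_banded(sc, 0)
    mom <- null_moments(sig, sc$n, c(1, 2))
    L <- c(ispu_finite(sc, 1)$value, ispu_finite(sc, 2)$value)
    z <- (L - mom$psi) / mom$omega
    if (cc == 1) z_ref <- z else expect_equal(z, z_ref, tolerance = 1e-10)
  }
})

test_that("finite-power p-values use the correct tails", {
  expect_equal(pvalue_finite(0, 0, 1, gamma = 2), 0.5)
  expect_equal(pvalue_finite(0, 0, 1, gamma = 3), 1.0)
  expect_equal(pvalue_finite(1.6449, 0, 1, gamma = 2), 0.05,
               tolerance = 1e-4)
  # odd-power two-sided symmetry
  expect_equal(pvalue_finite(2, 0, 1, gamma = 1),
               pvalue_finite(-2, 0, 1, gamma = 1))
  expect_error(pvalue_finite(1, 0, 0, 2), "omega")
})

test_that("the extreme-value tail for the maximum statistic is exact", {
  p <- 100
  a_p <- 2 * log(p) - log(log(p))
  expect_equal(a_p, 7.6831, tolerance = 1e-4)
  expect_equal(pvalue_inf(a_p, p), 1 - exp(-1 / sqrt(pi)), tolerance = 1e-12)
  expect_lt(pvalue_inf(a_p + 50, p), 1e-10)
  expect_error(pvalue_inf(1, 2), "p >= 3")
})

test_that("the adaptive combination follows the min-p construction", {
  p <- 50
  sig <- sigma_from_matrix(diag(p))
  mom <- null_moments(sig, 100, 1:6)
  stats <- c(`1` = 0.05, `2` = p / 100 + 0.01, `3` = 0.001,
             `4` = 3 * p / 1e4, `5` = 0, `6` = 15 * p / 1e6)
  res <- combine_aispu(mom, stats, L_inf = 9, p = p)
  expect_true(all(res$per_gamma$p >= 0 & res$per_gamma$p <= 1))
  expect_equal(res$p_min, min(res$p_O, res$p_E, res$p_inf))
  expect_equal(res$p_aispu, 1 - (1 - res$p_min)^3)
  expect_equal(res$p_inf, pvalue_inf(9, p))
  # direct evaluation of the combination formula
  expect_equal(1 - (1 - 0.05)^3, 0.142625)
  # one group only: the combination reduces to that group's p-value
  mom2 <- null_moments(sig, 100, 2L)
  res2 <- combine_aispu(mom2, c(`2` = p / 100 + 0.005))
  expect_equal(res2$p_aispu, res2$p_E)
  expect_equal(res2$k, 1L)
  # p_aispu is monotone in p_min
  pm <- seq(0, 1, by = 0.01)
  expect_true(all(diff(1 - (1 - pm)^3) >= 0))
})

test_that("group p-values match the single- and two-gamma normal tails", {
  p <- 30
  sig <- sigma_from_matrix(diag(p))
  mom <- null_moments(sig, 60, c(1, 2))
  L1 <- 0.12; L2 <- p / 60 + 0.03
  res <- combine_aispu(mom, c(`1` = L1, `2` = L2))
  z1 <- L1 / mom$omega[["1"]]
  z2 <- (L2 - mom$psi[["2"]]) / mom$omega[["2"]]
  expect_equal(res$p_O, 2 * pnorm(-abs(z1)), tolerance = 1e-10)
  expect_equal(res$p_E, pnorm(z2, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(res$p_aispu, 1 - (1 - min(res$p_O, res$p_E))^2)
})

test_that("the local-alternative power formula behaves at its anchors", {
  expect_equal(theoretical_power(1, 1, 1, 1, gamma = 2, alpha = 0.05), 0.05)
  expect_equal(theoretical_power(1, 1, 1, 1, gamma = 3, alpha = 0.05), 0.05,
               tolerance = 1e-12)
  expect_gt(theoretical_power(50, 0, 1, 1, gamma = 2, alpha = 0.05), 0.999)
  expect_gt(theoretical_power(-50, 0, 1, 1, gamma = 1, alpha = 0.05), 0.999)
  expect_error(theoretical_power(1, 0, 1, 0, 2, 0.05), "omegaA")
})
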