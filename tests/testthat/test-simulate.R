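test_that("genotypes are haplotype sums with the requested frequencies", {
  G <- simulate_genotypes(10000, 12, rho = 0, maf = c(0.1, 0.3), seed = 1)
  expect_true(all(G %in% 0:2))
  mafs <- attr(G, "maf")
  expect_true(all(mafs >= 0.1 & mafs <= 0.3))
  # per-marker mean within 3 binomial standard errors of 2*MAF
  se <- sqrt(2 * mafs * (1 - mafs) / 10000)
  expect_true(all(abs(colMeans(G) - 2 * mafs) < 3.5 * se))
  # independent markers when rho = 0
  cors <- cor(G)
  expect_lt(mean(abs(cors[upper.tri(cors)])), 0.05)
  # determinism
  expect_identical(G, simulate_genotypes(10000, 12, seed = 1))
})

test_that("latent autocorrelation induces genotype correlation", {
  G <- simulate_genotypes(4000, 10, rho = 0.8, maf = c(0.2, 0.3), seed = 2)
  r1 <- mean(diag(cor(G)[-1, -10]))   # lag-1 correlations
  expect_gt(r1, 0.3)
})

test_that("the case-control sampler fills exact quotas and honors nulls", {
  sim <- simulate_gxe(n = 300, p = 15, q1 = 2, q2 = 1, s = 0.2, c = 0,
                      seed = 3)
  expect_equal(sum(sim$y), 150)
  expect_equal(length(sim$y), 300)
  expect_true(all(sim$beta == 0))          # c = 0 is a null dataset
  expect_equal(dim(sim$Z), c(300, 19))     # [1, Z1, Z2, E, G]
  expect_equal(dim(sim$X), c(300, 15))
  expect_equal(sim$X, sim$Z[, -(1:4)] * sim$Z[, 4], ignore_attr = TRUE)
  expect_equal(sim$Z[, 1], rep(1, 300), ignore_attr = TRUE)
  expect_true(all(sim$Z[, 4] %in% c(-1, 1)))
  # genetic main effects: q1 at +0.4 then q2 at -0.4
  expect_equal(unname(sim$theta[5:7]), c(0.4, 0.4, -0.4))
  expect_identical(sim, simulate_gxe(n = 300, p = 15, q1 = 2, q2 = 1,
                                     s = 0.2, c = 0, seed = 3))
})

test_that("interaction sparsity gives floor(p*s) nonzero coefficients", {
  sim <- simulate_gxe(n = 100, p = 1000, q1 = 2, q2 = 2, s = 0.005, c = 2,
                      seed = 4)
  expect_equal(sum(sim$beta != 0), 5L)
  expect_true(all(abs(sim$beta) <= 2))
  sim1 <- simulate_gxe(n = 100, p = 200, q1 = 0, q2 = 0, s = 0.05, c = 1,
                       signs = "one_sided", seed = 5)
  expect_equal(sum(sim1$beta != 0), 10L)
  expect_true(all(sim1$beta >= 0))
})

test_that("weak background effects can be planted in the nuisance", {
  sim <- simulate_gxe(n = 100, p = 50, q1 = 2, q2 = 2, s = 0, c = 0,
                      weak_z = 10, seed = 6)
  t4 <- sim$theta[-(1:4)]
  weak <- t4[t4 != 0 & abs(t4) < 0.4]
  expect_equal(length(weak), 10L)
  expect_true(all(abs(weak) <= 0.01))
})

test_that("the linear-model generator matches its covariance description", {
  sim <- simulate_linear(n = 5000, p = 30, q = 10, s = 0, c = 0,
                         theta = numeric(0), block_rho = 0, seed = 7)
  # pure noise outcome: unit variance
  expect_lt(abs(var(sim$y) - 1), 3 * sqrt(2 / 5000))
  cors <- cor(sim$X)
  expect_lt(mean(abs(cors[upper.tri(cors)])), 0.05)
  # block-correlated version
  sim2 <- simulate_linear(n = 4000, p = 20, q = 10, s = 0, c = 0,
                          block_size = 10, block_rho = 0.3, seed = 8)
  cors2 <- cor(sim2$X)
  within <- cors2[1:10, 1:10][upper.tri(diag(10))]
  across <- cors2[1:10, 11:20]
  expect_lt(abs(mean(within) - 0.3), 0.05)
  expect_lt(mean(abs(across)), 0.05)
  # default dimensions of the high-dimensional regime
  sim3 <- simulate_linear(seed = 9)
  expect_equal(dim(sim3$X), c(200L, 1000L))
  expect_equal(dim(sim3$Z), c(200L, 1001L))   # intercept prepended
  expect_equal(unname(sim3$theta[2:3]), c(0.4, 0.4))
})

test_that("oracle refits on simulated data recover the generating model", {
  sim <- simulate_gxe(n = 5000, p = 20, q1 = 2, q2 = 1, s = 0, c = 0,
                      seed = 10)
  cols <- sort(unique(c(sim$unpenalized, sim$oracle_support)))
  g <- glm.fit(sim$Z[, cols], sim$y, family = binomial())
  se <- sqrt(diag(chol2inv(chol(crossprod(sim$Z[, cols] * sqrt(g$weights))))))
  truth <- sim$theta[cols]
  # intercept shifts under case-control sampling; check the slopes
  expect_true(all(abs(g$coefficients[-1] - truth[-1]) < 3.5 * se[-1]))
})

test_that("datasets round-trip through the delimited writer", {
  sim <- simulate_gxe(n = 30, p = 4, q1 = 1, q2 = 0, s = 0.25, c = 1,
                      seed = 11)
  d <- file.path(tempdir(), "aispu-sim-test")
  write_sim(sim, d)
  y2 <- read_design(file.path(d, "y.csv"))
  Z2 <- read_design(file.path(d, "Z.csv"))
  X2 <- read_design(file.path(d, "X.csv"))
  expect_equal(drop(y2), sim$y, ignore_attr = TRUE)
  expect_equal(unname(Z2), unname(sim$Z), tolerance = 1e-12)
  expect_equal(unname(X2), unname(sim$X), tolerance = 1e-12)
  cfg <- jsonlite::read_json(file.path(d, "config.json"))
  expect_equal(cfg$n, 30)
  unlink(d, recursive = TRUE)
})
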