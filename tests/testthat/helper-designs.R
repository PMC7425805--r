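# Small reusable fixtures, all generated in code.

# Gaussian design whose non-intercept columns are exactly centered with
# population standard deviation 1, so the internal standardization is the
# identity and penalties act on the raw coefficient scale.
unit_scale_design <- function(n, q, seed) {
  withr_seed <- function(expr) aispu:::with_seed_(seed, expr)
  withr_seed({
    Z <- matrix(rnorm(n * (q - 1)), n, q - 1)
    Z <- sweep(Z, 2L, colMeans(Z), "-")
    s <- apply(Z, 2L, function(z) sd(z) * sqrt((n - 1) / n))
    Z <- sweep(Z, 2L, s, "/")
    cbind(1, Z)
  })
}

# Penalized objective of a gaussian TLP fit on the unit-scale design.
tlp_objective_gaussian <- function(Z, y, b, lambda, tau, penalized) {
  0.5 * mean((y - drop(Z %*% b))^2) +
    lambda * sum(pmin(abs(b[penalized]), tau))
}

# Manual score_matrix with prescribed column means (each row contributes
# the same value, so col_mean is exact).
score_with_means <- function(means, n = 2L) {
  X <- matrix(rep(means, each = n), n, length(means))
  score_matrix(rep(1, n), X, rep(0, n), center = FALSE)
}

# sigma_estimate with a prescribed dense covariance matrix (helper for
# moment tests).
sigma_from_matrix <- function(S) {
  p <- ncol(S)
  structure(list(
    p = p, diag = diag(S),
    offdiag = if (p > 1L) lapply(seq_len(p - 1L), function(o)
      S[cbind(seq_len(p - o), seq_len(p - o) + o)]) else list(),
    bandwidth = p - 1L, method = "banded", psd_adjusted = FALSE
  ), class = "sigma_estimate")
}
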