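#' Banded estimate of the score-component covariance
#'
#' Sample covariance of the rows of the score-component matrix \code{U},
#' with all entries further than \code{bandwidth} from the diagonal set to
#' zero (banding; consistent for bandable covariance structures such as
#' those induced by markers ordered along the genome).  The matrix is stored
#' compactly as the diagonal plus one vector per retained off-diagonal.
#'
#' Banding does not guarantee positive semidefiniteness.  For problems with
#' \code{p <= 500} a full eigendecomposition is checked and eigenvalues are
#' clipped at 1e-8 when needed; in all cases every retained off-diagonal
#' entry is clamped so each 2 x 2 principal submatrix is valid (this is what
#' the downstream moment computations consume pairwise).  \code{psd_adjusted}
#' records whether any repair happened.
#'
#' @param score a [score_matrix()] object (needs n >= 2).
#' @param bandwidth non-negative integer band half-width; 0 keeps only the
#'   diagonal, \code{p - 1} or more keeps the full sample covariance.
#' @return An object of class \code{"sigma_estimate"}: list with \code{p},
#'   \code{diag}, \code{offdiag} (list indexed by offset), \code{bandwidth},
#'   \code{method = "banded"} and \code{psd_adjusted}.
#' @seealso [select_bandwidth()], [null_moments()]
#' @export
estimate_sigma_banded <- function(score, bandwidth) {
  stopifnot(inherits(score, "score_matrix"))
  if (score$n < 2L) stop("need n >= 2 to estimate the covariance")
  bandwidth <- as.integer(bandwidth)
  if (bandwidth < 0L) stop("'bandwidth' must be >= 0")
  U <- score$U
  p <- ncol(U); n <- nrow(U)
  bw <- min(bandwidth, p - 1L)
  m <- colMeans(U)
  d <- (colSums(U^2) - n * m^2) / (n - 1)
  off <- list()
  if (bw >= 1L) {
    for (o in seq_len(bw)) {
      a <- seq_len(p - o); b <- a + o
      off[[o]] <- (colSums(U[, a, drop = FALSE] * U[, b, drop = FALSE]) -
                     n * m[a] * m[b]) / (n - 1)
    }
  }
  out <- structure(list(p = p, diag = d, offdiag = off,
                        bandwidth = bandwidth, method = "banded",
                        psd_adjusted = FALSE),
                   class = "sigma_estimate")
  psd_repair_(out)
}

# Repair a sigma_estimate so every 2x2 principal submatrix is PSD; for
# small p additionally clip global eigenvalues at 1e-8.
psd_repair_ <- function(sig) {
  adjusted <- FALSE
  p <- sig$p
  if (sig$p <= 500L && length(sig$offdiag)) {
    S <- as.matrix(sig)
    ev <- eigen(S, symmetric = TRUE)
    if (min(ev$values) < 1e-8) {
      S <- ev$vectors %*% (pmax(ev$values, 1e-8) * t(ev$vectors))
      adjusted <- TRUE
      sig$diag <- diag(S)
      for (o in seq_along(sig$offdiag))
        sig$offdiag[[o]] <- S[cbind(seq_len(p - o), seq_len(p - o) + o)]
    }
  }
  if (any(sig$diag <= 0)) {
    sig$diag <- pmax(sig$diag, 1e-8)
    adjusted <- TRUE
  }
  for (o in seq_along(sig$offdiag)) {
    a <- seq_len(p - o); b <- a + o
    bound <- (1 - 1e-8) * sqrt(sig$diag[a] * sig$diag[b])
    v <- sig$offdiag[[o]]
    if (any(abs(v) > bound)) {
      sig$offdiag[[o]] <- sign(v) * pmin(abs(v), bound)
      adjusted <- TRUE
    }
  }
  sig$psd_adjusted <- sig$psd_adjusted || adjusted
  sig
}

#' Parametric-bootstrap estimate of the score-component covariance
#'
#' Draws outcomes from the fitted null model, recomputes the score components
#' and pools the rows across replicates into one sample covariance.  Stored
#' densely (every off-diagonal retained), so intended for small to moderate
#' p; for large p use the banded estimator.
#'
#' @param fit a [tlp_glm()] null fit.
#' @param X tested design matrix (centered internally as in
#'   [score_matrix()]).
#' @param B number of bootstrap replicates to pool.
#' @param seed optional seed.
#' @return A \code{"sigma_estimate"} with \code{method = "bootstrap"}.
#' @export
estimate_sigma_bootstrap <- function(fit, X, B = 100L, seed = NULL) {
  stopifnot(inherits(fit, "tlp_glm"))
  X <- check_matrix_(X, "X")
  Xc <- sweep(X, 2L, colMeans(X), "-")
  n <- nrow(X); p <- ncol(X)
  Ymat <- simulate(fit, nsim = B, seed = seed)
  S <- matrix(0, p, p)
  for (b in seq_len(B)) {
    U <- (Ymat[, b] - fit$fitted) * Xc
    U <- sweep(U, 2L, colMeans(U), "-")
    S <- S + crossprod(U) / (n - 1)
  }
  S <- S / B
  out <- structure(list(p = p, diag = diag(S),
                        offdiag = lapply(seq_len(p - 1L), function(o)
                          S[cbind(seq_len(p - o), seq_len(p - o) + o)]),
                        bandwidth = p - 1L, method = "bootstrap",
                        psd_adjusted = FALSE),
                   class = "sigma_estimate")
  psd_repair_(out)
}

#' @export
as.matrix.sigma_estimate <- function(x, ...) {
  S <- diag(x$diag, nrow = x$p)
  for (o in seq_along(x$offdiag)) {
    idx <- cbind(seq_len(x$p - o), seq_len(x$p - o) + o)
    S[idx] <- x$offdiag[[o]]
    S[idx[, 2:1, drop = FALSE]] <- x$offdiag[[o]]
  }
  S
}

#' @export
print.sigma_estimate <- function(x, ...) {
  cat("Score-component covariance estimate (", x$method, ")\n", sep = "")
  cat("  p = ", x$p, ", bandwidth = ", x$bandwidth,
      if (x$psd_adjusted) ", psd-adjusted" else "", "\n", sep = "")
  invisible(x)
}

#' Select the banding half-width by random half-splits
#'
#' Resampling bandwidth selection for the banded covariance estimator: the
#' sample is randomly split in half, the banded covariance from one half is
#' compared (squared Frobenius distance) with the raw sample covariance of
#' the other half, and the candidate minimizing the average risk over the
#' splits is returned (ties toward the smaller bandwidth).  Implemented
#' without forming the full p x p matrices, so it stays cheap for large p.
#'
#' @param score a [score_matrix()] object.
#' @param candidates non-empty integer vector of candidate bandwidths.
#' @param splits number of random half-splits.
#' @param seed optional seed (caller's RNG state is preserved).
#' @return the selected bandwidth (integer).
#' @export
select_bandwidth <- function(score, candidates = 0:5, splits = 5L,
                             seed = NULL) {
  stopifnot(inherits(score, "score_matrix"))
  candidates <- sort(unique(as.integer(candidates)))
  if (!length(candidates)) stop("'candidates' must be non-empty")
  if (length(candidates) == 1L) return(candidates)
  U <- score$U
  n <- nrow(U); p <- ncol(U)
  kmax <- min(max(candidates), p - 1L)
  risk <- numeric(length(candidates))
  with_seed_(seed, {
    for (s in seq_len(splits)) {
      idx <- sample.int(n, ceiling(n / 2))
      risk <- risk + split_risk_(U[idx, , drop = FALSE],
                                 U[-idx, , drop = FALSE], candidates, kmax)
    }
  })
  candidates[which.min(risk)]   # which.min takes the first (smallest) tie
}

# risk(k) = sum_{|i-j|<=k} (S1_ij - S2_ij)^2 + sum_{|i-j|>k} S2_ij^2
# computed from per-offset covariance vectors plus ||S2||_F^2 via the Gram
# trick (n2 x n2 inner-product matrix instead of p x p).
split_risk_ <- function(U1, U2, candidates, kmax) {
  p <- ncol(U1)
  cov_off <- function(U, o) {
    n <- nrow(U); m <- colMeans(U)
    a <- seq_len(p - o); b <- a + o
    (colSums(U[, a, drop = FALSE] * U[, b, drop = FALSE]) -
        n * m[a] * m[b]) / (n - 1)
  }
  cov_diag <- function(U) {
    n <- nrow(U); m <- colMeans(U)
    (colSums(U^2) - n * m^2) / (n - 1)
  }
  U2c <- sweep(U2, 2L, colMeans(U2), "-")
  G <- tcrossprod(U2c) / (nrow(U2) - 1)
  total2 <- sum(G^2)                 # ||S2||_F^2
  # per-offset squared-difference and S2^2 band sums, offsets 0..kmax
  A <- numeric(kmax + 1L); B2 <- numeric(kmax + 1L)
  d1 <- cov_diag(U1); d2 <- cov_diag(U2)
  A[1L] <- sum((d1 - d2)^2); B2[1L] <- sum(d2^2)
  if (kmax >= 1L) for (o in seq_len(kmax)) {
    s1 <- cov_off(U1, o); s2 <- cov_off(U2, o)
    A[o + 1L] <- 2 * sum((s1 - s2)^2)
    B2[o + 1L] <- 2 * sum(s2^2)
  }
  vapply(candidates, function(k) {
    kk <- min(k, kmax)
    sum(A[seq_len(kk + 1L)]) + (total2 - sum(B2[seq_len(kk + 1L)]))
  }, numeric(1))
}
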