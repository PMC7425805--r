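#' Per-subject score components for the tested coefficients
#'
#' Under the null fit with fitted means \code{mu0}, the score component of
#' subject i for tested column j is \code{U[i, j] = (y[i] - mu0[i]) * X[i, j]}.
#' Columns of \code{X} are mean-centered first by default (the tested design
#' is assumed mean-zero; re-centering by the sample mean enforces it).
#'
#' @param y outcome vector (length n).
#' @param X tested design matrix (n x p), e.g. genotype-by-exposure
#'   interaction columns.
#' @param mu0 fitted null means (length n).
#' @param center logical; mean-center the columns of \code{X} before scoring.
#' @return An object of class \code{"score_matrix"}: a list with the n x p
#'   component matrix \code{U}, the column averages \code{col_mean}
#'   (\code{Ubar_j = mean(U[, j])}), and the dimensions \code{n}, \code{p}.
#' @examples
#' sc <- score_matrix(c(1, 0), matrix(c(2, 0), 2, 1), c(0.5, 0.5),
#'                    center = FALSE)
#' sc$U
#' @export
score_matrix <- function(y, X, mu0, center = TRUE) {
  X <- check_matrix_(X, "X")
  y <- as.numeric(y); mu0 <- as.numeric(mu0)
  if (length(y) != nrow(X) || length(mu0) != nrow(X))
    stop("dimensions of y, X and mu0 do not conform")
  if (center) X <- sweep(X, 2L, colMeans(X), "-")
  U <- (y - mu0) * X
  structure(list(U = U, col_mean = colMeans(U), n = nrow(X), p = ncol(X)),
            class = "score_matrix")
}

#' Efficient-score adjustment of the tested design
#'
#' Removes from each tested column its weighted projection onto the fitted
#' null-model directions: \code{X_adj = X - Z_A (Z_A' W Z_A)^{-1} Z_A' W X}
#' with \code{Z_A} the columns actually estimated under the null and
#' \code{W} the GLM variance weights.  Score components built from the
#' adjusted design have the covariance of the efficient score, which is the
#' correct null covariance of the score averages once the nuisance
#' coefficients are estimated; without the adjustment the score variance is
#' overstated whenever tested columns correlate with fitted covariates
#' (for genotype-by-exposure interactions, every column correlates with the
#' exposure main effect).  The score averages themselves are essentially
#' unchanged: at the null fit the residuals are orthogonal to the freely
#' fitted directions.
#'
#' @param X tested design (n x p).
#' @param Z_active matrix of fitted null-model columns (n x a).
#' @param w GLM variance weights (length n): \code{mu0 (1 - mu0)} for the
#'   binomial family, constant for the gaussian family.
#' @return the adjusted n x p design matrix.
#' @export
project_scores <- function(X, Z_active, w) {
  X <- check_matrix_(X, "X")
  Z_active <- check_matrix_(Z_active, "Z_active")
  if (nrow(Z_active) != nrow(X) || length(w) != nrow(X))
    stop("dimensions do not conform")
  ZW <- Z_active * w
  A <- crossprod(Z_active, ZW)
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {   # rank-deficient active set: weighted least squares
    sw <- sqrt(w)
    co <- qr.coef(qr(Z_active * sw), X * sw)
    co[is.na(co)] <- 0
    return(X - Z_active %*% co)
  }
  X - Z_active %*% backsolve(R, forwardsolve(t(R), crossprod(ZW, X)))
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("Score components: n =", x$n, ", p =", x$p, "\n")
  cat("  max |col mean| =", signif(max(abs(x$col_mean)), 4), "\n")
  invisible(x)
}

#' Sum-of-powered-score statistic for a finite power index
#'
#' \code{L(gamma) = sum_j Ubar_j^gamma}.  Small powers target dense signal
#' in the tested coefficients, large powers sparse signal.
#'
#' @param score a [score_matrix()] object.
#' @param gamma positive integer power index.
#' @return An object of class \code{"ispu_stat"} with fields \code{gamma}
#'   and \code{value}.
#' @export
ispu_finite <- function(score, gamma) {
  stopifnot(inherits(score, "score_matrix"))
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma < 1 || gamma != round(gamma))
    stop("'gamma' must be a finite positive integer")
  structure(list(gamma = gamma, value = sum(score$col_mean^gamma)),
            class = "ispu_stat")
}

#' Standardized maximum score statistic (power index infinity)
#'
#' \code{L(Inf) = max_j n * Ubar_j^2 / sigma_jj} where \code{sigma_jj} is an
#' estimate of the variance of the per-subject score component in column j.
#'
#' @param score a [score_matrix()] object.
#' @param sigma_diag length-p vector of positive variance estimates; by
#'   default the sample variances of the columns of \code{U}.
#' @return An object of class \code{"ispu_stat"} with fields \code{gamma =
#'   Inf}, \code{value} and \code{index} (the attaining column).
#' @export
ispu_inf <- function(score, sigma_diag = NULL) {
  stopifnot(inherits(score, "score_matrix"))
  if (is.null(sigma_diag)) sigma_diag <- apply(score$U, 2L, stats::var)
  if (length(sigma_diag) != score$p)
    stop("'sigma_diag' must have length p")
  bad <- which(sigma_diag <= 0)
  if (length(bad))
    stop("non-positive score-component variance in column ", bad[1L])
  z2 <- score$n * score$col_mean^2 / sigma_diag
  structure(list(gamma = Inf, value = max(z2), index = which.max(z2)),
            class = "ispu_stat")
}

#' @export
print.ispu_stat <- function(x, ...) {
  cat("iSPU(", if (is.finite(x$gamma)) x$gamma else "Inf", ") = ",
      signif(x$value, 6), "\n", sep = "")
  invisible(x)
}
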