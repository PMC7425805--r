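#' Cross moments of a mean-zero bivariate normal
#'
#' Exact evaluation of \code{E[Z1^s Z2^t]} for \code{(Z1, Z2)} mean-zero
#' bivariate normal with variances \code{s11}, \code{s22} and covariance
#' \code{s12}, via the Isserlis/Wick recursion
#' \code{M(s, t) = (s - 1) s11 M(s - 2, t) + t s12 M(s - 1, t - 1)}.
#' These are the building blocks of the null mean, variance and correlation
#' of the sum-of-powered-score statistics under their normal working model.
#'
#' @param s,t non-negative integer exponents.
#' @param s11,s22 variances (>= 0).
#' @param s12 covariance; the implied 2 x 2 matrix must be positive
#'   semidefinite.
#' @return the scalar cross moment (0 whenever \code{s + t} is odd).
#' @examples
#' gaussian_cross_moment(2, 2, 1, 1, 0.5)  # 1 + 2 * 0.25 = 1.5
#' @export
gaussian_cross_moment <- function(s, t, s11, s22, s12) {
  s <- as.integer(s); t <- as.integer(t)
  if (s < 0L || t < 0L) stop("exponents must be non-negative integers")
  if (s11 < 0 || s22 < 0 || s12^2 > s11 * s22 * (1 + 1e-12))
    stop("invalid covariance: the 2 x 2 matrix is not positive semidefinite")
  M <- cross_moment_table_(max(s, t, 1L), s11, s22, s12)
  M[[s + 1L]][[t + 1L]][1L]
}

# Vectorized table of cross moments M[[a+1]][[b+1]] = E[Z1^a Z2^b] for
# a, b = 0..gmax, where s11, s22, s12 are parallel vectors over pairs.
cross_moment_table_ <- function(gmax, s11, s22, s12) {
  one <- rep(1, length(s11))
  M <- vector("list", gmax + 1L)
  for (a in 0:gmax) M[[a + 1L]] <- vector("list", gmax + 1L)
  for (a in 0:gmax) for (b in 0:gmax) {
    M[[a + 1L]][[b + 1L]] <- if (a == 0L && b == 0L) {
      one
    } else if (a == 0L) {
      if (b %% 2L == 1L) 0 * one else double_factorial_(b - 1L) * s22^(b / 2)
    } else {
      v <- if (a >= 2L) (a - 1L) * s11 * M[[a - 1L]][[b + 1L]] else 0
      if (b >= 1L) v <- v + b * s12 * M[[a]][[b]]
      v
    }
  }
  M
}

double_factorial_ <- function(k) {
  if (k <= 0L) return(1)
  prod(seq(k, 1L, by = -2L))
}

# E[Z^k] for Z ~ N(0, v), vectorized over v.
gauss_moment_ <- function(k, v) {
  if (k %% 2L == 1L) rep(0, length(v)) else double_factorial_(k - 1L) * v^(k / 2)
}

#' Null moments of the sum-of-powered-score statistics
#'
#' Computes the null mean \code{psi(gamma)}, standard deviation
#' \code{omega(gamma)} and the correlation matrix \code{R} of the
#' standardized statistics over the finite power indices in \code{gammas},
#' under the normal working model \code{Ubar ~ N(0, Sigma / n)} implied by
#' the asymptotic null distribution.  All expectations are evaluated exactly
#' by Gaussian cross moments; pairs with a zero covariance entry contribute
#' nothing and are skipped, so the cost is O(p * bandwidth) for a banded
#' estimate.  Covariances between statistics whose power indices sum to an
#' odd number are exactly zero (odd moments of a centered normal vanish),
#' which is what makes the odd and even groups asymptotically independent.
#'
#' @param sigma a \code{"sigma_estimate"} (see [estimate_sigma_banded()]).
#' @param n the sample size behind the score averages.
#' @param gammas finite positive integer power indices.
#' @return An object of class \code{"null_moments"}: named vectors
#'   \code{psi} and \code{omega}, the correlation matrix \code{R}, and the
#'   inputs \code{gammas}, \code{n}.
#' @export
null_moments <- function(sigma, n, gammas) {
  stopifnot(inherits(sigma, "sigma_estimate"))
  gammas <- sort(unique(as.integer(gammas)))
  if (any(gammas < 1L)) stop("all power indices must be >= 1")
  G <- length(gammas)
  p <- sigma$p
  sjj <- sigma$diag / n
  gmax2 <- 2L * max(gammas)

  # diagonal (j = k) contributions
  psi <- vapply(gammas, function(g) sum(gauss_moment_(g, sjj)), numeric(1))
  names(psi) <- gammas
  covmat <- matrix(0, G, G, dimnames = list(gammas, gammas))
  for (a in seq_len(G)) for (b in a:G) {
    s <- gammas[a]; t <- gammas[b]
    if ((s + t) %% 2L == 1L) next
    covmat[a, b] <- sum(gauss_moment_(s + t, sjj) -
                          gauss_moment_(s, sjj) * gauss_moment_(t, sjj))
  }

  # off-diagonal pairs within the band, chunked to bound memory
  offs <- sigma$offdiag
  if (length(offs)) {
    pair_s11 <- pair_s22 <- pair_s12 <- vector("list", length(offs))
    for (o in seq_along(offs)) {
      a <- seq_len(p - o)
      pair_s11[[o]] <- sjj[a]
      pair_s22[[o]] <- sjj[a + o]
      pair_s12[[o]] <- offs[[o]] / n
    }
    s11 <- unlist(pair_s11); s22 <- unlist(pair_s22); s12 <- unlist(pair_s12)
    keep <- s12 != 0
    if (any(keep)) {
      s11 <- s11[keep]; s22 <- s22[keep]; s12 <- s12[keep]
      chunks <- split(seq_along(s11), ceiling(seq_along(s11) / 2e5))
      for (ch in chunks) {
        M <- cross_moment_table_(max(gammas), s11[ch], s22[ch], s12[ch])
        for (a in seq_len(G)) for (b in a:G) {
          s <- gammas[a]; t <- gammas[b]
          if ((s + t) %% 2L == 1L) next
          m_s1 <- gauss_moment_(s, s11[ch]); m_t1 <- gauss_moment_(t, s11[ch])
          m_s2 <- gauss_moment_(s, s22[ch]); m_t2 <- gauss_moment_(t, s22[ch])
          # ordered pairs (j,k) and (k,j)
          covmat[a, b] <- covmat[a, b] +
            sum(M[[s + 1L]][[t + 1L]] - m_s1 * m_t2) +
            sum(M[[t + 1L]][[s + 1L]] - m_t1 * m_s2)
        }
      }
    }
  }

  omega2 <- diag(covmat)
  if (any(omega2 <= 0))
    stop("non-positive variance for L(", gammas[which(omega2 <= 0)[1L]],
         "): the covariance estimate is broken")
  omega <- sqrt(omega2)
  names(omega) <- gammas
  R <- matrix(0, G, G, dimnames = list(gammas, gammas))
  for (a in seq_len(G)) for (b in a:G) {
    R[a, b] <- R[b, a] <- covmat[a, b] / (omega[a] * omega[b])
  }
  diag(R) <- 1
  structure(list(psi = psi, omega = omega, R = R, gammas = gammas, n = n),
            class = "null_moments")
}

#' @export
print.null_moments <- function(x, ...) {
  cat("Null moments over power indices", paste(x$gammas, collapse = ", "),
      "\n")
  print(data.frame(gamma = x$gammas, psi = x$psi, omega = x$omega,
                   row.names = NULL))
  invisible(x)
}

#' Asymptotic p-value of a single finite-power statistic
#'
#' Standardizes \code{L(gamma)} by its null moments and returns the normal
#' tail probability: two-sided for odd powers (the statistic can be large in
#' either direction), upper-tailed for even powers (only large positive
#' values indicate signal).
#'
#' @param L observed statistic.
#' @param psi,omega null mean and standard deviation (\code{omega > 0}).
#' @param gamma the power index (only its parity is used).
#' @return the p-value.
#' @export
pvalue_finite <- function(L, psi, omega, gamma) {
  if (omega <= 0) stop("'omega' must be positive")
  z <- (L - psi) / omega
  if (gamma %% 2 == 1) 2 * stats::pnorm(-abs(z)) else stats::pnorm(z, lower.tail = FALSE)
}

#' Asymptotic p-value of the maximum statistic via its extreme-value limit
#'
#' With centering constant \code{a_p = 2 log p - log log p}, the maximum
#' statistic satisfies \code{Pr(L(Inf) - a_p <= x) -> exp(-pi^(-1/2)
#' exp(-x/2))} (a Gumbel-type limit), giving
#' \code{p = 1 - exp(-pi^(-1/2) exp(-(L - a_p)/2))}.
#'
#' @param L_inf observed maximum statistic.
#' @param p number of tested columns (must be >= 3 so that
#'   \code{log log p > 0}).
#' @return the p-value.
#' @export
pvalue_inf <- function(L_inf, p) {
  if (p <= 2) stop("the extreme-value approximation requires p >= 3")
  a_p <- 2 * log(p) - log(log(p))
  -expm1(-exp(-(L_inf - a_p) / 2) / sqrt(pi))
}

# Multivariate-normal rectangle probability with a frozen quasi-Monte-Carlo
# seed so repeated calls give identical p-values; the caller's RNG state is
# untouched.  Retries with a larger point budget if the reported estimation
# error exceeds `err_tol`.
pmvnorm_seeded_ <- function(lower, upper, corr, abseps = 1e-5,
                            err_tol = 1e-4) {
  if (length(lower) == 1L)
    return(stats::pnorm(upper, sd = 1) - stats::pnorm(lower, sd = 1))
  corr <- psd_corr_(corr)
  run <- function(maxpts) {
    with_seed_(20240571L,
               mvtnorm::pmvnorm(lower = lower, upper = upper, corr = corr,
                                algorithm = mvtnorm::GenzBretz(
                                  abseps = abseps, maxpts = maxpts)))
  }
  res <- run(50000L)
  if (isTRUE(attr(res, "error") > err_tol)) {
    res <- run(500000L)
    if (isTRUE(attr(res, "error") > err_tol))
      warning("rectangle probability estimation error ",
              signif(attr(res, "error"), 2), " exceeds 1e-4")
  }
  min(max(as.numeric(res), 0), 1)
}

# Clip eigenvalues at 1e-8 and renormalize to a correlation matrix.
psd_corr_ <- function(R) {
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(ev$values) >= 1e-8) return(R)
  S <- ev$vectors %*% (pmax(ev$values, 1e-8) * t(ev$vectors))
  stats::cov2cor(S)
}

#' Combine the powered-score statistics into the adaptive test
#'
#' The finite power indices split into an odd and an even group; together
#' with the maximum statistic these three groups are asymptotically
#' independent under the null.  Within each finite group the most extreme
#' standardized statistic is referred to the multivariate-normal rectangle
#' probability implied by the correlation matrix \code{R}; the maximum
#' statistic uses its extreme-value tail.  The adaptive p-value is
#' \code{1 - (1 - p_min)^k} with \code{k} the number of groups present.
#'
#' @param moments a [null_moments()] object covering the finite indices.
#' @param stats named numeric vector of observed \code{L(gamma)} for the
#'   finite indices (names = gamma).
#' @param L_inf observed maximum statistic, or \code{NULL} if infinity is
#'   not in the candidate set.
#' @param p number of tested columns (needed for the extreme-value tail).
#' @return An object of class \code{"aispu_combination"}: a per-gamma table
#'   (statistic, z-score, p-value), the group p-values \code{p_O},
#'   \code{p_E}, \code{p_inf}, \code{p_min} and \code{p_aispu}.
#' @export
combine_aispu <- function(moments, stats, L_inf = NULL, p = NULL) {
  stopifnot(inherits(moments, "null_moments"))
  gam <- as.integer(names(stats))
  if (!all(gam %in% moments$gammas))
    stop("moments do not cover all finite power indices")
  idx <- match(gam, moments$gammas)
  z <- (as.numeric(stats) - moments$psi[idx]) / moments$omega[idx]
  pv <- ifelse(gam %% 2L == 1L, 2 * stats::pnorm(-abs(z)),
               stats::pnorm(z, lower.tail = FALSE))
  tab <- data.frame(gamma = gam, L = as.numeric(stats), z = z, p = pv)

  odd <- which(gam %% 2L == 1L); even <- which(gam %% 2L == 0L)
  p_O <- p_E <- p_inf <- NA_real_
  if (length(odd)) {
    t_O <- max(abs(z[odd]))
    R_O <- moments$R[idx[odd], idx[odd], drop = FALSE]
    p_O <- 1 - pmvnorm_seeded_(rep(-t_O, length(odd)),
                               rep(t_O, length(odd)), R_O)
  }
  if (length(even)) {
    t_E <- max(z[even])
    R_E <- moments$R[idx[even], idx[even], drop = FALSE]
    p_E <- 1 - pmvnorm_seeded_(rep(-Inf, length(even)),
                               rep(t_E, length(even)), R_E)
  }
  if (!is.null(L_inf)) {
    if (is.null(p)) stop("'p' is required when the maximum statistic is used")
    p_inf <- pvalue_inf(L_inf, p)
    tab <- rbind(tab, data.frame(gamma = Inf, L = L_inf,
                                 z = L_inf - (2 * log(p) - log(log(p))),
                                 p = p_inf))
  }
  groups <- c(p_O = p_O, p_E = p_E, p_inf = p_inf)
  present <- groups[!is.na(groups)]
  p_min <- min(present)
  k <- length(present)
  structure(list(per_gamma = tab, p_O = p_O, p_E = p_E, p_inf = p_inf,
                 p_min = p_min, k = k,
                 p_aispu = 1 - (1 - p_min)^k),
            class = "aispu_combination")
}

#' @export
print.aispu_combination <- function(x, ...) {
  print(x$per_gamma, row.names = FALSE)
  cat("group p-values: odd =", signif(x$p_O, 4), ", even =",
      signif(x$p_E, 4), ", max =", signif(x$p_inf, 4), "\n")
  cat("adaptive p-value:", signif(x$p_aispu, 4), "\n")
  invisible(x)
}

#' Asymptotic power of a single powered-score test (diagnostic)
#'
#' Local-alternative power approximation: with null moments
#' \code{(psi0, omega0)} and alternative moments \code{(psiA, omegaA)},
#' the power at level \code{alpha} is
#' \code{Phi((psiA - psi0 - z_alpha * omega0) / omegaA)} for even powers and
#' the two-sided analogue (with \code{z_{alpha/2}}) for odd powers.
#'
#' @param psiA,omegaA mean and standard deviation of the statistic under the
#'   alternative (\code{omegaA > 0}).
#' @param psi0,omega0 mean and standard deviation under the null.
#' @param gamma power index (only parity used).
#' @param alpha significance level in (0, 1).
#' @return the approximate power.
#' @export
theoretical_power <- function(psiA, psi0, omega0, omegaA, gamma,
                              alpha = 0.05) {
  if (omegaA <= 0) stop("'omegaA' must be positive")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  d <- psiA - psi0
  if (gamma %% 2 == 0) {
    stats::pnorm((d - stats::qnorm(1 - alpha) * omega0) / omegaA)
  } else {
    za <- stats::qnorm(1 - alpha / 2)
    stats::pnorm((d - za * omega0) / omegaA) +
      stats::pnorm((-d - za * omega0) / omegaA)
  }
}
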