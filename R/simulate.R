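#' Simulate genotypes from a dichotomized latent-Gaussian model
#'
#' Each haplotype is generated by thresholding a latent normal vector with
#' first-order autoregressive correlation (\code{rho^|k-j|} between markers
#' k and j): allele j carries the minor allele when the latent variable
#' falls below \code{qnorm(MAF_j)}, so the population allele frequency
#' equals the MAF exactly.  The genotype is the sum of two independent
#' haplotypes, giving values in \{0, 1, 2\} with marginal
#' Binomial(2, MAF_j).  Per-marker MAFs are drawn once per dataset from
#' \code{U(maf[1], maf[2])}.
#'
#' @param n number of subjects.
#' @param p number of markers.
#' @param rho latent AR(1) correlation, in [0, 1).
#' @param maf length-2 MAF sampling range, within (0, 0.5); use
#'   \code{c(0.1, 0.3)} for common variants, \code{c(0.005, 0.05)} for rare
#'   variants.
#' @param seed optional seed (caller's RNG state preserved).
#' @return an n x p integer-valued genotype matrix with attribute
#'   \code{"maf"}.
#' @export
simulate_genotypes <- function(n, p, rho = 0, maf = c(0.1, 0.3),
                               seed = NULL) {
  check_geno_cfg_(rho, maf)
  with_seed_(seed, {
    mafs <- runif(p, maf[1], maf[2])
    G <- gen_genotypes_(n, p, rho, qnorm(mafs))
    attr(G, "maf") <- mafs
    G
  })
}

check_geno_cfg_ <- function(rho, maf) {
  if (rho < 0 || rho >= 1) stop("'rho' must be in [0, 1)")
  if (length(maf) != 2L || maf[1] <= 0 || maf[2] >= 0.5 || maf[1] > maf[2])
    stop("'maf' must be an increasing range inside (0, 0.5)")
}

# Latent AR(1) haplotype pair; thr = qnorm(MAF) per marker.
gen_genotypes_ <- function(n, p, rho, thr) {
  one_hap <- function() {
    s <- matrix(rnorm(n * p), n, p)
    if (rho > 0 && p > 1L) {
      sq <- sqrt(1 - rho^2)
      for (j in 2:p) s[, j] <- rho * s[, j - 1L] + sq * s[, j]
    }
    sweep(s, 2L, thr, "<") * 1L
  }
  one_hap() + one_hap()
}

#' Simulate a case-control gene-environment interaction dataset
#'
#' Generates data from the logistic model
#' \deqn{logit P(Y = 1) = t0 + t1 Z1 + t2 Z2 + t3 E + t4' G + beta' (G x E),}
#' with \code{Z1} standard normal, \code{Z2 ~ Bernoulli(0.5)},
#' environmental exposure \code{E} in \{-1, +1\} equiprobable, genotypes
#' \code{G} from [simulate_genotypes()], genetic main effects \code{t4}
#' equal to +0.4 for the first \code{q1} markers, -0.4 for the next
#' \code{q2}, and 0 elsewhere, and interaction coefficients \code{beta}
#' with \code{floor(p * s)} nonzero entries at uniformly random positions
#' drawn from \code{U(-c, c)} (or \code{U(0, c)} under
#' \code{signs = "one_sided"}).  Subjects are sampled retrospectively:
#' prospective batches are generated and kept until exactly \code{n/2}
#' cases and \code{n/2} controls are retained.
#'
#' The default intercept and covariate effects are
#' \code{t0 = log(0.4/0.6)}, \code{t1 = 0.05}, \code{t2 = 0.057},
#' \code{t3 = 0.64}.  Setting \code{weak_z > 0} adds small
#' \code{U(weak_range)} main effects to that many additional randomly
#' chosen markers, emulating a dense-weak-background (omnigenic) violation
#' of the sparse-nuisance assumption.
#'
#' @param n number of subjects (even; n/2 cases, n/2 controls).
#' @param p number of markers.
#' @param q1,q2 counts of +0.4 / -0.4 genetic main effects.
#' @param s interaction sparsity: \code{floor(p * s)} nonzero interaction
#'   coefficients.
#' @param c interaction signal strength bound; \code{c = 0} gives a null
#'   dataset.
#' @param signs \code{"two_sided"} (U(-c, c)) or \code{"one_sided"}
#'   (U(0, c)).
#' @param rho,maf genotype generator controls, see [simulate_genotypes()].
#' @param theta intercept and covariate coefficients (t0, t1, t2, t3).
#' @param weak_z number of additional markers given weak main effects.
#' @param weak_range range of the weak main effects.
#' @param seed optional seed.
#' @param max_draw_factor abort if more than \code{max_draw_factor * n}
#'   prospective subjects are needed to fill the case/control quotas.
#' @return A list of class \code{"aispu_sim"}: outcome \code{y}, nuisance
#'   design \code{Z = [1, Z1, Z2, E, G]} (q = p + 4 columns), tested design
#'   \code{X = G * E}, true \code{beta}, full nuisance coefficient vector
#'   \code{theta}, \code{unpenalized = 1:4}, \code{oracle_support} (indices
#'   of truly nonzero nuisance coefficients) and the configuration.
#' @export
simulate_gxe <- function(n, p, q1 = 2L, q2 = 2L, s = 0.005, c = 0,
                         signs = c("two_sided", "one_sided"),
                         rho = 0, maf = c(0.1, 0.3),
                         theta = c(log(0.4 / 0.6), 0.05, 0.057, 0.64),
                         weak_z = 0L, weak_range = c(-0.01, 0.01),
                         seed = NULL, max_draw_factor = 1000) {
  signs <- match.arg(signs)
  if (n %% 2L != 0L) stop("'n' must be even (n/2 cases and n/2 controls)")
  if (q1 + q2 + weak_z > p) stop("q1 + q2 + weak_z must not exceed p")
  if (s < 0 || s > 1) stop("'s' must be in [0, 1]")
  if (c < 0) stop("'c' must be >= 0")
  check_geno_cfg_(rho, maf)
  with_seed_(seed, {
    mafs <- runif(p, maf[1], maf[2])
    thr <- qnorm(mafs)
    t4 <- c(rep(0.4, q1), rep(-0.4, q2), rep(0, p - q1 - q2))
    if (weak_z > 0L) {
      wk <- sample(which(t4 == 0), weak_z)
      t4[wk] <- runif(weak_z, weak_range[1], weak_range[2])
    }
    nsig <- floor(p * s)
    beta <- numeric(p)
    if (nsig > 0L && c > 0) {
      pos <- sample.int(p, nsig)
      beta[pos] <- if (signs == "two_sided") runif(nsig, -c, c)
                   else runif(nsig, 0, c)
    }

    half <- n %/% 2L
    keep_y <- integer(0); keep_Z <- NULL; keep_G <- NULL; keep_E <- numeric(0)
    drawn <- 0L
    need <- c(ctrl = half, case = half)
    while (any(need > 0L)) {
      nb <- max(n, 512L)
      drawn <- drawn + nb
      if (drawn > max_draw_factor * n)
        stop("case-control sampling exceeded the draw budget (",
             max_draw_factor, " * n); the model prevalence is too extreme")
      G <- gen_genotypes_(nb, p, rho, thr)
      Z1 <- rnorm(nb); Z2 <- rbinom(nb, 1L, 0.5)
      E <- ifelse(rbinom(nb, 1L, 0.5) == 1L, 1, -1)
      eta <- theta[1] + theta[2] * Z1 + theta[3] * Z2 + theta[4] * E +
        drop(G %*% t4) + drop((G * E) %*% beta)
      yb <- rbinom(nb, 1L, stats::plogis(eta))
      for (cls in c(0L, 1L)) {
        k <- need[cls + 1L]
        if (k == 0L) next
        idx <- which(yb == cls)
        idx <- idx[seq_len(min(k, length(idx)))]
        if (!length(idx)) next
        keep_y <- c(keep_y, yb[idx])
        keep_Z <- rbind(keep_Z, cbind(Z1[idx], Z2[idx]))
        keep_E <- c(keep_E, E[idx])
        keep_G <- rbind(keep_G, G[idx, , drop = FALSE])
        need[cls + 1L] <- k - length(idx)
      }
    }
    ord <- sample.int(n)   # shuffle cases/controls together
    y <- keep_y[ord]
    Zmat <- cbind(1, keep_Z[ord, 1L], keep_Z[ord, 2L], keep_E[ord],
                  keep_G[ord, , drop = FALSE])
    colnames(Zmat) <- c("(Intercept)", "Z1", "Z2", "E",
                        paste0("G", seq_len(p)))
    X <- keep_G[ord, , drop = FALSE] * keep_E[ord]
    colnames(X) <- paste0("GxE", seq_len(p))
    theta_full <- c(theta, t4)
    structure(list(
      y = y, Z = Zmat, X = X, beta = beta, theta = theta_full,
      unpenalized = 1:4,
      oracle_support = c(which(theta_full != 0)),
      config = list(model = "gxe", n = n, p = p, q1 = q1, q2 = q2, s = s,
                    c = c, signs = signs, rho = rho, maf = maf,
                    theta = theta, weak_z = weak_z,
                    weak_range = weak_range, seed = seed),
      maf = mafs
    ), class = "aispu_sim")
  })
}

#' Simulate a high-dimensional linear-model dataset
#'
#' Rows of the tested design X and the nuisance design are drawn from
#' mean-zero multivariate normals with block-diagonal covariance (blocks of
#' size \code{block_size} with compound-symmetric correlation
#' \code{block_rho}), and \code{Y = Z theta + X beta + eps} with standard
#' normal noise.  The nuisance coefficients default to
#' \code{theta = c(0.4, 0.4, 0, ...)}; \code{beta} has \code{floor(p * s)}
#' nonzero entries at uniformly random positions from \code{U(-c, c)} (or
#' \code{U(0, c)}).  The returned \code{Z} has an intercept column of ones
#' prepended (the fitted null model always carries an intercept), so it has
#' q + 1 columns.
#'
#' @param n,p,q sample size, tested dimension, nuisance dimension
#'   (defaults follow the high-dimensional regime n = 200,
#'   p = q = 1000).
#' @param s,c,signs sparsity and signal controls, as in [simulate_gxe()].
#' @param block_size,block_rho covariance-block controls.
#' @param theta values of the leading nuisance coefficients (the rest are
#'   zero).
#' @param seed optional seed.
#' @return A list of class \code{"aispu_sim"} with \code{y}, \code{Z}
#'   (n x (q + 1), first column the intercept), \code{X}, \code{beta},
#'   \code{theta} (length q + 1), \code{unpenalized = 1},
#'   \code{oracle_support} and the configuration.
#' @export
simulate_linear <- function(n = 200L, p = 1000L, q = 1000L, s = 0.005,
                            c = 0, signs = c("two_sided", "one_sided"),
                            block_size = 10L, block_rho = 0.3,
                            theta = c(0.4, 0.4), seed = NULL) {
  signs <- match.arg(signs)
  if (block_rho < 0 || block_rho >= 1) stop("'block_rho' must be in [0, 1)")
  if (length(theta) > q) stop("length(theta) must not exceed q")
  with_seed_(seed, {
    X <- block_normal_(n, p, block_size, block_rho)
    Zr <- block_normal_(n, q, block_size, block_rho)
    th <- c(theta, rep(0, q - length(theta)))
    nsig <- floor(p * s)
    beta <- numeric(p)
    if (nsig > 0L && c > 0) {
      pos <- sample.int(p, nsig)
      beta[pos] <- if (signs == "two_sided") runif(nsig, -c, c)
                   else runif(nsig, 0, c)
    }
    y <- drop(Zr %*% th) + drop(X %*% beta) + rnorm(n)
    Zmat <- cbind(1, Zr)
    colnames(Zmat) <- c("(Intercept)", paste0("Z", seq_len(q)))
    colnames(X) <- paste0("X", seq_len(p))
    theta_full <- c(0, th)
    structure(list(
      y = y, Z = Zmat, X = X, beta = beta, theta = theta_full,
      unpenalized = 1L,
      oracle_support = which(theta_full != 0),
      config = list(model = "linear", n = n, p = p, q = q, s = s, c = c,
                    signs = signs, block_size = block_size,
                    block_rho = block_rho, theta = theta, seed = seed)
    ), class = "aispu_sim")
  })
}

# n x p draw with block-diagonal compound-symmetric covariance.
block_normal_ <- function(n, p, block_size, block_rho) {
  if (block_rho == 0 || block_size <= 1L) return(matrix(rnorm(n * p), n, p))
  M <- matrix(NA_real_, n, p)
  start <- 1L
  chol_cache <- list()
  while (start <= p) {
    b <- min(block_size, p - start + 1L)
    key <- as.character(b)
    if (is.null(chol_cache[[key]])) {
      S <- matrix(block_rho, b, b); diag(S) <- 1
      chol_cache[[key]] <- chol(S)
    }
    M[, start:(start + b - 1L)] <-
      matrix(rnorm(n * b), n, b) %*% chol_cache[[key]]
    start <- start + b
  }
  M
}

#' @export
print.aispu_sim <- function(x, ...) {
  cfg <- x$config
  cat("Simulated dataset (", cfg$model, "): n = ", cfg$n, ", p = ", cfg$p,
      ", nonzero beta = ", sum(x$beta != 0), "\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to delimited files
#'
#' Writes \code{y.csv}, \code{Z.csv}, \code{X.csv} and \code{beta_true.csv}
#' plus a \code{config.json} sidecar recording the full generator
#' configuration and seed.
#'
#' @param sim an \code{"aispu_sim"} object.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "aispu_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(data.frame(y = sim$y),
                   file.path(dir, "y.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(sim$Z),
                   file.path(dir, "Z.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(sim$X),
                   file.path(dir, "X.csv"), row.names = FALSE)
  utils::write.csv(data.frame(beta = sim$beta),
                   file.path(dir, "beta_true.csv"), row.names = FALSE)
  jsonlite::write_json(sim$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a delimited design matrix
#'
#' Thin reader for CSV/TSV inputs: the delimiter is inferred from the file
#' extension (.tsv/.txt use tab) and the result is returned as a numeric
#' matrix.
#'
#' @param path file path.
#' @param header does the file carry a header row?
#' @return a numeric matrix.
#' @export
read_design <- function(path, header = TRUE) {
  df <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    utils::read.delim(path, header = header)
  } else {
    utils::read.csv(path, header = header)
  }
  as.matrix(df)
}
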