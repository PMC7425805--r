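#' Univariate minimum-p interaction test (baseline)
#'
#' For each marker j, fits the GLM of the outcome on the low-dimensional
#' adjustment covariates, the marker main effect and the marker-by-exposure
#' interaction, records the Wald p-value of the interaction term, and
#' returns the Bonferroni-adjusted minimum: \code{min(1, p * min_j p_j)}.
#' A marker whose fit fails (e.g. separation) gets p-value 1 and is counted
#' in the \code{"n_failed"} attribute.
#'
#' @param y outcome vector.
#' @param Z_low low-dimensional adjustment design (n x q0), including an
#'   intercept column.
#' @param G genotype matrix (n x p).
#' @param E exposure vector (length n).
#' @param family GLM family.
#' @return the Bonferroni-adjusted p-value, with attributes
#'   \code{"per_snp"} (the p per-marker p-values) and \code{"n_failed"}.
#' @export
uminp_test <- function(y, Z_low, G, E, family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  Z_low <- check_matrix_(Z_low, "Z_low")
  G <- check_matrix_(G, "G")
  y <- as.numeric(y); E <- as.numeric(E)
  n <- length(y); p <- ncol(G)
  if (nrow(Z_low) != n || nrow(G) != n || length(E) != n)
    stop("dimensions do not conform")
  fam <- if (family == "binomial") binomial() else gaussian()
  pj <- rep(1, p)
  failed <- 0L
  for (j in seq_len(p)) {
    x <- cbind(Z_low, G[, j], G[, j] * E)
    pj[j] <- tryCatch({
      g <- suppressWarnings(stats::glm.fit(x, y, family = fam))
      w <- g$weights
      XtWX <- crossprod(x * sqrt(w))
      V <- chol2inv(chol(XtWX))
      phi <- if (family == "gaussian")
        sum(g$residuals^2 * w) / g$df.residual else 1
      se <- sqrt(phi * V[ncol(x), ncol(x)])
      zstat <- g$coefficients[ncol(x)] / se
      if (!is.finite(zstat)) stop("non-finite Wald statistic")
      2 * stats::pnorm(-abs(zstat))
    }, error = function(e) { failed <<- failed + 1L; 1 })
  }
  out <- min(1, p * min(pj))
  attr(out, "per_snp") <- pj
  attr(out, "n_failed") <- failed
  out
}

#' Run a size/power simulation experiment
#'
#' Generates \code{reps} datasets from one of the built-in simulators, runs
#' every requested method on each dataset (all methods see the same data:
#' paired comparisons with lower Monte-Carlo variance), and tabulates the
#' empirical rejection proportion at level \code{alpha} with its
#' Monte-Carlo standard error \code{sqrt(phat (1 - phat) / reps)}.
#' Per-replicate seeds are derived deterministically from \code{seed}, so
#' an identical specification reproduces an identical table.  For the
#' adaptive methods the per-gamma test p-values are tabulated as well
#' (columns \code{<method>.ispu<gamma>}).  A method erroring on a replicate
#' is recorded as NA and excluded from its denominator, with the failure
#' count reported.
#'
#' @param generator \code{"gxe"} or \code{"linear"}.
#' @param config named list of arguments for [simulate_gxe()] or
#'   [simulate_linear()] (without \code{seed}).
#' @param methods character subset of \code{"aispu_tlp"},
#'   \code{"aispu_lasso"}, \code{"aispu_ridge"}, \code{"aispu_full"},
#'   \code{"aispu_oracle"}, \code{"uminp"}.
#' @param reps number of replicate datasets.
#' @param alpha significance level.
#' @param pvalue p-value route for the adaptive methods.
#' @param B bootstrap replicates (bootstrap route only).
#' @param gamma candidate power indices.
#' @param refit bootstrap refit policy.
#' @param moment_backend null-moment backend for the asymptotic route, see
#'   [aispu()].
#' @param seed master seed.
#' @param verbose print a progress line every 25 replicates.
#' @return A list of class \code{"aispu_experiment"}: the rejection
#'   \code{table} (method, rejection proportion, MC standard error, reps
#'   used, failures) and the full \code{pvalues} matrix.
#' @export
run_experiment <- function(generator = c("gxe", "linear"), config = list(),
                           methods = "aispu_tlp", reps = 1000L,
                           alpha = 0.05,
                           pvalue = c("asymptotic", "bootstrap"),
                           B = 500L, gamma = c(1:6, Inf),
                           refit = c("coefficients", "none"),
                           moment_backend = c("bootstrap", "gaussian"),
                           seed = 1L, verbose = FALSE) {
  generator <- match.arg(generator)
  pvalue <- match.arg(pvalue)
  refit <- match.arg(refit)
  moment_backend <- match.arg(moment_backend)
  known <- c("aispu_tlp", "aispu_lasso", "aispu_ridge", "aispu_full",
             "aispu_oracle", "uminp")
  if (!all(methods %in% known))
    stop("unknown method(s): ", paste(setdiff(methods, known), collapse = ", "))
  reps <- as.integer(reps)
  if (reps < 1L) stop("'reps' must be >= 1")
  rep_seeds <- with_seed_(seed, sample.int(2147483646L, reps))

  cols <- character(0)
  for (m in methods) {
    cols <- c(cols, m)
    if (startsWith(m, "aispu_"))
      cols <- c(cols, paste0(m, ".ispu", gamma))
  }
  P <- matrix(NA_real_, reps, length(cols), dimnames = list(NULL, cols))

  for (r in seq_len(reps)) {
    sim <- do.call(if (generator == "gxe") simulate_gxe else simulate_linear,
                   c(config, list(seed = rep_seeds[r])))
    fam <- if (generator == "gxe") "binomial" else "gaussian"
    for (m in methods) {
      res <- tryCatch({
        if (m == "uminp") {
          if (generator != "gxe")
            stop("uminp is defined for the gene-environment design")
          pv <- uminp_test(sim$y, sim$Z[, 1:4, drop = FALSE],
                           sim$Z[, -(1:4), drop = FALSE], sim$Z[, 4L],
                           family = fam)
          as.numeric(pv)
        } else {
          pen <- sub("aispu_", "", m)
          ft <- aispu(sim$y, sim$Z, sim$X, family = fam, gamma = gamma,
                      method = pvalue, penalty = pen,
                      unpenalized = sim$unpenalized,
                      oracle_support = if (pen == "oracle")
                        sim$oracle_support else NULL,
                      B = B, refit = refit,
                      moment_backend = moment_backend,
                      seed = child_seed_(rep_seeds[r], 7L))
          c(ft$p_aispu, ft$per_gamma$p)
        }
      }, error = function(e) NULL)
      if (!is.null(res)) {
        tgt <- if (m == "uminp") m else c(m, paste0(m, ".ispu", gamma))
        P[r, tgt] <- res
      }
    }
    if (verbose && r %% 25L == 0L)
      message("replicate ", r, "/", reps)
  }

  tab <- data.frame(
    method = cols,
    reject = NA_real_, se = NA_real_,
    reps_used = NA_integer_, failures = NA_integer_,
    stringsAsFactors = FALSE)
  for (i in seq_along(cols)) {
    pv <- P[, i]
    ok <- !is.na(pv)
    tab$reps_used[i] <- sum(ok)
    tab$failures[i] <- sum(!ok)
    if (any(ok)) {
      ph <- mean(pv[ok] <= alpha)
      tab$reject[i] <- ph
      tab$se[i] <- sqrt(ph * (1 - ph) / sum(ok))
    }
  }
  structure(list(table = tab, pvalues = P, alpha = alpha,
                 spec = list(generator = generator, config = config,
                             methods = methods, reps = reps, alpha = alpha,
                             pvalue = pvalue, B = B, gamma = gamma,
                             refit = refit,
                             moment_backend = moment_backend,
                             seed = seed)),
            class = "aispu_experiment")
}

#' @export
print.aispu_experiment <- function(x, ...) {
  cat("Rejection proportions at alpha =", x$alpha, "(", x$spec$reps,
      "replicates,", x$spec$pvalue, "p-values )\n")
  tab <- x$table
  tab$reject <- round(tab$reject, 4)
  tab$se <- signif(tab$se, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
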