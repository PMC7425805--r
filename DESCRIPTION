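Package: aispu
Title: Adaptive Sum of Powered Score Tests for High-Dimensional
    Generalized Linear Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests a high-dimensional regression coefficient vector in a
    generalized linear model in the presence of a high-dimensional nuisance
    parameter, as arises in set-based gene-environment interaction testing.
    The nuisance parameter is estimated under the null by penalized
    regression with the non-convex truncated Lasso penalty (TLP), solved by
    difference-of-convex iterations over weighted-Lasso subproblems. On top
    of the fitted null, the package computes the family of interaction
    sum-of-powered-score statistics iSPU(gamma) (including the standardized
    maximum statistic for gamma = infinity) and combines them into the
    adaptive aiSPU test, with p-values available both from the asymptotic
    joint null distribution (normal limits for finite gamma, a Gumbel-type
    extreme-value limit for the maximum, and the asymptotic independence of
    the odd, even and infinite power groups) and from a parametric
    bootstrap. Includes simulators for case-control gene-environment
    designs with latent-Gaussian genotypes and for block-correlated
    high-dimensional linear models, plus a reproducible size/power
    experiment harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    mvtnorm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
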