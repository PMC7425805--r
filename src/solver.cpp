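// Penalized GLM solver used for the null-model fit.
//
// The truncated Lasso penalty TLP(x, tau) = min(|x|, tau) is handled by
// difference-of-convex (DC) iterations: at each DC step the concave part is
// linearized, leaving a weighted-Lasso GLM with per-coefficient weight
// 1{|theta_j| < tau}, solved by coordinate descent with an IRLS outer loop
// for the binomial family.  Everything lives in C++ because cross-validation
// and the parametric bootstrap need thousands of warm-started single-lambda
// refits where per-call R overhead would dominate.
//
// Design columns are assumed standardized by the R wrapper; penalty factors
// of exactly zero mark unpenalized columns (intercept etc.).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// lightweight instrumentation (sweep accounting)
static long g_full_sweeps = 0, g_act_sweeps = 0, g_wlasso_calls = 0;
// [[Rcpp::export]]
Rcpp::NumericVector solver_counters_(bool reset = false) {
  Rcpp::NumericVector out = Rcpp::NumericVector::create(
      (double) g_full_sweeps, (double) g_act_sweeps, (double) g_wlasso_calls);
  if (reset) { g_full_sweeps = g_act_sweeps = g_wlasso_calls = 0; }
  return out;
}

static inline double soft_thresh(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

static inline double softplus_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return 0.0;
  return std::log1p(std::exp(x));
}

// mean negative log-likelihood (family 0 = gaussian, 1 = binomial-logit)
static double glm_nll(const mat& Z, const vec& y, const vec& b, int family) {
  vec eta = Z * b;
  const double n = (double) Z.n_rows;
  if (family == 0) {
    vec r = y - eta;
    return 0.5 * dot(r, r) / n;
  }
  double s = 0.0;
  for (uword i = 0; i < eta.n_elem; ++i)
    s += softplus_(eta(i)) - y(i) * eta(i);
  return s / n;
}

static double tlp_penalty_sum(const vec& b, const vec& pf, double tau) {
  double s = 0.0;
  for (uword j = 0; j < b.n_elem; ++j)
    if (pf(j) > 0.0) s += pf(j) * std::min(std::abs(b(j)), tau);
  return s;
}

// Coordinate descent for the weighted quadratic
//   (1/(2n)) sum_i w_i (zw_i - Z_i b)^2 + lam * sum_j pf_j |b_j|
// r holds the working residual zw - Z b; Zw = Z with columns scaled by w.
// Active-set strategy: full sweep, then sweeps over nonzero/unpenalized
// coefficients until stable, then a full KKT sweep to confirm.
static void cd_quadratic(const mat& Z, const mat& Zw, const vec& a,
                         const vec& pf, double lam, vec& b, vec& r,
                         double tol, int max_full_sweeps) {
  const uword q = Z.n_cols;
  const double n = (double) Z.n_rows;
  auto update_j = [&](uword j, double& maxch) {
    double g = dot(Zw.unsafe_col(j), r) / n + a(j) * b(j);
    double bn = soft_thresh(g, lam * pf(j)) / a(j);
    double d = bn - b(j);
    if (d != 0.0) {
      r -= d * Z.unsafe_col(j);
      b(j) = bn;
      double ad = std::abs(d);
      if (ad > maxch) maxch = ad;
    }
  };
  std::vector<uword> act;
  act.reserve(64);
  for (int outer = 0; outer < max_full_sweeps; ++outer) {
    // converge on the current active set (nonzero or unpenalized), then
    // check the KKT conditions for all coordinates with one BLAS
    // matrix-vector product, fixing up any violators; stop when quiet
    act.clear();
    for (uword j = 0; j < q; ++j)
      if (a(j) > 0.0 && (b(j) != 0.0 || pf(j) == 0.0)) act.push_back(j);
    for (int it = 0; it < 50; ++it) {
      ++g_act_sweeps;
      double mc = 0.0;
      for (uword j : act) update_j(j, mc);
      if (mc < tol) break;
    }
    ++g_full_sweeps;
    vec grad = Zw.t() * r;   // stale after each fix-up, which is fine:
                             // remaining violators re-enter the next round
    double maxch = 0.0;
    for (uword j = 0; j < q; ++j) {
      if (a(j) <= 0.0) continue;
      double g = grad(j) / n + a(j) * b(j);
      double bn = soft_thresh(g, lam * pf(j)) / a(j);
      if (std::abs(bn - b(j)) > tol) update_j(j, maxch);
    }
    if (maxch < tol) break;
  }
}

// Logistic Lasso by majorized coordinate descent: the curvature is bounded
// by 1/4 (the maximum Bernoulli variance), so each coordinate uses the
// fixed majorant a_j = mean(z_j^2)/4 and the exact gradient.  eta and the
// raw residual v = y - mu are maintained incrementally (with the Bernoulli
// weights frozen within a sweep and refreshed after it), so a sweep costs
// O(n) per visited coefficient with no per-iteration matrix builds.  A
// fixed point satisfies the exact penalized-likelihood KKT conditions.
// returns false if the fit diverged (a free coefficient escaping toward
// separation); the caller should discard the solution
static bool cd_binomial(const mat& Z, const vec& y, const vec& pf,
                        double lam, vec& b, double tol,
                        int max_full_sweeps) {
  const uword q = Z.n_cols;
  const double n = (double) Z.n_rows;
  vec asq = (sum(square(Z), 0) / (4.0 * n)).t();
  vec eta = Z * b;
  vec mu(y.n_elem), w(y.n_elem), v(y.n_elem);
  auto refresh = [&]() {
    eta = clamp(eta, -30.0, 30.0);
    mu = 1.0 / (1.0 + exp(-eta));
    w = mu % (1.0 - mu);
    v = y - mu;
  };
  refresh();
  auto update_j = [&](uword j, double& maxch) {
    double g = dot(Z.unsafe_col(j), v) / n + asq(j) * b(j);
    double bn = soft_thresh(g, lam * pf(j)) / asq(j);
    double d = bn - b(j);
    if (d != 0.0) {
      b(j) = bn;
      eta += d * Z.unsafe_col(j);
      v -= d * (w % Z.unsafe_col(j));
      double ad = std::abs(d);
      if (ad > maxch) maxch = ad;
    }
  };
  // a standardized logistic coefficient this large is a separation
  // artefact, not a fit: bail out instead of grinding toward the clamp
  const double b_cap = 15.0;
  // the free (unpenalized or released) block is smooth: solve it by IRLS
  // Newton steps, which removes the slow cyclic-descent coupling between
  // correlated free columns (intercept, covariates, exposure)
  uvec freeidx = find(pf == 0.0);
  freeidx = freeidx(find(asq(freeidx) > 0.0));
  mat Zf;
  if (freeidx.n_elem > 0) Zf = Z.cols(freeidx);
  auto newton_free = [&](double& maxch) {
    const uword f = freeidx.n_elem;
    if (f == 0) return;
    mat H = Zf.t() * (Zf.each_col() % w) / n;
    vec gr = Zf.t() * v / n;
    vec delta;
    if (!solve(delta, H, gr, solve_opts::likely_sympd + solve_opts::no_approx))
      return;
    double mx = max(abs(delta));
    if (!std::isfinite(mx)) return;
    if (mx > 2.0) delta *= 2.0 / mx;   // damp early overshoot
    for (uword k = 0; k < f; ++k) b(freeidx(k)) += delta(k);
    eta += Zf * delta;
    refresh();
    if (mx > maxch) maxch = mx;
  };
  auto mean_nll = [&]() {
    double s = 0.0;
    for (uword i = 0; i < y.n_elem; ++i)
      s += softplus_(eta(i)) - y(i) * eta(i);
    return s / n;
  };
  std::vector<uword> act;
  act.reserve(64);
  double nll_outer = datum::inf;
  for (int outer = 0; outer < max_full_sweeps; ++outer) {
    // active set first, full sweep as the KKT check
    act.clear();
    for (uword j = 0; j < q; ++j)
      if (asq(j) > 0.0 && (b(j) != 0.0 || pf(j) == 0.0)) act.push_back(j);
    double nll_chk = datum::inf;
    for (int it = 0; it < 25; ++it) {
      ++g_act_sweeps;
      double mc = 0.0;
      // a couple of Newton applications settle the free block; afterwards
      // the cheap coordinate updates keep it current
      if (it < 2 || it % 8 == 7) {
        newton_free(mc);
        for (uword j : act) {
          if (pf(j) == 0.0) continue;
          update_j(j, mc);
        }
      } else {
        for (uword j : act) update_j(j, mc);
      }
      refresh();
      if (mc < tol) break;
      if (it % 4 == 3) {
        if (max(abs(b)) > b_cap) return false;
        // likelihood progress has stalled (a crawling near-separation
        // direction): accept the iterate instead of burning sweeps
        double cur = mean_nll();
        if (nll_chk - cur < 1e-6) break;
        nll_chk = cur;
      }
    }
    if (max(abs(b)) > b_cap) return false;
    ++g_full_sweeps;
    vec grad = Z.t() * v;    // one BLAS product for the full KKT check
    double maxch = 0.0;
    for (uword j = 0; j < q; ++j) {
      if (asq(j) <= 0.0) continue;
      double g = grad(j) / n + asq(j) * b(j);
      double bn = soft_thresh(g, lam * pf(j)) / asq(j);
      if (std::abs(bn - b(j)) > tol) update_j(j, maxch);
    }
    refresh();
    if (maxch < tol) break;
    double cur = mean_nll();
    if (nll_outer - cur < 1e-6) break;
    nll_outer = cur;
  }
  return true;
}

// Weighted-Lasso GLM at a single lambda; b is updated in place (warm
// start).  Returns false if the fit diverged (binomial separation).
static bool glm_wlasso(const mat& Z, const vec& y, const vec& pf, double lam,
                       int family, vec& b, double tol, int irls_max,
                       int max_full_sweeps) {
  ++g_wlasso_calls;
  const double n = (double) Z.n_rows;
  if (family == 0) {
    vec a = (sum(square(Z), 0) / n).t();
    vec r = y - Z * b;
    cd_quadratic(Z, Z, a, pf, lam, b, r, tol, max_full_sweeps);
    return true;
  }
  (void) irls_max;   // the majorized scheme has no separate outer loop
  return cd_binomial(Z, y, pf, lam, b, tol, max_full_sweeps);
}

// DC loop for TLP at a single (lambda, tau).  Returns true if converged;
// b is replaced by the best (lowest-objective) iterate.  trace (optional)
// collects the penalized objective at the initial point and after each DC
// step.
// status: 0 converged, 1 iteration cap reached (best iterate usable),
// 2 unidentifiable subproblem (grid point should be discarded)
static int dc_tlp(const mat& Z, const vec& y, const vec& pf, double lambda,
                  double tau, int family, vec& b, double tol, int dc_maxit,
                  int irls_max, std::vector<double>* trace,
                  int max_sweeps = 50) {
  auto objective = [&](const vec& bb) {
    return glm_nll(Z, y, bb, family) + lambda * tlp_penalty_sum(bb, pf, tau);
  };
  double obj = objective(b);
  if (trace) trace->push_back(obj);
  vec best = b;
  double best_obj = obj;
  bool conv = false;
  const double dc_tol = std::max(1e-6, 10.0 * tol);
  vec pfw(pf.n_elem), pfw_prev(pf.n_elem, fill::value(-1.0));
  // a weighted-Lasso subproblem with more free (unpenalized) coefficients
  // than half the sample is unidentifiable (separation for the binomial
  // family): declare non-convergence instead of grinding on it
  const uword free_cap = Z.n_rows / 2;
  for (int m = 0; m < dc_maxit; ++m) {
    uword nfree = 0;
    for (uword j = 0; j < pf.n_elem; ++j) {
      pfw(j) = (std::abs(b(j)) < tau) ? pf(j) : 0.0;
      if (pfw(j) == 0.0) ++nfree;
    }
    if (nfree > free_cap) { b = best; return 2; }
    // once the release pattern repeats, the subproblem is the one already
    // solved at the previous step: the DC sequence has stabilized
    if (m > 0 && all(pfw == pfw_prev)) { conv = true; break; }
    pfw_prev = pfw;
    vec bnew = b;
    if (!glm_wlasso(Z, y, pfw, lambda, family, bnew, tol, irls_max,
                    max_sweeps)) {
      b = best;
      return 2;
    }
    double onew = objective(bnew);
    if (trace) trace->push_back(onew);
    double gain = best_obj - onew;
    if (onew < best_obj) { best_obj = onew; best = bnew; }
    double ch = max(abs(bnew - b));
    b = bnew;
    if (ch < dc_tol) { conv = true; break; }
    // boundary oscillation: the release pattern keeps flipping but the
    // objective no longer improves -- treat as converged at the best iterate
    if (m > 0 && gain < 1e-8 * std::max(1.0, std::abs(best_obj))) {
      conv = true; break;
    }
  }
  b = best;
  return conv ? 0 : 1;
}

// [[Rcpp::export]]
Rcpp::List glm_wlasso_cpp(const arma::mat& Z, const arma::vec& y,
                          const arma::vec& pf, double lambda, int family,
                          arma::vec beta, double tol = 1e-7,
                          int irls_max = 25) {
  glm_wlasso(Z, y, pf, lambda, family, beta, tol, irls_max, 100);
  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("nll") = glm_nll(Z, y, beta, family));
}

// [[Rcpp::export]]
arma::mat lasso_path_cpp(const arma::mat& Z, const arma::vec& y,
                         const arma::vec& pf, const arma::vec& lambdas,
                         int family, double tol = 1e-7, int irls_max = 25) {
  const uword q = Z.n_cols, L = lambdas.n_elem;
  mat B(q, L, fill::zeros);
  vec b(q, fill::zeros);
  for (uword l = 0; l < L; ++l) {
    glm_wlasso(Z, y, pf, lambdas(l), family, b, tol, irls_max, 50);
    B.col(l) = b;
  }
  return B;
}

// [[Rcpp::export]]
Rcpp::List tlp_fit_cpp(const arma::mat& Z, const arma::vec& y,
                       const arma::vec& pf, double lambda, double tau,
                       int family, arma::vec beta, double tol = 1e-7,
                       int dc_maxit = 50, int irls_max = 25) {
  std::vector<double> trace;
  int status = dc_tlp(Z, y, pf, lambda, tau, family, beta, tol, dc_maxit,
                      irls_max, &trace);
  return Rcpp::List::create(
      Rcpp::Named("beta") = beta,
      Rcpp::Named("objective") = trace,
      Rcpp::Named("converged") = (status == 0),
      Rcpp::Named("status") = status,
      Rcpp::Named("nll") = glm_nll(Z, y, beta, family));
}

// Cross-validation over a (lambda, tau) grid.  foldid has values in 1..K.
// Returns the summed out-of-fold deviance for each grid point plus a count
// of folds whose DC loop failed to converge and a non-finite flag.
// [[Rcpp::export]]
Rcpp::List cv_tlp_cpp(const arma::mat& Z, const arma::vec& y,
                      const arma::vec& pf, const arma::vec& lambdas,
                      const arma::vec& taus, const arma::ivec& foldid,
                      int family, double tol = 1e-6, int dc_maxit = 20,
                      int irls_max = 20, int window_up = 6,
                      int window_down = 3) {
  const uword q = Z.n_cols, L = lambdas.n_elem, T = taus.n_elem;
  const int K = foldid.max();
  mat dev(L, T, fill::zeros);
  cube dev_fold(L, T, K, fill::zeros);
  imat nonconv(L, T, fill::zeros);

  auto oof_dev = [&](const mat& Zte, const vec& yte, const vec& b) {
    vec eta = Zte * b;
    if (family == 0) {
      vec r = yte - eta;
      return dot(r, r);
    }
    double d = 0.0;
    for (uword i = 0; i < eta.n_elem; ++i)
      d += 2.0 * (softplus_(eta(i)) - yte(i) * eta(i));
    return d;
  };

  // pass 1: per-fold Lasso paths (the DC initializers) and their
  // out-of-fold deviance, used to screen the lambda grid: the TLP refinement
  // only needs to explore a window around the convex-relaxation optimum
  std::vector<mat> paths(K);
  std::vector<uvec> test_sets(K), train_sets(K);
  vec lasso_dev(L, fill::zeros);
  for (int k = 1; k <= K; ++k) {
    test_sets[k - 1] = find(foldid == k);
    train_sets[k - 1] = find(foldid != k);
    mat Ztr = Z.rows(train_sets[k - 1]);
    vec ytr = y(train_sets[k - 1]);
    mat Zte = Z.rows(test_sets[k - 1]);
    vec yte = y(test_sets[k - 1]);
    mat Blasso(q, L);
    vec b(q, fill::zeros);
    double nll0 = glm_nll(Ztr, ytr, b, family);
    for (uword l = 0; l < L; ++l) {
      glm_wlasso(Ztr, ytr, pf, lambdas(l), family, b, tol, irls_max, 6);
      Blasso.col(l) = b;
      if (family == 1 && l + 1 < L &&
          glm_nll(Ztr, ytr, b, family) < 0.1 * nll0) {
        for (uword l2 = l + 1; l2 < L; ++l2) Blasso.col(l2) = b;
        break;
      }
    }
    for (uword l = 0; l < L; ++l)
      lasso_dev(l) += oof_dev(Zte, yte, Blasso.col(l));
    paths[k - 1] = Blasso;
  }
  // asymmetric window: lambdas are decreasing, and the one-standard-error
  // selection rule lives on the larger-lambda (smaller-index) side of the
  // convex-relaxation minimum
  uword lbest = lasso_dev.index_min();
  uword lo = (lbest >= (uword) window_up) ? lbest - window_up : 0;
  uword hi = std::min(L - 1, lbest + (uword) window_down);
  if (window_up < 0 || window_down < 0) { lo = 0; hi = L - 1; }

  // pass 2: DC refinement over the screened lambda window and the full tau
  // grid, warm-started pathwise; unscreened cells are marked unevaluated
  for (uword t = 0; t < T; ++t)
    for (uword l = 0; l < L; ++l)
      if (l < lo || l > hi) dev(l, t) = datum::nan;
  for (int k = 1; k <= K; ++k) {
    mat Ztr = Z.rows(train_sets[k - 1]);
    vec ytr = y(train_sets[k - 1]);
    mat Zte = Z.rows(test_sets[k - 1]);
    vec yte = y(test_sets[k - 1]);
    const mat& Blasso = paths[k - 1];
    for (uword t = 0; t < T; ++t) {
      vec bwarm;
      bool have_warm = false;
      for (uword l = lo; l <= hi; ++l) {
        vec b = have_warm ? bwarm : Blasso.col(l);
        int status = dc_tlp(Ztr, ytr, pf, lambdas(l), taus(t), family, b,
                            tol, dc_maxit, irls_max, nullptr, 4);
        if (status != 0) nonconv(l, t) += 1;
        if (status == 2) {   // unidentifiable: discard this grid point
          dev(l, t) = datum::inf;
          have_warm = false;
          continue;
        }
        bwarm = b; have_warm = true;
        double d = oof_dev(Zte, yte, b);
        dev(l, t) += d;
        dev_fold(l, t, k - 1) = d / (double) yte.n_elem;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("deviance") = dev,
                            Rcpp::Named("deviance_fold") = dev_fold,
                            Rcpp::Named("nonconv") = nonconv,
                            Rcpp::Named("lasso_deviance") = lasso_dev,
                            Rcpp::Named("lambda_window") =
                              Rcpp::IntegerVector::create(lo + 1, hi + 1));
}

// Refit the TLP null model on B simulated outcome vectors (columns of Ymat),
// all at the same frozen (lambda, tau), warm-started from beta_init.
// Returns the n x B matrix of fitted null means.
// [[Rcpp::export]]
arma::mat tlp_refit_many_cpp(const arma::mat& Z, const arma::mat& Ymat,
                             const arma::vec& pf, double lambda, double tau,
                             int family, const arma::vec& beta_init,
                             double tol = 1e-6, int dc_maxit = 20,
                             int irls_max = 20) {
  const uword n = Z.n_rows, B = Ymat.n_cols;
  mat mu(n, B);
  for (uword bb = 0; bb < B; ++bb) {
    vec b = beta_init;
    vec yb = Ymat.col(bb);
    dc_tlp(Z, yb, pf, lambda, tau, family, b, tol, dc_maxit, irls_max,
           nullptr, 6);
    vec eta = Z * b;
    if (family == 0) {
      mu.col(bb) = eta;
    } else {
      mu.col(bb) = 1.0 / (1.0 + exp(-clamp(eta, -30.0, 30.0)));
    }
  }
  return mu;
}
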