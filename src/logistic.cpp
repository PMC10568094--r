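// Logistic IRLS fitter and per-variant association scans.
//
// The evaluation and experiment machinery refits thousands of logistic models
// (one per variant per scan, times dozens of scans for the noise and
// training-size experiments), so the inner loop lives here rather than in R.
// Non-convergence / separation is handled by a ridge fallback (penalty 1e-6,
// "capped" flag) so small or separated folds still return a usable,
// penalized likelihood.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double ETA_CLAMP = 30.0;

struct FitResult {
  arma::vec coef;
  arma::vec se;
  double loglik;
  bool converged;
  bool capped;
};

static double binom_loglik(const arma::vec& eta, const arma::vec& y) {
  // log L = sum y*eta - log(1 + exp(eta)), computed stably
  double ll = 0.0;
  for (arma::uword i = 0; i < eta.n_elem; ++i) {
    double e = eta[i];
    double lse = (e > 0) ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
    ll += y[i] * e - lse;
  }
  return ll;
}

static FitResult irls(const arma::mat& X, const arma::vec& y,
                      const arma::vec& start, double ridge,
                      int max_iter, double tol) {
  const arma::uword p = X.n_cols;
  arma::vec beta = start;
  bool converged = false;
  arma::mat XtWX(p, p);
  for (int it = 0; it < max_iter; ++it) {
    arma::vec eta = arma::clamp(X * beta, -ETA_CLAMP, ETA_CLAMP);
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = mu % (1.0 - mu);
    w.transform([](double v) { return (v < 1e-10) ? 1e-10 : v; });
    arma::vec z = eta + (y - mu) / w;
    arma::mat Xw = X.each_col() % w;
    XtWX = X.t() * Xw;
    if (ridge > 0) XtWX.diag() += ridge;
    arma::vec rhs = X.t() * (w % z);
    arma::vec beta_new;
    bool ok = arma::solve(beta_new, XtWX, rhs, arma::solve_opts::no_approx);
    if (!ok) { converged = false; break; }
    double delta = arma::abs(beta_new - beta).max();
    beta = beta_new;
    if (delta < tol) { converged = true; break; }
  }
  if (arma::abs(beta).max() > 20.0) converged = false;  // quasi-separation
  FitResult res;
  res.coef = beta;
  res.converged = converged;
  res.capped = false;
  arma::vec eta = arma::clamp(X * beta, -ETA_CLAMP, ETA_CLAMP);
  res.loglik = binom_loglik(eta, y) - 0.5 * ridge * arma::dot(beta, beta);
  arma::mat cov;
  if (arma::inv_sympd(cov, XtWX)) {
    res.se = arma::sqrt(cov.diag());
  } else {
    res.se = arma::vec(p, arma::fill::value(NA_REAL));
  }
  return res;
}

static FitResult fit_with_fallback(const arma::mat& X, const arma::vec& y,
                                   const arma::vec& start,
                                   int max_iter, double tol, double ridge_fallback) {
  FitResult res = irls(X, y, start, 0.0, max_iter, tol);
  if (!res.converged) {
    arma::vec zero(X.n_cols, arma::fill::zeros);
    res = irls(X, y, zero, ridge_fallback, 4 * max_iter, tol);
    res.capped = true;
  }
  return res;
}

// [[Rcpp::export]]
List cpp_logistic_fit(const arma::mat& X, const arma::vec& y,
                      int max_iter = 25, double tol = 1e-8,
                      double ridge_fallback = 1e-6) {
  arma::vec start(X.n_cols, arma::fill::zeros);
  FitResult res = fit_with_fallback(X, y, start, max_iter, tol, ridge_fallback);
  return List::create(
    _["coef"] = res.coef, _["se"] = res.se, _["loglik"] = res.loglik,
    _["converged"] = res.converged, _["capped"] = res.capped);
}

// Per-variant scan: trait ~ intercept + covariates + dosage.
// G is n x m (may contain NaN for missing); C is n x k and must include the
// intercept column. Missing dosages drop the sample for that variant only.
// [[Rcpp::export]]
List cpp_logistic_scan(const arma::mat& G, const arma::mat& C,
                       const arma::vec& y, int max_iter = 25,
                       double tol = 1e-8) {
  const arma::uword n = G.n_rows, m = G.n_cols, k = C.n_cols;
  arma::vec beta(m), se(m), nused(m);
  arma::ivec conv(m), capped(m);

  // warm start from covariate-only fit
  arma::vec cov_start(k, arma::fill::zeros);
  FitResult base = irls(C, y, cov_start, 0.0, max_iter, tol);
  arma::vec warm(k + 1, arma::fill::zeros);
  if (base.converged) warm.head(k) = base.coef;

  arma::mat X(n, k + 1);
  X.cols(0, k - 1) = C;
  for (arma::uword j = 0; j < m; ++j) {
    arma::vec g = G.col(j);
    arma::uvec ok = arma::find_finite(g);
    FitResult res;
    if (ok.n_elem == n) {
      X.col(k) = g;
      res = fit_with_fallback(X, y, warm, max_iter, tol, 1e-6);
    } else {
      arma::mat Xs(ok.n_elem, k + 1);
      Xs.cols(0, k - 1) = C.rows(ok);
      Xs.col(k) = g.elem(ok);
      res = fit_with_fallback(Xs, y.elem(ok), warm, max_iter, tol, 1e-6);
    }
    beta[j] = res.coef[k];
    se[j] = res.se[k];
    conv[j] = res.converged ? 1 : 0;
    capped[j] = res.capped ? 1 : 0;
    nused[j] = (double)ok.n_elem;
  }
  return List::create(
    _["beta"] = beta, _["se"] = se, _["converged"] = conv,
    _["capped"] = capped, _["n_used"] = nused);
}

// Likelihood-ratio interaction scan: for each variant compare
//   trait ~ C + g            (null)
//   trait ~ C + g + g*S      (alternative; S = interaction dummy columns)
// Returns the LRT statistic (2*(l1 - l0)), truncated at 0, and df = ncol(S).
// [[Rcpp::export]]
List cpp_interaction_scan(const arma::mat& G, const arma::mat& C,
                          const arma::mat& S, const arma::vec& y,
                          int max_iter = 25, double tol = 1e-8) {
  const arma::uword n = G.n_rows, m = G.n_cols, k = C.n_cols, q = S.n_cols;
  arma::vec lrt(m);
  arma::ivec conv(m);

  arma::vec cov_start(k, arma::fill::zeros);
  FitResult base = irls(C, y, cov_start, 0.0, max_iter, tol);
  arma::vec warm0(k + 1, arma::fill::zeros);
  if (base.converged) warm0.head(k) = base.coef;

  arma::mat X0(n, k + 1), X1(n, k + 1 + q);
  X0.cols(0, k - 1) = C;
  X1.cols(0, k - 1) = C;
  for (arma::uword j = 0; j < m; ++j) {
    arma::vec g = G.col(j);
    arma::uvec ok = arma::find_finite(g);
    FitResult r0, r1;
    if (ok.n_elem == n) {
      X0.col(k) = g;
      X1.col(k) = g;
      X1.cols(k + 1, k + q) = S.each_col() % g;
      r0 = fit_with_fallback(X0, y, warm0, max_iter, tol, 1e-6);
      arma::vec warm1(k + 1 + q, arma::fill::zeros);
      warm1.head(k + 1) = r0.coef;
      r1 = fit_with_fallback(X1, y, warm1, max_iter, tol, 1e-6);
    } else {
      arma::mat X0s(ok.n_elem, k + 1), X1s(ok.n_elem, k + 1 + q);
      X0s.cols(0, k - 1) = C.rows(ok);
      X0s.col(k) = g.elem(ok);
      X1s.cols(0, k) = X0s;
      arma::mat Ss = S.rows(ok);
      X1s.cols(k + 1, k + q) = Ss.each_col() % g.elem(ok);
      r0 = fit_with_fallback(X0s, y.elem(ok), warm0, max_iter, tol, 1e-6);
      arma::vec warm1(k + 1 + q, arma::fill::zeros);
      warm1.head(k + 1) = r0.coef;
      r1 = fit_with_fallback(X1s, y.elem(ok), warm1, max_iter, tol, 1e-6);
    }
    double stat = 2.0 * (r1.loglik - r0.loglik);
    lrt[j] = (stat > 0) ? stat : 0.0;
    conv[j] = (r0.converged && r1.converged) ? 1 : 0;
  }
  return List::create(_["lrt"] = lrt, _["df"] = (int)q, _["converged"] = conv);
}
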