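// Fast profiled-(RE)ML fit of the random-intercept linear mixed model
//   y = X beta + b_group + e,  b ~ N(0, s2 * lambda), e ~ N(0, s2)
// used for per-feature association screening. With a single grouping factor
// V = I + lambda * Z Z' is block diagonal and inverts in closed form, so the
// likelihood profiles down to a 1-D search over lambda >= 0.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct SuffStats {
  mat XtX;        // p x p
  vec Xty;        // p
  double yty;
  mat Sx;         // g x p  per-group column sums of X
  vec Sy;         // g      per-group sums of y
  vec ni;         // g      group sizes
  uword n, p, g;
};

SuffStats make_stats(const mat& X, const vec& y, const uvec& grp, uword g) {
  SuffStats s;
  s.n = X.n_rows; s.p = X.n_cols; s.g = g;
  s.XtX = X.t() * X;
  s.Xty = X.t() * y;
  s.yty = dot(y, y);
  s.Sx.zeros(g, s.p);
  s.Sy.zeros(g);
  s.ni.zeros(g);
  for (uword i = 0; i < s.n; ++i) {
    uword k = grp(i);
    s.Sx.row(k) += X.row(i);
    s.Sy(k) += y(i);
    s.ni(k) += 1.0;
  }
  return s;
}

// Profiled -2 log (restricted) likelihood at lambda, up to an additive
// constant; also returns the GLS pieces when requested.
double objective(const SuffStats& s, double lambda, bool reml,
                 vec* beta_out, mat* xvx_out, double* rss_out) {
  mat XVX = s.XtX;
  vec XVy = s.Xty;
  double yVy = s.yty, logdetV = 0.0;
  for (uword k = 0; k < s.g; ++k) {
    if (s.ni(k) == 0) continue;
    double c = lambda / (1.0 + lambda * s.ni(k));
    XVX -= c * (s.Sx.row(k).t() * s.Sx.row(k));
    XVy -= c * s.Sy(k) * s.Sx.row(k).t();
    yVy -= c * s.Sy(k) * s.Sy(k);
    logdetV += std::log1p(lambda * s.ni(k));
  }
  vec beta;
  bool ok = solve(beta, XVX, XVy, solve_opts::likely_sympd + solve_opts::no_approx);
  if (!ok) return datum::inf;
  double rss = yVy - dot(beta, XVy);
  if (rss <= 0) rss = 1e-300;
  double val;
  if (reml) {
    double ld2, sign2;
    log_det(ld2, sign2, XVX);
    val = logdetV + ld2 + (double)(s.n - s.p) * std::log(rss);
  } else {
    val = logdetV + (double)s.n * std::log(rss);
  }
  if (beta_out) *beta_out = beta;
  if (xvx_out) *xvx_out = XVX;
  if (rss_out) *rss_out = rss;
  return val;
}

// Golden-section minimisation of the profiled objective over u = log(lambda),
// compared against the lambda = 0 boundary (OLS limit).
double optimise_lambda(const SuffStats& s, bool reml) {
  const double lo = -14.0, hi = 14.0, gr = (std::sqrt(5.0) - 1.0) / 2.0;
  double a = lo, b = hi;
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = objective(s, std::exp(c), reml, nullptr, nullptr, nullptr);
  double fd = objective(s, std::exp(d), reml, nullptr, nullptr, nullptr);
  for (int it = 0; it < 80 && (b - a) > 1e-9; ++it) {
    if (fc < fd) {
      b = d; d = c; fd = fc;
      c = b - gr * (b - a);
      fc = objective(s, std::exp(c), reml, nullptr, nullptr, nullptr);
    } else {
      a = c; c = d; fc = fd;
      d = a + gr * (b - a);
      fd = objective(s, std::exp(d), reml, nullptr, nullptr, nullptr);
    }
  }
  double lam = std::exp((a + b) / 2.0);
  double fbest = objective(s, lam, reml, nullptr, nullptr, nullptr);
  double f0 = objective(s, 0.0, reml, nullptr, nullptr, nullptr);
  if (f0 <= fbest) lam = 0.0;
  return lam;
}

} // namespace

// [[Rcpp::export(name = ".lmm_fit_one")]]
Rcpp::List lmm_fit_one(const arma::mat& X, const arma::vec& y,
                       const arma::uvec& group, int n_groups, bool reml) {
  SuffStats s = make_stats(X, y, group, (uword)n_groups);
  if (s.n <= s.p) return Rcpp::List::create(Rcpp::Named("ok") = false);
  double lam = optimise_lambda(s, reml);
  vec beta; mat XVX; double rss;
  double val = objective(s, lam, reml, &beta, &XVX, &rss);
  bool ok = std::isfinite(val);
  if (!ok && reml) { // ML fallback for pathological restricted surfaces
    lam = optimise_lambda(s, false);
    val = objective(s, lam, false, &beta, &XVX, &rss);
    ok = std::isfinite(val);
    reml = false;
  }
  if (!ok) return Rcpp::List::create(Rcpp::Named("ok") = false);
  double denom = reml ? (double)(s.n - s.p) : (double)s.n;
  double sigma2 = rss / denom;
  mat cov = sigma2 * inv_sympd(symmatu(XVX));
  return Rcpp::List::create(
    Rcpp::Named("ok") = true,
    Rcpp::Named("beta") = beta,
    Rcpp::Named("se") = sqrt(cov.diag()).eval(),
    Rcpp::Named("sigma2") = sigma2,
    Rcpp::Named("lambda") = lam,
    Rcpp::Named("reml") = reml,
    Rcpp::Named("n") = (int)s.n);
}

// GLS estimate at a *fixed* variance ratio; kept separate so tests can
// compare the profiled fit against the closed form with known components.
// [[Rcpp::export(name = ".lmm_gls_fixed")]]
Rcpp::List lmm_gls_fixed(const arma::mat& X, const arma::vec& y,
                         const arma::uvec& group, int n_groups, double lambda) {
  SuffStats s = make_stats(X, y, group, (uword)n_groups);
  vec beta; mat XVX; double rss;
  objective(s, lambda, true, &beta, &XVX, &rss);
  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("XVX") = XVX);
}
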