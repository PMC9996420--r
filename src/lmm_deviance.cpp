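// Restricted / profiled log-likelihood for a two-level linear mixed model
// with a diagonal random-effect covariance:
//   y_i = X_i gamma + W_i u_i + e_i,  u_i ~ N(0, diag(s2u)),  e_i ~ N(0, s2e I)
// Marginally V_i = s2e I + W_i diag(s2u) W_i'.  Groups are contiguous blocks.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// theta = c(s2u (length q), s2e), variances on the natural scale.
// grp = 0-based start index of each group block, length m+1 (last = n).
// reml: use the REML adjustment log|X'V^-1 X| and (n-p) in the constant.
// details: also return GLS fixed effects and their covariance.
// [[Rcpp::export]]
Rcpp::List lmm_deviance_cpp(const arma::vec& theta,
                            const arma::vec& y,
                            const arma::mat& X,
                            const arma::mat& W,
                            const arma::ivec& grp,
                            const bool reml,
                            const bool details) {
  const uword n = y.n_elem, p = X.n_cols, q = W.n_cols;
  const double s2e = theta(q);
  const vec d = theta.head(q);
  const uword m = grp.n_elem - 1;

  double logdetV = 0.0, ytViy = 0.0;
  mat XtViX(p, p, fill::zeros);
  vec XtViy(p, fill::zeros);

  bool ok = true;
  for (uword g = 0; g < m && ok; ++g) {
    const uword a = (uword)grp(g), b = (uword)grp(g + 1);
    const mat Wi = W.rows(a, b - 1);
    const mat Xi = X.rows(a, b - 1);
    const vec yi = y.subvec(a, b - 1);
    mat Vi = Wi * diagmat(d) * Wi.t();
    Vi.diag() += s2e;
    mat L;
    if (!chol(L, Vi, "lower")) { ok = false; break; }
    logdetV += 2.0 * sum(log(L.diag()));
    const mat Xs = solve(trimatl(L), Xi);
    const vec ys = solve(trimatl(L), yi);
    XtViX += Xs.t() * Xs;
    XtViy += Xs.t() * ys;
    ytViy += dot(ys, ys);
  }

  if (!ok) {
    return Rcpp::List::create(Rcpp::Named("deviance") = 1e10,
                              Rcpp::Named("ok") = false);
  }

  mat XtViX_inv;
  if (!inv_sympd(XtViX_inv, XtViX)) {
    return Rcpp::List::create(Rcpp::Named("deviance") = 1e10,
                              Rcpp::Named("ok") = false);
  }
  const vec gamma = XtViX_inv * XtViy;
  const double yPy = ytViy - dot(XtViy, gamma);

  double dev;  // -2 log-likelihood (restricted or profiled)
  const double log2pi = std::log(2.0 * M_PI);
  if (reml) {
    double ld2;
    double sign;
    log_det(ld2, sign, XtViX);
    dev = logdetV + ld2 + yPy + (double)(n - p) * log2pi;
  } else {
    dev = logdetV + yPy + (double)n * log2pi;
  }

  if (!details) {
    return Rcpp::List::create(Rcpp::Named("deviance") = dev,
                              Rcpp::Named("ok") = true);
  }
  return Rcpp::List::create(Rcpp::Named("deviance") = dev,
                            Rcpp::Named("ok") = true,
                            Rcpp::Named("beta") = gamma,
                            Rcpp::Named("vcov_beta") = XtViX_inv,
                            Rcpp::Named("yPy") = yPy);
}
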