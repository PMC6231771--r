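// Gibbs sampler for the normal random-intercept regression
//   y_i = x_i' beta + s_{species(i)} + u_{pixel(i)} + e_i,
//   e_i ~ N(0, sigma2), s_j ~ N(0, tau_sp), u_k ~ N(0, tau_px)
// with N(0, prior_beta_var) priors on the fixed effects and Uniform(0,
// var_upper) priors on all three variances.
//
// All location parameters (beta, s, u) are drawn jointly from their exact
// multivariate-normal full conditional via one Cholesky factorization per
// sweep; the variances are updated by slice sampling on their bounded
// support. Uses R's RNG, so chains are reproducible under set.seed().

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Slice sample a variance v on (0, upper) with conditional
// log f(v) = -(n_eff/2) log v - ssq/(2 v)  (uniform prior absorbed in the
// bounds). Stepping is by shrinkage from the full bounded support, so no
// tuning parameter is needed.
static double slice_variance(double cur, double n_eff, double ssq,
                             double upper) {
  auto logf = [&](double v) {
    return -0.5 * n_eff * std::log(v) - ssq / (2.0 * v);
  };
  double ly = logf(cur) - R::rexp(1.0);
  double lo = 1e-12, hi = upper;
  for (int it = 0; it < 1000; ++it) {
    double v = R::runif(lo, hi);
    if (logf(v) >= ly) return v;
    if (v < cur) lo = v; else hi = v;
  }
  return cur;
}

// [[Rcpp::export]]
arma::mat hb_gibbs_chain(const arma::vec& y, const arma::mat& W,
                         int p, int q_sp, int q_px, int n_iter,
                         double prior_beta_var, double var_upper) {
  const int n = y.n_elem;
  const int m = W.n_cols;
  if (m != p + q_sp + q_px)
    Rcpp::stop("design matrix columns do not match p + q_sp + q_px");
  arma::mat WtW = W.t() * W;
  arma::vec Wty = W.t() * y;

  double sig2 = 1.0, tau_sp = 1.0, tau_px = 1.0;
  if (n > 1) {
    double vy = arma::var(y);
    if (vy > 1e-10 && vy < var_upper) sig2 = vy;
  }
  arma::vec coef(m, arma::fill::zeros);
  arma::mat out(n_iter, m + 3);

  for (int it = 0; it < n_iter; ++it) {
    // joint update of (beta, s, u)
    arma::vec dprec(m);
    for (int j = 0; j < p; ++j) dprec(j) = 1.0 / prior_beta_var;
    for (int j = 0; j < q_sp; ++j) dprec(p + j) = 1.0 / tau_sp;
    for (int j = 0; j < q_px; ++j) dprec(p + q_sp + j) = 1.0 / tau_px;
    arma::mat A = WtW / sig2 + arma::diagmat(dprec);
    arma::mat L = arma::chol(A, "lower");
    arma::vec mu = arma::solve(arma::trimatu(L.t()),
                               arma::solve(arma::trimatl(L), Wty / sig2));
    arma::vec z(m);
    for (int j = 0; j < m; ++j) z(j) = R::norm_rand();
    coef = mu + arma::solve(arma::trimatu(L.t()), z);

    // residual variance
    double ssq = 0.0;
    if (n > 0) {
      arma::vec resid = y - W * coef;
      ssq = arma::dot(resid, resid);
    }
    sig2 = slice_variance(sig2, (double)n, ssq, var_upper);

    // random-intercept variances
    if (q_sp > 0) {
      double s2 = arma::dot(coef.subvec(p, p + q_sp - 1),
                            coef.subvec(p, p + q_sp - 1));
      tau_sp = slice_variance(tau_sp, (double)q_sp, s2, var_upper);
    }
    if (q_px > 0) {
      double s2 = arma::dot(coef.subvec(p + q_sp, m - 1),
                            coef.subvec(p + q_sp, m - 1));
      tau_px = slice_variance(tau_px, (double)q_px, s2, var_upper);
    }

    out(it, arma::span(0, m - 1)) = coef.t();
    out(it, m) = sig2;
    out(it, m + 1) = q_sp > 0 ? tau_sp : NA_REAL;
    out(it, m + 2) = q_px > 0 ? tau_px : NA_REAL;
  }
  return out;
}
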