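#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Plain logistic IRLS used on the bootstrap hot path; returns coefficients
// and fitted probabilities. Non-convergence is reported, not fixed: the R
// wrapper falls back to stats::glm.fit.
// [[Rcpp::export]]
Rcpp::List logistic_irls_cpp(const arma::mat& X, const arma::vec& y,
                             int maxit = 40, double tol = 1e-9) {
  vec beta(X.n_cols, fill::zeros);
  bool conv = false;
  for (int it = 0; it < maxit; ++it) {
    vec eta = X * beta;
    vec p = 1.0 / (1.0 + exp(-eta));
    p = clamp(p, 1e-10, 1.0 - 1e-10);
    vec w = p % (1.0 - p);
    vec z = eta + (y - p) / w;
    mat Xw = X.each_col() % w;
    mat H = X.t() * Xw;
    vec g = X.t() * (w % z);
    vec beta_new;
    bool ok = solve(beta_new, H, g, solve_opts::no_approx);
    if (!ok || !beta_new.is_finite()) break;
    double step = norm(beta_new - beta, "inf");
    beta = beta_new;
    if (step < tol) { conv = true; break; }
  }
  vec eta = X * beta;
  vec p = 1.0 / (1.0 + exp(-eta));
  return Rcpp::List::create(Rcpp::Named("coef") = beta,
                            Rcpp::Named("fitted") = p,
                            Rcpp::Named("converged") = conv);
}
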