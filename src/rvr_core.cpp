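// Evidence-maximisation sweeps for relevance vector regression.
// Operates on the precomputed Gram products of Phi = [1 | K]; mirrors the
// update equations documented in rvr_fit().

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// [[Rcpp::export(name = ".rvr_em_core")]]
Rcpp::List rvr_em_core(const arma::mat& PtP, const arma::vec& Pty,
                       double yty, int n, double alpha_init,
                       double sigma2_init, double sigma2_floor,
                       int max_iter, double tol, double prune_at,
                       bool fixed_alpha, bool fixed_sigma2) {
  const uword M = PtP.n_rows;
  uvec active = regspace<uvec>(0, M - 1);
  vec alpha(M, fill::value(alpha_init));
  double sigma2 = sigma2_init;
  vec evidence(max_iter, fill::zeros);
  bool converged = false;
  double max_dla = datum::inf;
  int it = 0;
  bool finite_ok = true;

  for (it = 1; it <= max_iter; ++it) {
    vec a = alpha.elem(active);
    mat H = PtP.submat(active, active) / sigma2;
    H.diag() += a;
    mat R;
    if (!chol(R, H)) {
      mat Hj = H;
      Hj.diag() += 1e-10 * H.diag().max();
      if (!chol(R, Hj)) { finite_ok = false; break; }
    }
    // chol2inv equivalent: Sigma = (R^-1)(R^-1)^T for upper-triangular R
    mat Rinv = inv(trimatu(R));
    mat Sigma = Rinv * Rinv.t();
    vec pty = Pty.elem(active);
    vec mu = (Sigma * pty) / sigma2;
    if (!mu.is_finite()) { finite_ok = false; break; }
    vec gamma = 1.0 - a % Sigma.diag();
    double rss = yty - 2.0 * dot(mu, pty) +
      dot(mu, PtP.submat(active, active) * mu);
    if (rss < 0) rss = 0;

    double logdetC = n * std::log(sigma2) +
      2.0 * accu(log(R.diag())) - accu(log(a));
    double quad = (yty - dot(pty, mu)) / sigma2;
    evidence(it - 1) =
      -0.5 * (n * std::log(2.0 * datum::pi) + logdetC + quad);

    vec alpha_new_act = a;
    if (!fixed_alpha) {
      for (uword i = 0; i < a.n_elem; ++i) {
        double g = gamma(i) > 0 ? gamma(i) : 0.0;
        double m2 = mu(i) * mu(i);
        double v = (m2 > 0) ? g / m2 : datum::inf;
        if (!std::isfinite(v)) v = datum::inf;
        alpha_new_act(i) = v;
      }
    }
    double sigma2_new = sigma2;
    if (!fixed_sigma2) {
      double denom = n - accu(gamma);
      if (denom < 1e-6) denom = 1e-6;
      sigma2_new = rss / denom;
      if (sigma2_new < sigma2_floor) sigma2_new = sigma2_floor;
    }

    max_dla = 0.0;
    bool any_ok = false;
    for (uword i = 0; i < a.n_elem; ++i) {
      if (std::isfinite(alpha_new_act(i)) && std::isfinite(a(i)) &&
          alpha_new_act(i) < prune_at) {
        double d = std::fabs(std::log(alpha_new_act(i)) - std::log(a(i)));
        if (d > max_dla) max_dla = d;
        any_ok = true;
      }
    }
    if (!any_ok) max_dla = 0.0;
    alpha.elem(active) = alpha_new_act;
    sigma2 = sigma2_new;

    uvec keep = find(alpha.elem(active) < prune_at);
    bool keep_changed;
    if (keep.n_elem == 0) { // degenerate: fall back to the bias column
      active = uvec{0};
      alpha(0) = prune_at / 2.0;
      keep_changed = true;
    } else {
      keep_changed = keep.n_elem != active.n_elem;
      active = active.elem(keep);
    }
    if (max_dla < tol && !keep_changed && !fixed_alpha) {
      converged = true;
      break;
    }
    if (fixed_alpha && fixed_sigma2) { converged = true; break; }
  }
  if (it > max_iter) it = max_iter;

  return Rcpp::List::create(
    Rcpp::Named("active") = active + 1, // 1-based for R
    Rcpp::Named("alpha") = alpha,
    Rcpp::Named("sigma2") = sigma2,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("max_dlogalpha") = max_dla,
    Rcpp::Named("evidence") = evidence.head(it),
    Rcpp::Named("finite_ok") = finite_ok);
}
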