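// EM for the maximum-likelihood admixture model.
//
// Observed-data log-likelihood (binomial constant omitted):
//   ll = sum_il [ g_il * log(f_il) + (2 - g_il) * log(1 - f_il) ],
//   f_il = sum_k q_ik * p_kl,
// skipping missing cells. The E-step attributes expected ALT/REF allele
// counts to ancestries; the M-step has closed-form Q and P updates.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// [[Rcpp::export]]
Rcpp::List admixture_em_cpp(const arma::mat& G, arma::mat Q, arma::mat P,
                            int max_iter, double tol, double pmin) {
  const uword n = G.n_rows, L = G.n_cols, K = Q.n_cols;

  mat obs(n, L, fill::ones);
  mat Gz = G;
  for (uword l = 0; l < L; ++l) {
    for (uword i = 0; i < n; ++i) {
      if (!std::isfinite(G(i, l))) {
        obs(i, l) = 0.0;
        Gz(i, l) = 0.0;
      }
    }
  }
  mat G2z = 2.0 * obs - Gz;  // (2 - g), zero at missing cells
  vec nobs = sum(obs, 1);
  nobs.transform([](double v) { return v > 0 ? v : 1.0; });

  std::vector<double> trace;
  trace.reserve(std::min(max_iter, 4096));
  double ll_prev = -datum::inf;
  bool converged = false;
  int iter = 0;

  // E/M steps written as dense products:
  //   P update: sum_i of the expected ALT (REF) counts from ancestry k is
  //     P_kl * (Q' A)_kl  resp.  (1 - P_kl) * (Q' B)_kl
  //   Q update: sum_l of expected counts for (i, k) is
  //     Q_ik * (A P' + B (1 - P)')_ik
  mat F, A, B, QA, QB, sa, sb, M;
  for (iter = 1; iter <= max_iter; ++iter) {
    F = clamp(Q * P, pmin, 1.0 - pmin);
    double ll = accu(Gz % log(F) + G2z % log(1.0 - F));
    trace.push_back(ll);
    if (iter > 1 && std::fabs(ll - ll_prev) < tol) {
      converged = true;
      break;
    }
    ll_prev = ll;

    A = Gz / F;
    B = G2z / (1.0 - F);
    QA = Q.t() * A;                      // K x L
    QB = Q.t() * B;
    sa = P % QA;
    sb = (1.0 - P) % QB;
    M = A * P.t() + B * (1.0 - P).t();   // n x K
    mat denom = sa + sb;
    denom.transform([](double v) { return v > 0 ? v : 1.0; });
    P = clamp(sa / denom, pmin, 1.0 - pmin);
    Q = (Q % M);
    Q.each_col() /= (2.0 * nobs);
    vec rs = sum(Q, 1);
    rs.transform([](double v) { return v > 0 ? v : 1.0; });
    Q.each_col() /= rs;
  }

  F = clamp(Q * P, pmin, 1.0 - pmin);
  double ll_final = accu(Gz % log(F) + G2z % log(1.0 - F));

  return Rcpp::List::create(
    Rcpp::Named("Q") = Q,
    Rcpp::Named("P") = P,
    Rcpp::Named("loglik") = ll_final,
    Rcpp::Named("trace") = trace,
    Rcpp::Named("n_iter") = std::min(iter, max_iter),
    Rcpp::Named("converged") = converged);
}
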