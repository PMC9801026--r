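// Goldman-Yang codon model: rate-matrix construction, transition
// probabilities via symmetric eigendecomposition (the chain is time
// reversible, so diag(sqrt(pi)) Q diag(1/sqrt(pi)) is symmetric), and the
// pairwise log-likelihood from a codon-pair count matrix. Kept in C++
// because the ML fits evaluate this thousands of times per alignment.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat build_q(const arma::vec& rates6, double omega,
                         const arma::vec& pi, const arma::imat& steps) {
  const arma::uword n = pi.n_elem;
  arma::mat Q(n, n, arma::fill::zeros);
  for (arma::uword r = 0; r < steps.n_rows; ++r) {
    const int i = steps(r, 0), j = steps(r, 1);
    double q = rates6(steps(r, 2)) * pi(j);
    if (steps(r, 3)) q *= omega;
    Q(i, j) = q;
  }
  Q.diag() = -arma::sum(Q, 1);
  const double scale = -arma::dot(pi, Q.diag());
  if (scale > 0) Q /= scale;
  return Q;
}

static arma::mat pmatrix(const arma::mat& Q, const arma::vec& pi, double t) {
  const arma::vec s = arma::sqrt(pi);
  arma::mat B = Q;
  B.each_col() %= s;
  B.each_row() /= s.t();
  B = 0.5 * (B + B.t()); // enforce exact symmetry before eig_sym
  arma::vec eval;
  arma::mat evec;
  arma::eig_sym(eval, evec, B);
  arma::mat E = evec;
  E.each_row() %= arma::exp(eval.t() * t);
  arma::mat P = E * evec.t();
  P.each_col() /= s;
  P.each_row() %= s.t();
  return P;
}

// [[Rcpp::export]]
arma::mat cpp_gy_qmatrix(const arma::vec& rates6, double omega,
                         const arma::vec& pi, const arma::imat& steps) {
  return build_q(rates6, omega, pi, steps);
}

// [[Rcpp::export]]
arma::mat cpp_gy_pmatrix(double t, const arma::vec& rates6, double omega,
                         const arma::vec& pi, const arma::imat& steps) {
  return pmatrix(build_q(rates6, omega, pi, steps), pi, t);
}

// [[Rcpp::export]]
double cpp_gy_loglik(double t, const arma::vec& rates6, double omega,
                     const arma::vec& pi, const arma::imat& steps,
                     const arma::mat& counts) {
  const arma::mat P = pmatrix(build_q(rates6, omega, pi, steps), pi, t);
  double ll = 0.0;
  for (arma::uword i = 0; i < counts.n_rows; ++i) {
    for (arma::uword j = 0; j < counts.n_cols; ++j) {
      const double c = counts(i, j);
      if (c <= 0) continue;
      double lik = pi(i) * P(i, j);
      if (!(lik > 1e-300)) lik = 1e-300;
      ll += c * std::log(lik);
    }
  }
  return ll;
}
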