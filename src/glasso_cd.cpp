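// Block coordinate descent for the graphical lasso: column-wise lasso
// problems solved by cyclic soft-threshold coordinate descent, with warm
// starts over W (estimated covariance) and B (regression coefficients).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// [[Rcpp::export(name = ".glasso_cd")]]
List glasso_cd(const arma::mat& S, double rho, double tol, int maxit,
               arma::mat W, arma::mat B) {
  const int p = S.n_cols;
  const double inner_tol = 1e-8;
  const int inner_maxit = 1000;
  // convergence scale: mean absolute off-diagonal of S
  double crit = 0.0;
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) crit += std::fabs(S(i, j));
  crit = crit / (p * (p - 1) / 2.0) + 1e-12;

  bool converged = false;
  int sweep = 0;
  arma::uvec all = arma::regspace<arma::uvec>(0, p - 1);
  for (sweep = 1; sweep <= maxit; ++sweep) {
    arma::mat W_old = W;
    for (int j = 0; j < p; ++j) {
      arma::uvec idx = arma::find(all != (unsigned) j);
      arma::mat W11 = W.submat(idx, idx);
      arma::vec s12 = S.col(j);
      s12 = s12.elem(idx);
      arma::vec beta = B.col(j);
      arma::vec r = W11 * beta;  // running W11 %*% beta
      for (int it = 0; it < inner_maxit; ++it) {
        double delta = 0.0;
        for (int k = 0; k < p - 1; ++k) {
          double bk = beta(k);
          double z = s12(k) - r(k) + W11(k, k) * bk;
          double nb = soft(z, rho) / W11(k, k);
          double d = nb - bk;
          if (d != 0.0) {
            beta(k) = nb;
            r += W11.col(k) * d;
            if (std::fabs(d) > delta) delta = std::fabs(d);
          }
        }
        if (delta < inner_tol) break;
      }
      B.col(j) = beta;
      arma::vec w12 = W11 * beta;
      for (unsigned k = 0; k < idx.n_elem; ++k) {
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
      }
    }
    double diff = 0.0;
    for (int i = 0; i < p; ++i)
      for (int j = i + 1; j < p; ++j) diff += std::fabs(W(i, j) - W_old(i, j));
    diff /= (p * (p - 1) / 2.0);
    if (diff < tol * crit) { converged = true; break; }
  }
  return List::create(_["W"] = W, _["B"] = B, _["converged"] = converged,
                      _["sweeps"] = sweep);
}
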