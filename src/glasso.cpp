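// l1-penalised sparse precision-matrix estimation (graphical lasso).
// Blockwise coordinate descent on the covariance W = Sigma-hat with a
// lasso subproblem per column (Friedman-Hastie-Tibshirani scheme), warm
// started along a decreasing path of penalties so repeated fits (StARS
// subsamples, bootstrap replicates) stay cheap.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// One full glasso fit at penalty `lam`, warm-started from (W, B).
// W is the working covariance estimate (diagonal fixed at S.diag + lam),
// B holds the per-column lasso coefficients. Both are updated in place.
static void glasso_fit(const arma::mat& S, double lam, arma::mat& W,
                       arma::mat& B, double thr, int maxit) {
  const arma::uword p = S.n_rows;
  // mean absolute off-diagonal of S sets the convergence scale
  double soff = (arma::accu(arma::abs(S)) - arma::trace(arma::abs(S)));
  double scale = (p > 1) ? soff / (double)(p * (p - 1)) : 1.0;
  if (scale <= 0) scale = 1e-12;

  W.diag() = S.diag() + lam;

  for (int it = 0; it < maxit; ++it) {
    double dW = 0.0;
    for (arma::uword j = 0; j < p; ++j) {
      // lasso on column j given the other p-1 variables
      arma::vec beta = B.col(j);
      for (int sweep = 0; sweep < 200; ++sweep) {
        double dmax = 0.0;
        for (arma::uword k = 0; k < p; ++k) {
          if (k == j) continue;
          // partial residual: s_kj - sum_{l != k,j} W_kl beta_l
          double r = S(k, j) - (arma::dot(W.col(k), beta) -
                                W(k, k) * beta(k) - W(k, j) * beta(j));
          double bnew = soft(r, lam) / W(k, k);
          double d = std::abs(bnew - beta(k));
          if (d > dmax) dmax = d;
          beta(k) = bnew;
        }
        if (dmax < thr * scale) break;
      }
      beta(j) = 0.0;
      B.col(j) = beta;
      arma::vec w12 = W * beta - W.col(j) * beta(j);
      w12(j) = W(j, j);
      for (arma::uword k = 0; k < p; ++k) {
        if (k == j) continue;
        dW = std::max(dW, std::abs(W(k, j) - w12(k)));
        W(k, j) = w12(k);
        W(j, k) = w12(k);
      }
    }
    if (dW < thr * scale) break;
  }
}

// Recover Theta (precision) from the converged (W, B) pair.
static arma::mat glasso_theta(const arma::mat& W, const arma::mat& B) {
  const arma::uword p = W.n_rows;
  arma::mat Theta(p, p, arma::fill::zeros);
  for (arma::uword j = 0; j < p; ++j) {
    double denom = W(j, j) - arma::dot(W.col(j), B.col(j));
    double tjj = 1.0 / denom;
    Theta(j, j) = tjj;
    for (arma::uword k = 0; k < p; ++k)
      if (k != j) Theta(k, j) = -B(k, j) * tjj;
  }
  // exact zeros are shared (B support), so averaging only symmetrises
  // the magnitudes of the nonzero entries
  return 0.5 * (Theta + Theta.t());
}

//' @rdname glassoPath
//' @param S empirical covariance matrix.
//' @param lambdas penalty values (any order).
//' @param thr convergence threshold relative to the mean absolute
//'   off-diagonal of `S`.
//' @param maxit maximum outer iterations per fit.
//' @return list of precision matrices, one per penalty, in input order.
//' @keywords internal
// [[Rcpp::export]]
List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                     double thr = 1e-4, int maxit = 100) {
  const arma::uword p = S.n_rows;
  arma::uvec ord = arma::sort_index(lambdas, "descend");
  arma::mat W = S;
  arma::mat B(p, p, arma::fill::zeros);
  List out(lambdas.n_elem);
  for (arma::uword i = 0; i < ord.n_elem; ++i) {
    glasso_fit(S, lambdas(ord(i)), W, B, thr, maxit);
    out[ord(i)] = glasso_theta(W, B);
  }
  return out;
}
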