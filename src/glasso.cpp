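// Graphical lasso by block coordinate descent (Friedman-style sweeps over
// columns of the working covariance W, each column solved as an L1 lasso).
// Written against the standard estimator contract: maximize
//   log det K - tr(S K) - lambda * sum_{i != j} |K_ij|
// (optionally penalizing the diagonal as well).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// One glasso solve. W and Beta are warm-start state (modified in place).
static int glasso_solve(const mat& S, double lambda, bool pen_diag,
                        double tol, int maxit, mat& W, mat& Beta,
                        bool& converged) {
  const uword p = S.n_rows;
  double off_mean = 0.0;
  if (p > 1) {
    off_mean = (accu(abs(S)) - accu(abs(S.diag()))) /
               static_cast<double>(p * (p - 1));
  }
  const double thr = tol * std::max(off_mean, 1e-12);
  const double inner_thr = 0.1 * thr;

  converged = false;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    double max_delta = 0.0;
    for (uword j = 0; j < p; ++j) {
      // Coordinate descent on beta for column j:
      // min 0.5 b' W11 b - s12' b + lambda |b|_1
      for (int inner = 0; inner < 200; ++inner) {
        double inner_delta = 0.0;
        for (uword k = 0; k < p; ++k) {
          if (k == j) continue;
          double r = S(k, j);
          for (uword l = 0; l < p; ++l) {
            if (l == j || l == k) continue;
            r -= W(k, l) * Beta(l, j);
          }
          double b_new = soft(r, lambda) / W(k, k);
          double d = std::abs(b_new - Beta(k, j));
          if (d > inner_delta) inner_delta = d;
          Beta(k, j) = b_new;
        }
        if (inner_delta < inner_thr) break;
      }
      // w12 = W11 beta
      for (uword k = 0; k < p; ++k) {
        if (k == j) continue;
        double w = 0.0;
        for (uword l = 0; l < p; ++l) {
          if (l == j) continue;
          w += W(k, l) * Beta(l, j);
        }
        double d = std::abs(w - W(k, j));
        if (d > max_delta) max_delta = d;
        W(k, j) = w;
        W(j, k) = w;
      }
    }
    if (max_delta < thr) { converged = true; ++it; break; }
  }
  (void)pen_diag;
  return it;
}

static mat glasso_recover_K(const mat& S, const mat& W, const mat& Beta) {
  const uword p = S.n_rows;
  mat K(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    double q = W(j, j);
    for (uword k = 0; k < p; ++k) {
      if (k == j) continue;
      q -= W(k, j) * Beta(k, j);
    }
    double k22 = 1.0 / q;
    K(j, j) = k22;
    for (uword k = 0; k < p; ++k) {
      if (k == j) continue;
      K(k, j) = -Beta(k, j) * k22;
    }
  }
  return 0.5 * (K + K.t());
}

// [[Rcpp::export]]
Rcpp::List cpp_glasso(const arma::mat& S, double lambda, bool pen_diag,
                      double tol, int maxit) {
  const uword p = S.n_rows;
  mat W = S;
  if (pen_diag) W.diag() += lambda;
  mat Beta(p, p, fill::zeros);
  bool conv = false;
  int it = glasso_solve(S, lambda, pen_diag, tol, maxit, W, Beta, conv);
  mat K = glasso_recover_K(S, W, Beta);
  return Rcpp::List::create(Rcpp::Named("K") = K,
                            Rcpp::Named("W") = W,
                            Rcpp::Named("iterations") = it,
                            Rcpp::Named("converged") = conv);
}

// Warm-started solution path over a decreasing lambda sequence.
// [[Rcpp::export]]
Rcpp::List cpp_glasso_path(const arma::mat& S, const arma::vec& lambdas,
                           bool pen_diag, double tol, int maxit) {
  const uword p = S.n_rows, m = lambdas.n_elem;
  cube Ks(p, p, m);
  ivec iters(m);
  uvec convs(m);
  mat W = S;
  if (pen_diag) W.diag() += lambdas(0);
  mat Beta(p, p, fill::zeros);
  for (uword i = 0; i < m; ++i) {
    if (pen_diag) W.diag() = S.diag() + lambdas(i);
    bool conv = false;
    iters(i) = glasso_solve(S, lambdas(i), pen_diag, tol, maxit, W, Beta, conv);
    convs(i) = conv ? 1 : 0;
    Ks.slice(i) = glasso_recover_K(S, W, Beta);
  }
  return Rcpp::List::create(Rcpp::Named("K") = Ks,
                            Rcpp::Named("iterations") = iters,
                            Rcpp::Named("converged") = convs);
}
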