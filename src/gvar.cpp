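// Pooled-lag panel graphical VAR: Gaussian discrepancy function for the
// stacked (p * T)-dimensional observation vector, with analytic gradient
// and expected (Fisher) information.
//
// Parameterization (canonical order used by the R side):
//   theta = [ vec(B) | dz (p) | oz upper-tri (p(p-1)/2) | db (p) | ob upper-tri ]
// where the innovation precision is Kz = Dz (I - Oz) Dz, Dz = diag(exp(dz)),
// Oz symmetric with zero diagonal holding the contemporaneous partial
// correlations, and analogously Kb for the between-person component.
// Implied covariance blocks: Sigma[t,s] = B^{t-s} S + Sigma_b (t >= s), with
// S the stationary within-person covariance solving S = B S B' + Sigma_z.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static const double GVAR_BIG = 1e10;
static const double RADIUS_MAX = 0.995;

// Upper-triangle (i<j) index pairs in column-major order.
static void tri_index(uword p, uvec& ri, uvec& ci) {
  uword m = p * (p - 1) / 2, k = 0;
  ri.set_size(m); ci.set_size(m);
  for (uword j = 1; j < p; ++j)
    for (uword i = 0; i < j; ++i) { ri(k) = i; ci(k) = j; ++k; }
}

static bool build_precision(const vec& d, const mat& O, mat& K, mat& Sig) {
  vec e = exp(d);
  mat M = -O;
  M.diag().ones();
  K = diagmat(e) * M * diagmat(e);
  K = 0.5 * (K + K.t());
  return inv_sympd(Sig, K);
}

// [[Rcpp::export]]
arma::mat cpp_lyap(const arma::mat& B, const arma::mat& Q) {
  uword p = B.n_rows;
  mat A = eye(p * p, p * p) - kron(B, B);
  vec s = solve(A, vectorise(Q));
  mat S = reshape(s, p, p);
  return 0.5 * (S + S.t());
}

// Assemble the pT x pT implied covariance from per-lag blocks C[k] = B^k S
// and the between-person covariance (added to every block).
static mat assemble_sigma(const std::vector<mat>& C, const mat& Sb, uword T) {
  uword p = Sb.n_rows;
  mat Sig(p * T, p * T);
  for (uword t = 0; t < T; ++t) {
    for (uword s = 0; s <= t; ++s) {
      mat blk = C[t - s] + Sb;
      Sig.submat(t * p, s * p, (t + 1) * p - 1, (s + 1) * p - 1) = blk;
      if (s != t)
        Sig.submat(s * p, t * p, (s + 1) * p - 1, (t + 1) * p - 1) = blk.t();
    }
  }
  return Sig;
}

// [[Rcpp::export]]
Rcpp::List cpp_gvar_eval(const arma::mat& B, const arma::vec& dz,
                         const arma::mat& Oz, const arma::vec& db,
                         const arma::mat& Ob, const arma::mat& Sn,
                         int T_, bool want_grad, bool want_info) {
  const uword p = B.n_rows;
  const uword T = static_cast<uword>(T_);
  const uword m = p * (p - 1) / 2;
  const uword np = p * p + 2 * (p + m);

  Rcpp::List fail = Rcpp::List::create(
      Rcpp::Named("f") = GVAR_BIG, Rcpp::Named("ok") = false,
      Rcpp::Named("grad") = R_NilValue, Rcpp::Named("info") = R_NilValue);

  cx_vec ev = eig_gen(B);
  double radius = max(abs(ev));
  if (!std::isfinite(radius) || radius >= RADIUS_MAX) {
    fail["f"] = GVAR_BIG * (1.0 + std::max(0.0, radius - RADIUS_MAX));
    return fail;
  }

  mat Kz, Sz, Kb, Sb;
  if (!build_precision(dz, Oz, Kz, Sz)) return fail;
  if (!build_precision(db, Ob, Kb, Sb)) return fail;

  mat A = eye(p * p, p * p) - kron(B, B);
  mat Ainv_lu_l, Ainv_lu_u;  // use solve() with factorization reuse via pre-inverted A? p small: just invert once
  mat Ainv;
  if (!inv(Ainv, A)) return fail;

  mat S = reshape(Ainv * vectorise(Sz), p, p);
  S = 0.5 * (S + S.t());

  std::vector<mat> C(T);
  C[0] = S;
  for (uword k = 1; k < T; ++k) C[k] = B * C[k - 1];

  mat Sig = assemble_sigma(C, Sb, T);
  Sig = 0.5 * (Sig + Sig.t());
  mat L;
  if (!chol(L, Sig, "lower")) return fail;
  double logdet = 2.0 * accu(log(L.diag()));
  mat Siginv;
  if (!inv_sympd(Siginv, Sig)) return fail;

  double f = logdet + accu(Sn % Siginv);
  if (!std::isfinite(f)) return fail;

  if (!want_grad && !want_info)
    return Rcpp::List::create(Rcpp::Named("f") = f, Rcpp::Named("ok") = true,
                              Rcpp::Named("grad") = R_NilValue,
                              Rcpp::Named("info") = R_NilValue);

  uvec ri, ci;
  tri_index(p, ri, ci);
  vec ez = exp(dz), eb = exp(db);
  mat Mz = -Oz; Mz.diag().ones();
  mat Mb = -Ob; Mb.diag().ones();
  mat Dz = diagmat(ez), Db = diagmat(eb);

  // dSigma for every parameter, in canonical order.
  std::vector<mat> dSig(np);
  uword idx = 0;

  // Helper: blocks from a perturbation dS of the stationary covariance plus
  // optional dB (temporal) contribution.
  auto blocks_from = [&](const mat& dS, const mat* dB) -> mat {
    std::vector<mat> dC(T);
    dC[0] = dS;
    for (uword k = 1; k < T; ++k) {
      dC[k] = B * dC[k - 1];
      if (dB) dC[k] += (*dB) * C[k - 1];
    }
    return assemble_sigma(dC, zeros<mat>(p, p), T);
  };

  // B parameters (column-major).
  mat SBt = S * B.t();
  for (uword j = 0; j < p; ++j) {
    for (uword i = 0; i < p; ++i) {
      mat dB(p, p, fill::zeros);
      dB(i, j) = 1.0;
      mat R = dB * SBt;
      R += R.t();
      mat dS = reshape(Ainv * vectorise(R), p, p);
      dS = 0.5 * (dS + dS.t());
      dSig[idx++] = blocks_from(dS, &dB);
    }
  }

  // Innovation precision parameters -> dSz = -Sz dKz Sz -> Lyapunov -> blocks.
  auto within_param = [&](const mat& dK) {
    mat dSz = -Sz * dK * Sz;
    mat dS = reshape(Ainv * vectorise(dSz), p, p);
    dS = 0.5 * (dS + dS.t());
    dSig[idx++] = blocks_from(dS, nullptr);
  };
  for (uword i = 0; i < p; ++i) {
    mat dD(p, p, fill::zeros);
    dD(i, i) = ez(i);
    mat dK = dD * Mz * Dz;
    dK += dK.t();
    within_param(dK);
  }
  for (uword k = 0; k < m; ++k) {
    mat dK(p, p, fill::zeros);
    dK(ri(k), ci(k)) = -ez(ri(k)) * ez(ci(k));
    dK(ci(k), ri(k)) = dK(ri(k), ci(k));
    within_param(dK);
  }

  // Between-person precision parameters: dSigma = J_T (x) dSb.
  auto between_param = [&](const mat& dK) {
    mat dSb = -Sb * dK * Sb;
    mat dFull(p * T, p * T);
    for (uword t = 0; t < T; ++t)
      for (uword s = 0; s < T; ++s)
        dFull.submat(t * p, s * p, (t + 1) * p - 1, (s + 1) * p - 1) = dSb;
    dSig[idx++] = dFull;
  };
  for (uword i = 0; i < p; ++i) {
    mat dD(p, p, fill::zeros);
    dD(i, i) = eb(i);
    mat dK = dD * Mb * Db;
    dK += dK.t();
    between_param(dK);
  }
  for (uword k = 0; k < m; ++k) {
    mat dK(p, p, fill::zeros);
    dK(ri(k), ci(k)) = -eb(ri(k)) * eb(ci(k));
    dK(ci(k), ri(k)) = dK(ri(k), ci(k));
    between_param(dK);
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("f") = f, Rcpp::Named("ok") = true,
      Rcpp::Named("grad") = R_NilValue, Rcpp::Named("info") = R_NilValue);

  if (want_grad) {
    mat W = Siginv - Siginv * Sn * Siginv;
    vec g(np);
    for (uword k = 0; k < np; ++k) g(k) = accu(W % dSig[k]);
    out["grad"] = g;
  }

  if (want_info) {
    // Fisher information of the discrepancy per observation:
    // I_jk = 0.5 * tr(Siginv dSig_j Siginv dSig_k); Var(theta) = inv(n/2 * 2I)…
    // we return tr(Siginv dSig_j Siginv dSig_k) and let R scale.
    std::vector<mat> Y(np);
    for (uword k = 0; k < np; ++k) Y[k] = Siginv * dSig[k] * Siginv;
    mat I(np, np);
    for (uword a = 0; a < np; ++a) {
      for (uword b = a; b < np; ++b) {
        double v = accu(Y[a] % dSig[b]);
        I(a, b) = v;
        I(b, a) = v;
      }
    }
    out["info"] = I;
  }
  return out;
}
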