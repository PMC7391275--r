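// Exact inference core for the per-voxel two-output Gaussian process.
//
// Model (intrinsic coregionalization): for outputs a, b in {1, 2} and
// subjects i, j with standardized inputs x = (pma_std, sex),
//   K[(i,a),(j,b)] = B[a,b] * exp(-||x_i - x_j||^2 / (2 l^2))
//                    + delta_ij delta_ab s2_a,
// with B = L L' (L lower triangular, positive diagonal) and per-output
// white-noise variances s2_a. The joint target vector stacks the two
// standardized outputs output-block-wise: y = (y_FA, y_MD).
//
// theta (length 6): log(l), log(L11), L21, log(L22), log(s2_1), log(s2_2).
//
// All routines operate on a precomputed matrix of squared input distances
// so that the (shared) design can be reused across voxels.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void unpack_theta(const vec& theta, double& ell, mat& B, mat& L,
                         double& s1, double& s2) {
  ell = std::exp(theta(0));
  L.zeros(2, 2);
  L(0, 0) = std::exp(theta(1));
  L(1, 0) = theta(2);
  L(1, 1) = std::exp(theta(3));
  B = L * L.t();
  s1 = std::exp(theta(4));
  s2 = std::exp(theta(5));
}

static mat build_K(const mat& E, const mat& B, double s1, double s2) {
  const uword n = E.n_rows;
  mat K(2 * n, 2 * n);
  K.submat(0, 0, n - 1, n - 1) = B(0, 0) * E;
  K.submat(0, n, n - 1, 2 * n - 1) = B(0, 1) * E;
  K.submat(n, 0, 2 * n - 1, n - 1) = B(1, 0) * E;
  K.submat(n, n, 2 * n - 1, 2 * n - 1) = B(1, 1) * E;
  K.submat(0, 0, n - 1, n - 1).diag() += s1;
  K.submat(n, n, 2 * n - 1, 2 * n - 1).diag() += s2;
  return K;
}

// Cholesky with escalating jitter: start at `jitter`, multiply by 10 up to
// three more times before giving up. Returns the jitter actually used (< 0
// on failure).
static double chol_jitter(mat& Lo, const mat& K, double jitter) {
  double j = jitter;
  for (int attempt = 0; attempt < 4; ++attempt) {
    mat Kj = K;
    Kj.diag() += j;
    if (chol(Lo, Kj, "lower")) return j;
    j *= 10.0;
  }
  return -1.0;
}

// Negative log marginal likelihood and its gradient in theta.
// [[Rcpp::export]]
Rcpp::List gp_nll_grad(const arma::vec& theta, const arma::mat& D2,
                       const arma::vec& y, double jitter) {
  double ell, s1, s2;
  mat B, L;
  unpack_theta(theta, ell, B, L, s1, s2);
  const uword n = D2.n_rows;
  const uword m = 2 * n;

  mat E = exp(-0.5 * D2 / (ell * ell));
  mat K = build_K(E, B, s1, s2);

  mat Lo;
  double jused = chol_jitter(Lo, K, jitter);
  if (jused < 0) {
    return Rcpp::List::create(Rcpp::Named("nll") = R_PosInf,
                              Rcpp::Named("grad") = Rcpp::NumericVector(6),
                              Rcpp::Named("ok") = false,
                              Rcpp::Named("jitter_used") = jused);
  }

  vec alpha = solve(trimatu(Lo.t()), solve(trimatl(Lo), y));
  double logdet = 2.0 * accu(log(Lo.diag()));
  double nll = 0.5 * dot(y, alpha) + 0.5 * logdet +
               0.5 * double(m) * std::log(2.0 * M_PI);

  // A = alpha alpha' - K^{-1}; d lml / d theta_i = 0.5 tr(A dK/dtheta_i)
  mat Linv = inv(trimatl(Lo));
  mat Kinv = Linv.t() * Linv;
  mat A = alpha * alpha.t() - Kinv;

  const mat A11 = A.submat(0, 0, n - 1, n - 1);
  const mat A12 = A.submat(0, n, n - 1, 2 * n - 1);
  const mat A21 = A.submat(n, 0, 2 * n - 1, n - 1);
  const mat A22 = A.submat(n, n, 2 * n - 1, 2 * n - 1);

  // lengthscale: dE/dlog(l) = E % D2 / l^2
  mat dE = E % D2 / (ell * ell);
  double g_ell = 0.5 * (B(0, 0) * accu(A11 % dE) + B(0, 1) * accu(A12 % dE) +
                        B(1, 0) * accu(A21 % dE) + B(1, 1) * accu(A22 % dE));

  // coregionalization: T[a,b] = sum(A_ab % E); dlml/dB = 0.5 * T (sym)
  mat T(2, 2);
  T(0, 0) = accu(A11 % E);
  T(0, 1) = accu(A12 % E);
  T(1, 0) = accu(A21 % E);
  T(1, 1) = accu(A22 % E);

  // chain through B = L L' for the three free parameters of L
  auto dB_for = [&](const mat& dL) { return dL * L.t() + L * dL.t(); };
  mat dL1(2, 2, fill::zeros), dL2(2, 2, fill::zeros), dL3(2, 2, fill::zeros);
  dL1(0, 0) = L(0, 0);  // d/d log(L11)
  dL2(1, 0) = 1.0;      // d/d L21
  dL3(1, 1) = L(1, 1);  // d/d log(L22)
  double g_l11 = 0.5 * accu(T % dB_for(dL1));
  double g_l21 = 0.5 * accu(T % dB_for(dL2));
  double g_l22 = 0.5 * accu(T % dB_for(dL3));

  // noise: dK/dlog(s2_a) = s2_a on the corresponding diagonal block
  double g_s1 = 0.5 * s1 * trace(A11);
  double g_s2 = 0.5 * s2 * trace(A22);

  // gradient of the NEGATIVE lml
  Rcpp::NumericVector grad =
      Rcpp::NumericVector::create(-g_ell, -g_l11, -g_l21, -g_l22, -g_s1, -g_s2);
  return Rcpp::List::create(Rcpp::Named("nll") = nll, Rcpp::Named("grad") = grad,
                            Rcpp::Named("ok") = true,
                            Rcpp::Named("jitter_used") = jused);
}

// Posterior predictive mean and SD per output at q query points.
// D2cross: n x q squared distances between training and query inputs.
// [[Rcpp::export]]
Rcpp::List gp_predict_cpp(const arma::vec& theta, const arma::mat& D2,
                          const arma::mat& D2cross, const arma::vec& y,
                          bool include_noise, double jitter) {
  double ell, s1, s2;
  mat B, L;
  unpack_theta(theta, ell, B, L, s1, s2);
  const uword n = D2.n_rows;
  const uword q = D2cross.n_cols;

  mat E = exp(-0.5 * D2 / (ell * ell));
  mat K = build_K(E, B, s1, s2);
  mat Lo;
  double jused = chol_jitter(Lo, K, jitter);
  if (jused < 0) Rcpp::stop("covariance factorization failed at maximum jitter");

  vec alpha = solve(trimatu(Lo.t()), solve(trimatl(Lo), y));
  mat Ec = exp(-0.5 * D2cross / (ell * ell));  // n x q

  mat mean_out(q, 2), var_out(q, 2);
  const double noise[2] = {s1, s2};
  for (uword b = 0; b < 2; ++b) {
    mat Kstar(2 * n, q);
    Kstar.rows(0, n - 1) = B(0, b) * Ec;
    Kstar.rows(n, 2 * n - 1) = B(1, b) * Ec;
    mean_out.col(b) = Kstar.t() * alpha;
    mat V = solve(trimatl(Lo), Kstar);
    vec v = B(b, b) - sum(V % V, 0).t();
    v.transform([](double x) { return x < 1e-12 ? 1e-12 : x; });
    if (include_noise) v += noise[b];
    var_out.col(b) = v;
  }
  return Rcpp::List::create(Rcpp::Named("mean") = mean_out,
                            Rcpp::Named("sd") = sqrt(var_out),
                            Rcpp::Named("jitter_used") = jused);
}
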