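#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Accumulate the ridge-GLS system for the coefficient update:
//   LHS = sum_i (f_i f_i') (x) Sigma_i^-1,  RHS = sum_i (f_i (x) I) Sigma_i^-1 z_i
// with Sigma_i^-1 = diag(1/a_i) Rinv diag(1/a_i) / phi, a_iq = sqrt(nu(mu_iq)).
// Parameter ordering is pathway-major: element (a, q) sits at index a*Q + q.
// [[Rcpp::export]]
Rcpp::List bsys_cpp(const arma::mat& F, const arma::mat& Z,
                    const arma::mat& Ahalf, const arma::mat& Rinv,
                    double phi) {
  const uword N = F.n_rows, P = F.n_cols, Q = Z.n_cols;
  mat LHS(P * Q, P * Q, fill::zeros);
  // F scaled per phenotype by 1/a_iq
  cube Fs(N, P, Q);
  for (uword q = 0; q < Q; ++q)
    Fs.slice(q) = F.each_col() / Ahalf.col(q);
  for (uword q = 0; q < Q; ++q) {
    for (uword r = q; r < Q; ++r) {
      mat H = Fs.slice(q).t() * Fs.slice(r) * (Rinv(q, r) / phi);
      for (uword a = 0; a < P; ++a)
        for (uword b = 0; b < P; ++b) {
          LHS(a * Q + q, b * Q + r) = H(a, b);
          if (r != q) LHS(a * Q + r, b * Q + q) = H(b, a);
        }
    }
  }
  mat Zt = ((Z / Ahalf) * Rinv) / Ahalf / phi;  // Rinv symmetric
  mat FZ = F.t() * Zt;                          // P x Q
  vec RHS(P * Q);
  for (uword a = 0; a < P; ++a)
    for (uword q = 0; q < Q; ++q)
      RHS(a * Q + q) = FZ(a, q);
  return Rcpp::List::create(Rcpp::Named("LHS") = LHS,
                            Rcpp::Named("RHS") = RHS);
}

// Accumulate the ridge-GLS system for the free weight update:
//   LHS[t,t'] = sum_i x_it x_it' G_i[k(t), k(t')],  G_i = Bn Sigma_i^-1 Bn'
//   RHS[t]    = sum_i x_it (Bn Sigma_i^-1 zr_i)[k(t)]
// Xc is the non-intercept design (pathway-major columns), Bn the K x Q block
// of non-intercept coefficients, zr the working response minus the intercept
// offset, map the 0-based pathway index of each column (must be sorted).
// [[Rcpp::export]]
Rcpp::List wsys_cpp(const arma::mat& Xc, const arma::mat& Bn,
                    const arma::uvec& map, const arma::mat& Zr,
                    const arma::mat& Ahalf, const arma::mat& Rinv,
                    double phi) {
  const uword N = Xc.n_rows, T = Xc.n_cols, K = Bn.n_rows;
  const uword Q = Bn.n_cols;
  // G_i[k,l] = sum_{q,q'} Rinv(q,q') Bn(k,q) Bn(l,q') / (a_iq a_iq' phi),
  // assembled as one GEMM: Gflat (N x K^2) = U (N x Q^2) * C (Q^2 x K^2)
  mat U(N, Q * Q);
  mat Ainv = 1.0 / Ahalf;
  for (uword q = 0; q < Q; ++q)
    for (uword r = 0; r < Q; ++r)
      U.col(q * Q + r) = Ainv.col(q) % Ainv.col(r);
  mat C(Q * Q, K * K);
  for (uword q = 0; q < Q; ++q)
    for (uword r = 0; r < Q; ++r)
      for (uword k = 0; k < K; ++k)
        for (uword l = 0; l < K; ++l)
          C(q * Q + r, k * K + l) = Rinv(q, r) * Bn(k, q) * Bn(l, r) / phi;
  mat Gflat = U * C;  // column k*K + l holds G_i[k,l] over i
  // column ranges per pathway
  uvec start(K), stop(K);
  start.fill(T); stop.fill(0);
  for (uword t = 0; t < T; ++t) {
    uword k = map(t);
    if (t < start(k)) start(k) = t;
    stop(k) = t;
  }
  mat LHS(T, T, fill::zeros);
  for (uword k = 0; k < K; ++k) {
    if (start(k) == T) continue;
    mat Xk = Xc.cols(start(k), stop(k));
    for (uword l = k; l < K; ++l) {
      if (start(l) == T) continue;
      vec g = Gflat.col(k * K + l);
      mat Xl = Xc.cols(start(l), stop(l));
      mat blk = Xk.t() * (Xl.each_col() % g);
      LHS.submat(start(k), start(l), stop(k), stop(l)) = blk;
      if (l != k)
        LHS.submat(start(l), start(k), stop(l), stop(k)) = blk.t();
    }
  }
  mat Zt = ((Zr / Ahalf) * Rinv) / Ahalf / phi;  // N x Q
  mat V = Zt * Bn.t();                           // N x K
  vec RHS(T);
  for (uword t = 0; t < T; ++t)
    RHS(t) = dot(Xc.col(t), V.col(map(t)));
  return Rcpp::List::create(Rcpp::Named("LHS") = LHS,
                            Rcpp::Named("RHS") = RHS);
}
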