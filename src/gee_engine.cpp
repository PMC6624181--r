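#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// declared in gee_systems.cpp
Rcpp::List bsys_cpp(const arma::mat& F, const arma::mat& Z,
                    const arma::mat& Ahalf, const arma::mat& Rinv,
                    double phi);
Rcpp::List wsys_cpp(const arma::mat& Xc, const arma::mat& Bn,
                    const arma::uvec& map, const arma::mat& Zr,
                    const arma::mat& Ahalf, const arma::mat& Rinv,
                    double phi);

namespace {

const double EPS_MU = 1e-8;

struct Working {
  mat mu, z, dhalf;
};

// GEE working response and IRLS weight factor for the current eta
Working working_parts(const mat& Y, const mat& eta, int family) {
  Working w;
  if (family == 0) {            // gaussian / identity
    w.mu = eta;
    w.z = Y;
    w.dhalf = ones<mat>(Y.n_rows, Y.n_cols);
  } else {                      // binomial / logit
    w.mu = clamp(1.0 / (1.0 + exp(-eta)), EPS_MU, 1.0 - EPS_MU);
    mat nu = w.mu % (1.0 - w.mu);
    w.z = eta + (Y - w.mu) / nu;
    w.dhalf = 1.0 / sqrt(nu);
  }
  return w;
}

mat comp_scores(const mat& Xc, const vec& w, const uvec& start,
                const uvec& stop, uword K) {
  mat F(Xc.n_rows, K + 1);
  F.col(0).ones();
  for (uword k = 0; k < K; ++k)
    F.col(k + 1) = Xc.cols(start(k), stop(k)) * w.subvec(start(k), stop(k));
  return F;
}

// moment working correlation; structure: 0 indep, 1 exch, 2 ar1, 3 unstr
mat estimate_R(const mat& r, double phi, int structure) {
  const uword N = r.n_rows, Q = r.n_cols;
  const double cap = 0.99;
  mat R = eye<mat>(Q, Q);
  if (Q == 1 || structure == 0) return R;
  if (structure == 1) {
    mat cp = r.t() * r / (double(N) * phi);
    double a = 0.0; uword n = 0;
    for (uword j = 0; j < Q; ++j)
      for (uword k = j + 1; k < Q; ++k) { a += cp(j, k); ++n; }
    a /= double(n);
    a = std::min(std::max(a, -1.0 / double(Q - 1) + 1e-6), cap);
    R.fill(a); R.diag().ones();
    return R;
  }
  if (structure == 2) {
    double a = accu(r.cols(0, Q - 2) % r.cols(1, Q - 1)) /
      (double(N * (Q - 1)) * phi);
    a = std::min(std::max(a, -cap), cap);
    for (uword j = 0; j < Q; ++j)
      for (uword k = 0; k < Q; ++k)
        R(j, k) = std::pow(a, double(j > k ? j - k : k - j));
    return R;
  }
  // unstructured
  R = r.t() * r / (double(N) * phi);
  R = (R + R.t()) / 2.0;
  R.diag().ones();
  for (uword j = 0; j < Q; ++j)
    for (uword k = 0; k < Q; ++k)
      if (j != k) R(j, k) = std::min(std::max(R(j, k), -cap), cap);
  vec ev; mat V;
  eig_sym(ev, V, R);
  if (ev.min() < 1e-6) {
    ev = clamp(ev, 1e-6, datum::inf);
    R = V * diagmat(ev) * V.t();
    vec d = sqrt(R.diag());
    R = R / (d * d.t());
  }
  return R;
}

double quasi_dev(const mat& Y, const mat& mu, int family) {
  if (family == 0) return accu(square(Y - mu));
  double s = 0.0;
  for (uword i = 0; i < Y.n_elem; ++i) {
    double y = Y(i), m = mu(i);
    if (y > 0) s += y * std::log(y / m);
    if (y < 1) s += (1.0 - y) * std::log((1.0 - y) / (1.0 - m));
  }
  return 2.0 * s;
}

}  // namespace

// Full alternating doubly-penalized GEE fit; mirrors the R reference loop
// (update B, update W, ridge-balanced rescale, Anderson mixing, working
// correlation and dispersion refresh) with identical numerics.
// [[Rcpp::export]]
Rcpp::List fit_engine_cpp(const arma::mat& X, const arma::mat& Y,
                          const arma::uvec& map, arma::vec w, arma::mat B,
                          int family, int structure,
                          double lambdaG, double lambdaP,
                          double tol, int max_iter, bool est_phi,
                          int aa_depth, double aa_cap) {
  const uword N = X.n_rows, Q = Y.n_cols;
  const uword T = map.n_elem;
  const uword K = B.n_rows - 1;
  const mat Xc = X.cols(1, T);
  uvec start(K), stop(K);
  start.fill(T); stop.fill(0);
  for (uword t = 0; t < T; ++t) {
    uword k = map(t);
    if (t < start(k)) start(k) = t;
    stop(k) = t;
  }
  double dfree = double(N * Q) - double(K + T);

  mat Rinv = eye<mat>(Q, Q);
  double phi = 1.0;
  mat F = comp_scores(Xc, w, start, stop, K);
  std::vector<vec> f_hist, g_hist;
  const uword nB = B.n_elem;
  std::vector<double> trace;
  double obj_best = datum::nan;
  mat B_best = B; vec w_best = w;
  mat Rcur = eye<mat>(Q, Q);
  bool converged = false;
  int iter = 0;
  double delta = datum::nan;

  while (iter < max_iter) {
    ++iter;
    // --- update B for fixed W
    Working wp = working_parts(Y, F * B, family);
    Rcpp::List bs = bsys_cpp(F, wp.z, wp.dhalf, Rinv, phi);
    mat LHSb = Rcpp::as<mat>(bs["LHS"]);
    vec RHSb = Rcpp::as<vec>(bs["RHS"]);
    for (uword j = Q; j < (K + 1) * Q; ++j) LHSb(j, j) += lambdaP;
    vec b = solve(LHSb, RHSb, solve_opts::likely_sympd);
    mat B_new(K + 1, Q);
    for (uword a = 0; a <= K; ++a)
      for (uword q = 0; q < Q; ++q)
        B_new(a, q) = b(a * Q + q);
    // --- update W for fixed B
    Working wp2 = working_parts(Y, F * B_new, family);
    mat Zr = wp2.z;
    Zr.each_row() -= B_new.row(0);
    mat Bn = B_new.rows(1, K);
    Rcpp::List ws = wsys_cpp(Xc, Bn, map, Zr, wp2.dhalf, Rinv, phi);
    mat LHSw = Rcpp::as<mat>(ws["LHS"]);
    vec RHSw = Rcpp::as<vec>(ws["RHS"]);
    LHSw.diag() += lambdaG;
    vec w_new = solve(LHSw, RHSw, solve_opts::likely_sympd);
    // --- ridge-balanced rescale along the scale-indeterminate direction
    if (lambdaG > 0 && lambdaP > 0) {
      for (uword k = 0; k < K; ++k) {
        double nw = norm(w_new.subvec(start(k), stop(k)));
        double nb = norm(B_new.row(k + 1));
        if (nw > 1e-12 && nb > 1e-12) {
          double cc = std::pow(lambdaP / lambdaG, 0.25) * std::sqrt(nb / nw);
          w_new.subvec(start(k), stop(k)) *= cc;
          B_new.row(k + 1) /= cc;
        }
      }
    }
    vec g_vec(nB + T), theta_old(nB + T);
    g_vec.subvec(0, nB - 1) = vectorise(B_new);
    g_vec.subvec(nB, nB + T - 1) = w_new;
    theta_old.subvec(0, nB - 1) = vectorise(B);
    theta_old.subvec(nB, nB + T - 1) = w;
    vec f_vec = g_vec - theta_old;
    delta = abs(f_vec).max();
    if (!std::isfinite(delta) || delta > 1e6) {
      B = B_best; w = w_best;
      break;
    }
    if (delta < tol) { B = B_new; w = w_new; converged = true; break; }
    // --- Anderson mixing over the recent map evaluations
    f_hist.push_back(f_vec); g_hist.push_back(g_vec);
    if (f_hist.size() > size_t(aa_depth + 1)) {
      f_hist.erase(f_hist.begin()); g_hist.erase(g_hist.begin());
    }
    int m = int(f_hist.size()) - 1;
    vec theta_next = g_vec;
    if (m >= 1 && aa_depth > 0 && delta > 10 * tol) {
      mat dF(nB + T, m), dG(nB + T, m);
      for (int j = 1; j <= m; ++j) {
        dF.col(j - 1) = f_hist[m - j + 1] - f_hist[m - j];
        dG.col(j - 1) = g_hist[m - j + 1] - g_hist[m - j];
      }
      vec gam;
      bool ok = solve(gam, dF, f_vec, solve_opts::no_approx);
      if (ok && gam.is_finite() && abs(gam).max() <= aa_cap)
        theta_next = g_vec - dG * gam;
    }
    for (uword a = 0; a <= K; ++a)
      for (uword q = 0; q < Q; ++q)
        B(a, q) = theta_next(q * (K + 1) + a);  // vectorise is column-major
    w = theta_next.subvec(nB, nB + T - 1);
    // --- refresh working quantities from the accepted iterate
    F = comp_scores(Xc, w, start, stop, K);
    mat eta = F * B;
    mat mu = (family == 0) ? eta
      : clamp(1.0 / (1.0 + exp(-eta)), EPS_MU, 1.0 - EPS_MU);
    mat res = Y - mu;
    if (family != 0) res /= sqrt(mu % (1.0 - mu));
    phi = est_phi ? accu(square(res)) / dfree : 1.0;
    Rcur = estimate_R(res, phi, structure);
    Rinv = inv_sympd(Rcur);
    double obj = quasi_dev(Y, mu, family) +
      lambdaP * accu(square(B.rows(1, K))) + lambdaG * dot(w, w);
    trace.push_back(obj);
    if (std::isfinite(obj) && (!std::isfinite(obj_best) || obj < obj_best)) {
      obj_best = obj; B_best = B; w_best = w;
    }
  }
  if (!converged && std::isfinite(obj_best)) { B = B_best; w = w_best; }

  return Rcpp::List::create(
      Rcpp::Named("B") = B, Rcpp::Named("w") = w,
      Rcpp::Named("R") = Rcur, Rcpp::Named("phi") = phi,
      Rcpp::Named("n_iter") = iter, Rcpp::Named("converged") = converged,
      Rcpp::Named("trace") = trace, Rcpp::Named("last_delta") = delta);
}
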