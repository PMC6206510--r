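// Compiled kernels for Procrustes superimposition.
// Configurations are passed as n x (3L) row-major flattenings
// (subject rows, landmark-major column order x1,y1,z1,x2,...).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat config_row(const mat& flat, uword i, uword L) {
  // L x 3 matrix for subject i
  mat out(L, 3);
  for (uword j = 0; j < L; ++j)
    for (uword k = 0; k < 3; ++k)
      out(j, k) = flat(i, 3 * j + k);
  return out;
}

static void store_row(mat& flat, uword i, const mat& cfg) {
  const uword L = cfg.n_rows;
  for (uword j = 0; j < L; ++j)
    for (uword k = 0; k < 3; ++k)
      flat(i, 3 * j + k) = cfg(j, k);
}

// rotation-only orthogonal Procrustes: rotate X onto Y (both L x 3, centered)
static mat procrustes_rotation(const mat& X, const mat& Y) {
  mat M = X.t() * Y;          // 3 x 3
  mat U, V;
  vec s;
  svd(U, s, V, M);
  mat R = U * V.t();
  if (det(R) < 0) {           // exclude reflections
    U.col(2) *= -1.0;
    R = U * V.t();
  }
  return R;
}

// [[Rcpp::export(name = ".cpp_center_scale")]]
Rcpp::List cpp_center_scale(const arma::mat& flat) {
  const uword n = flat.n_rows, L = flat.n_cols / 3;
  mat out(n, flat.n_cols);
  vec sizes(n);
  for (uword i = 0; i < n; ++i) {
    mat cfg = config_row(flat, i, L);
    rowvec ctr = mean(cfg, 0);
    cfg.each_row() -= ctr;
    double cs = std::sqrt(accu(square(cfg)));
    sizes(i) = cs;
    if (cs > 0) cfg /= cs;
    store_row(out, i, cfg);
  }
  return Rcpp::List::create(Rcpp::Named("scaled") = out,
                            Rcpp::Named("sizes") = sizes);
}

// rotate every (already centered, scaled) configuration onto `target`
// [[Rcpp::export(name = ".cpp_rotate_all")]]
arma::mat cpp_rotate_all(const arma::mat& flat, const arma::mat& target) {
  const uword n = flat.n_rows, L = flat.n_cols / 3;
  mat out(n, flat.n_cols);
  for (uword i = 0; i < n; ++i) {
    mat cfg = config_row(flat, i, L);
    mat R = procrustes_rotation(cfg, target);
    store_row(out, i, cfg * R);
  }
  return out;
}

// full GPA iteration loop on centered, unit-size configurations.
// Returns aligned flat matrix, consensus (L x 3), iteration count, last delta.
// [[Rcpp::export(name = ".cpp_gpa_iterate")]]
Rcpp::List cpp_gpa_iterate(const arma::mat& flat_scaled, double tol, int max_iter) {
  const uword n = flat_scaled.n_rows, L = flat_scaled.n_cols / 3;
  mat cur = flat_scaled;

  // order-invariant initial consensus: mean of centered-scaled configurations
  rowvec mrow = mean(cur, 0);
  mat consensus(L, 3);
  for (uword j = 0; j < L; ++j)
    for (uword k = 0; k < 3; ++k)
      consensus(j, k) = mrow(3 * j + k);
  consensus.each_row() -= mean(consensus, 0);
  double cs = std::sqrt(accu(square(consensus)));
  if (cs > 0) consensus /= cs;

  double delta = datum::inf;
  int it = 0;
  while (it < max_iter) {
    ++it;
    cur = cpp_rotate_all(cur, consensus);
    rowvec m2 = mean(cur, 0);
    mat newcon(L, 3);
    for (uword j = 0; j < L; ++j)
      for (uword k = 0; k < 3; ++k)
        newcon(j, k) = m2(3 * j + k);
    newcon.each_row() -= mean(newcon, 0);
    double ncs = std::sqrt(accu(square(newcon)));
    if (ncs > 0) newcon /= ncs;
    delta = std::sqrt(accu(square(newcon - consensus)));
    consensus = newcon;
    if (delta < tol) break;
  }
  return Rcpp::List::create(Rcpp::Named("aligned") = cur,
                            Rcpp::Named("consensus") = consensus,
                            Rcpp::Named("iterations") = it,
                            Rcpp::Named("delta") = delta);
}

// Parallel-analysis null eigenvalues: independently permute each column of
// the (already centered) matrix and return covariance eigenvalues per
// iteration (descending, divided by n-1). Uses R's RNG for reproducibility.
// [[Rcpp::export(name = ".cpp_pa_null")]]
arma::mat cpp_pa_null(const arma::mat& Xc, int n_iter) {
  const uword n = Xc.n_rows, p = Xc.n_cols;
  const uword r = std::min(n, p);
  mat out(n_iter, r);
  mat Xp = Xc;
  Rcpp::RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    for (uword j = 0; j < p; ++j) {
      Xp.col(j) = Xc.col(j);
      // Fisher-Yates with R's RNG
      for (uword i = n - 1; i > 0; --i) {
        uword k = (uword)(unif_rand() * (i + 1));
        if (k > i) k = i;
        std::swap(Xp(i, j), Xp(k, j));
      }
    }
    mat G = (p <= n) ? mat(Xp.t() * Xp) : mat(Xp * Xp.t());
    vec ev = eig_sym(G);            // ascending
    for (uword k = 0; k < r; ++k)
      out(it, k) = std::max(ev(G.n_rows - 1 - k), 0.0) / double(n - 1);
  }
  return out;
}
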