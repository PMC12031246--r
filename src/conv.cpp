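#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

// Mirror index without edge repetition: -1 -> 1, n -> n-2.
static inline int reflect_idx(int p, int n) {
  while (p < 0 || p >= n) {
    if (p < 0) p = -p;
    if (p >= n) p = 2 * n - 2 - p;
  }
  return p;
}

// 2-D cross-correlation with reflect padding, same-size output.
// [[Rcpp::export]]
arma::mat xcorr2_reflect(const arma::mat& x, const arma::mat& k) {
  const int nr = x.n_rows, nc = x.n_cols;
  const int kr = k.n_rows, kc = k.n_cols;
  const int ro = (kr - 1) / 2, co = (kc - 1) / 2;
  arma::mat out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int v = 0; v < kc; ++v) {
        const int jj = reflect_idx(j - co + v, nc);
        for (int u = 0; u < kr; ++u) {
          const int ii = reflect_idx(i - ro + u, nr);
          acc += x(ii, jj) * k(u, v);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Separable cross-correlation with reflect padding: kernel W[u, v] =
// a[u] * b[v] (column factor a over rows, row factor b over columns).
// Equals xcorr2_reflect(x, a * b^T) exactly: reflect padding along one
// axis commutes with filtering along the other.
// [[Rcpp::export]]
arma::mat xcorr2_sep_reflect(const arma::mat& x, const arma::vec& a,
                             const arma::vec& b) {
  const int nr = x.n_rows, nc = x.n_cols;
  const int ka = a.n_elem, kb = b.n_elem;
  const int ro = (ka - 1) / 2, co = (kb - 1) / 2;
  arma::mat tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const double* col = x.colptr(j);
    double* tcol = tmp.colptr(j);
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int u = 0; u < ka; ++u)
        acc += a(u) * col[reflect_idx(i - ro + u, nr)];
      tcol[i] = acc;
    }
  }
  for (int j = 0; j < nc; ++j) {
    double* ocol = out.colptr(j);
    std::memset(ocol, 0, sizeof(double) * nr);
    for (int v = 0; v < kb; ++v) {
      const double* tcol = tmp.colptr(reflect_idx(j - co + v, nc));
      const double bv = b(v);
      for (int i = 0; i < nr; ++i) ocol[i] += bv * tcol[i];
    }
  }
  return out;
}
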