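// Low-level numeric kernels: im2col/col2im for the convolution layers and a
// grid-hashed neighborhood/plane-fit core for point-cloud roughness.
#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_extent(int n, int K, int stride, int pad, int dil) {
  int eff = (K - 1) * dil + 1;
  return (n + 2 * pad - eff) / stride + 1;
}

// Unfold an H x W x C feature cube into a (K*K*C) x (Ho*Wo) matrix.
// Row index (0-based): c*K*K + b*K + a, a = kernel row, b = kernel col.
// Column index: j*Ho + i (column-major over the output grid).
// [[Rcpp::export]]
arma::mat im2col_cpp(const arma::cube& x, int K, int stride, int pad, int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_extent(H, K, stride, pad, dil);
  const int Wo = out_extent(W, K, stride, pad, dil);
  arma::mat out(K * K * C, (size_t)Ho * Wo, arma::fill::zeros);
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      const size_t col = (size_t)j * Ho + i;
      const int r0 = i * stride - pad, c0 = j * stride - pad;
      double* dst = out.colptr(col);
      for (int c = 0; c < C; ++c) {
        for (int b = 0; b < K; ++b) {
          const int cc = c0 + b * dil;
          if (cc < 0 || cc >= W) continue;
          for (int a = 0; a < K; ++a) {
            const int rr = r0 + a * dil;
            if (rr < 0 || rr >= H) continue;
            dst[c * K * K + b * K + a] = x(rr, cc, c);
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add columns back into an H x W x C cube.
// [[Rcpp::export]]
arma::cube col2im_cpp(const arma::mat& cols, int H, int W, int C,
                      int K, int stride, int pad, int dil) {
  const int Ho = out_extent(H, K, stride, pad, dil);
  const int Wo = out_extent(W, K, stride, pad, dil);
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      const size_t col = (size_t)j * Ho + i;
      const int r0 = i * stride - pad, c0 = j * stride - pad;
      const double* src = cols.colptr(col);
      for (int c = 0; c < C; ++c) {
        for (int b = 0; b < K; ++b) {
          const int cc = c0 + b * dil;
          if (cc < 0 || cc >= W) continue;
          for (int a = 0; a < K; ++a) {
            const int rr = r0 + a * dil;
            if (rr < 0 || rr >= H) continue;
            x(rr, cc, c) += src[c * K * K + b * K + a];
          }
        }
      }
    }
  }
  return x;
}

static inline long long cell_key(long long ix, long long iy, long long iz) {
  // pack three 21-bit signed cell indices into one key
  const long long M = 1LL << 20;
  return ((ix + M) << 42) | ((iy + M) << 21) | (iz + M);
}

// Per-point distance to the total-least-squares plane of the point's
// neighbors within `radius` (query excluded). < 3 neighbors or a collinear
// neighborhood yields NA.
// [[Rcpp::export]]
NumericVector roughness_cpp(const arma::mat& xyz, double radius) {
  const int n = xyz.n_rows;
  NumericVector out(n, NA_REAL);
  if (n == 0) return out;
  const double inv = 1.0 / radius;
  std::unordered_map<long long, std::vector<int>> grid;
  grid.reserve((size_t)n * 2);
  std::vector<long long> cx(n), cy(n), cz(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = (long long)std::floor(xyz(i, 0) * inv);
    cy[i] = (long long)std::floor(xyz(i, 1) * inv);
    cz[i] = (long long)std::floor(xyz(i, 2) * inv);
    grid[cell_key(cx[i], cy[i], cz[i])].push_back(i);
  }
  const double r2 = radius * radius;
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          auto it = grid.find(cell_key(cx[i] + dx, cy[i] + dy, cz[i] + dz));
          if (it == grid.end()) continue;
          for (int k : it->second) {
            if (k == i) continue;
            const double ddx = xyz(k, 0) - xyz(i, 0);
            const double ddy = xyz(k, 1) - xyz(i, 1);
            const double ddz = xyz(k, 2) - xyz(i, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz <= r2) nb.push_back(k);
          }
        }
    const int m = (int)nb.size();
    if (m < 3) continue;
    arma::vec cen(3, arma::fill::zeros);
    for (int k : nb) cen += xyz.row(k).t();
    cen /= m;
    arma::mat cov(3, 3, arma::fill::zeros);
    for (int k : nb) {
      arma::vec d = xyz.row(k).t() - cen;
      cov += d * d.t();
    }
    cov /= m;
    arma::vec eval;
    arma::mat evec;
    if (!arma::eig_sym(eval, evec, cov)) continue;
    // eval ascending; collinear neighborhoods have two ~zero eigenvalues
    if (eval(2) <= 0 || eval(1) <= 1e-12 * eval(2)) continue;
    arma::vec nrm = evec.col(0);
    arma::vec d = xyz.row(i).t() - cen;
    out[i] = std::fabs(arma::dot(d, nrm));
  }
  return out;
}
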