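// Minimal conv-net kernels: im2col + GEMM convolution (same zero padding),
// its adjoints, and 2x2 max pooling. Layout: arma::cube is H x W x C; the
// weight matrix is (K*K*Cin) x Cout with column index q = ki + K*kj + K*K*c.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col_same(const cube& x, const int K) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, pad = K / 2;
  mat cols(H * (sword)W, (sword)K * K * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        const int q = ki + K * kj + K * K * c;
        const int di = ki - pad, dj = kj - pad;
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        for (int j = j0; j < j1; ++j) {
          double* dst = cols.colptr(q) + (sword)j * H;
          const double* src = xc.colptr(j + dj);
          for (int i = i0; i < i1; ++i) dst[i] = src[i + di];
        }
      }
    }
  }
  return cols;
}

// adjoint of im2col_same: scatter-add columns back onto the padded grid
static cube col2im_same(const mat& cols, const int H, const int W,
                        const int C, const int K) {
  const int pad = K / 2;
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& xc = x.slice(c);
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        const int q = ki + K * kj + K * K * c;
        const int di = ki - pad, dj = kj - pad;
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        for (int j = j0; j < j1; ++j) {
          const double* src = cols.colptr(q) + (sword)j * H;
          double* dst = xc.colptr(j + dj);
          for (int i = i0; i < i1; ++i) dst[i + di] += src[i];
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export(rng = false)]]
arma::cube nt_conv2d_fwd(const arma::cube& x, const arma::mat& w,
                         const arma::vec& b, const int K) {
  const int H = x.n_rows, W = x.n_cols, Cout = w.n_cols;
  mat y = im2col_same(x, K) * w;
  y.each_row() += b.t();
  return cube(y.memptr(), H, W, Cout);
}

// [[Rcpp::export(rng = false)]]
Rcpp::List nt_conv2d_bwd(const arma::cube& x, const arma::mat& w,
                         const arma::cube& gy, const int K) {
  const int H = x.n_rows, W = x.n_cols;
  const mat cols = im2col_same(x, K);
  const mat gym(const_cast<double*>(gy.memptr()), (sword)H * W, gy.n_slices,
                false, true);
  mat gw = cols.t() * gym;
  vec gb = sum(gym, 0).t();
  cube gx = col2im_same(gym * w.t(), H, W, x.n_slices, K);
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export(rng = false)]]
Rcpp::List nt_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  ucube idx(Ho, Wo, C); // linear index within the input slice
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        uword best = (uword)(2 * i) + (uword)(2 * j) * H;
        double v = xc(2 * i, 2 * j);
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const double u = xc(2 * i + di, 2 * j + dj);
            if (u > v) { v = u; best = (uword)(2 * i + di) + (uword)(2 * j + dj) * H; }
          }
        y(i, j, c) = v;
        idx(i, j, c) = best;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(rng = false)]]
arma::cube nt_maxpool2_bwd(const arma::ucube& idx, const arma::cube& gy,
                           const int H, const int W) {
  const int C = gy.n_slices, Ho = gy.n_rows, Wo = gy.n_cols;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& g = gx.slice(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) g(idx(i, j, c)) += gy(i, j, c);
  }
  return gx;
}
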