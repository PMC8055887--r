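// Low-level tensor kernels for the density-regression network.
// Feature maps are H x W x C cubes (matching R's array layout); a conv
// weight is a (kh*kw*cin) x cout matrix whose row index is
// i + kh*j + kh*kw*c for kernel row-offset i, col-offset j, input channel c.
// All convolutions are centered cross-correlations with zero padding
// ("same" output size); dilation spaces the kernel taps d pixels apart.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

static mat im2col_dil(const cube& x, int kh, int kw, int d) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int ph = (kh - 1) * d / 2, pw = (kw - 1) * d / 2;
  mat cols(kh * kw * C, H * W, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * j + kh * kw * c;
        const int di = i * d - ph, dj = j * d - pw;
        const int a0 = std::max(0, -di), a1 = std::min(H, H - di);
        const int b0 = std::max(0, -dj), b1 = std::min(W, W - dj);
        for (int b = b0; b < b1; ++b) {
          const double* src = xs.colptr(b + dj);
          double* dst = cols.colptr(0);
          for (int a = a0; a < a1; ++a)
            cols(r, a + H * b) = src[a + di];
          (void)dst;
        }
      }
    }
  }
  return cols;
}

// scatter-add transpose of im2col_dil
static void col2im_dil(const mat& cols, cube& gx, int kh, int kw, int d) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  const int ph = (kh - 1) * d / 2, pw = (kw - 1) * d / 2;
  for (int c = 0; c < C; ++c) {
    mat& gs = gx.slice(c);
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * j + kh * kw * c;
        const int di = i * d - ph, dj = j * d - pw;
        const int a0 = std::max(0, -di), a1 = std::min(H, H - di);
        const int b0 = std::max(0, -dj), b1 = std::min(W, W - dj);
        for (int b = b0; b < b1; ++b)
          for (int a = a0; a < a1; ++a)
            gs(a + di, b + dj) += cols(r, a + H * b);
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv2d_fw(const arma::cube& x, const arma::mat& w,
                     const arma::vec& b, int kh, int kw, int d) {
  const int H = x.n_rows, W = x.n_cols;
  const int cout = w.n_cols;
  mat cols = im2col_dil(x, kh, kw, d);
  mat out = w.t() * cols;          // cout x (H*W)
  out.each_col() += b;
  cube y(H, W, cout);
  for (int c = 0; c < cout; ++c)
    y.slice(c) = reshape(out.row(c).t(), H, W);
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bw(const arma::cube& x, const arma::mat& w,
                     const arma::cube& gy, int kh, int kw, int d) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int cout = gy.n_slices;
  mat G(cout, H * W);
  for (int c = 0; c < cout; ++c)
    G.row(c) = vectorise(gy.slice(c)).t();
  mat cols = im2col_dil(x, kh, kw, d);
  mat gW = cols * G.t();
  vec gb = sum(G, 1);
  mat gcols = w * G;               // (kh*kw*C) x (H*W)
  cube gx(H, W, C, fill::zeros);
  col2im_dil(gcols, gx, kh, kw, d);
  return Rcpp::List::create(Rcpp::Named("W") = gW,
                            Rcpp::Named("b") = gb,
                            Rcpp::Named("x") = gx);
}

// 2x2 max pooling, stride 2; idx records the flat argmax within x per output
// element so the backward pass can scatter gradients.
// [[Rcpp::export]]
Rcpp::List maxpool2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int b = 0; b < Wo; ++b) {
      for (int a = 0; a < Ho; ++a) {
        double best = -datum::inf; uword bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int r = 2 * a + di, cc = 2 * b + dj;
            const double v = xs(r, cc);
            if (v > best) { best = v; bi = r + H * cc; }
          }
        }
        y(a, b, c) = best;
        idx(a, b, c) = bi + (uword)c * H * W;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bw(const arma::cube& gy, const arma::ucube& idx,
                       int H, int W) {
  const int C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  const uword n = gy.n_elem;
  for (uword k = 0; k < n; ++k)
    gx(idx(k)) += gy(k);
  return gx;
}

// 2x nearest-neighbour upsampling.
// [[Rcpp::export]]
arma::cube upsample2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < W; ++b)
      for (int a = 0; a < H; ++a) {
        const double v = x(a, b, c);
        y(2 * a, 2 * b, c) = v; y(2 * a + 1, 2 * b, c) = v;
        y(2 * a, 2 * b + 1, c) = v; y(2 * a + 1, 2 * b + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube upsample2_bw(const arma::cube& gy) {
  const int H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < W; ++b)
      for (int a = 0; a < H; ++a)
        gx(a, b, c) = gy(2 * a, 2 * b, c) + gy(2 * a + 1, 2 * b, c) +
                      gy(2 * a, 2 * b + 1, c) + gy(2 * a + 1, 2 * b + 1, c);
  return gx;
}
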