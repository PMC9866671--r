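// Low-level numeric kernels for the segmentation networks.
// Arrays follow R's column-major layout: an H x W x C feature map is an
// arma::cube with n_rows = H, n_cols = W, n_slices = C.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Build the im2col matrix: one row per output pixel (column-major pixel
// order), one column per (kernel row, kernel col, input channel) triple.
static arma::mat im2col(const arma::cube& x, int kh, int kw,
                        int pad, int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H, Wo = W; // stride 1, 'same' geometry governed by pad
  arma::mat cols(Ho * (size_t)Wo, (size_t)kh * kw * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const size_t col = (size_t)c * kh * kw + (size_t)kj * kh + ki;
        const int di = ki * dil - pad, dj = kj * dil - pad;
        for (int j = 0; j < Wo; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, -di), i1 = std::min(Ho, H - di);
          for (int i = i0; i < i1; ++i)
            cols((size_t)j * Ho + i, col) = x(i + di, sj, c);
        }
      }
    }
  }
  return cols;
}

// Scatter-add of a cols-shaped gradient back onto the input grid.
static arma::cube col2im(const arma::mat& dcols, int H, int W, int C,
                         int kh, int kw, int pad, int dil) {
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const size_t col = (size_t)c * kh * kw + (size_t)kj * kh + ki;
        const int di = ki * dil - pad, dj = kj * dil - pad;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int i = i0; i < i1; ++i)
            dx(i + di, sj, c) += dcols((size_t)j * H + i, col);
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::cube& w,
                      const arma::vec& b, int cout,
                      int pad, int dil) {
  // w arrives as kh x kw x (cin*cout); reshape to (kh*kw*cin) x cout
  const int H = x.n_rows, W = x.n_cols;
  const int cin = x.n_slices;
  const int kh = w.n_rows, kw = w.n_cols;
  arma::mat wm(const_cast<double*>(w.memptr()),
               (size_t)kh * kw * cin, cout, false, true);
  arma::mat cols = im2col(x, kh, kw, pad, dil);
  arma::mat y = cols * wm;
  y.each_row() += b.t();
  arma::cube out(H, W, cout);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(const arma::cube& x, const arma::cube& w,
                const arma::cube& dy, int pad, int dil) {
  const int H = x.n_rows, W = x.n_cols;
  const int cin = x.n_slices, cout = dy.n_slices;
  const int kh = w.n_rows, kw = w.n_cols;
  arma::mat wm(const_cast<double*>(w.memptr()),
               (size_t)kh * kw * cin, cout, false, true);
  arma::mat dym(const_cast<double*>(dy.memptr()),
                (size_t)H * W, cout, false, true);
  arma::mat cols = im2col(x, kh, kw, pad, dil);
  arma::mat dwm = cols.t() * dym;
  arma::vec db = arma::sum(dym, 0).t();
  arma::mat dcols = dym * wm.t();
  arma::cube dx = col2im(dcols, H, W, cin, kh, kw, pad, dil);
  arma::cube dw(kh, kw, (size_t)cin * cout);
  std::memcpy(dw.memptr(), dwm.memptr(), sizeof(double) * dwm.n_elem);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 non-overlapping max pooling; records argmax for the backward pass.
// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C); // linear index into the input slice
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = -1e300; arma::uword bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int ii = 2 * i + di, jj = 2 * j + dj;
            const double v = x(ii, jj, c);
            if (v > best) { best = v; bi = (arma::uword)jj * H + ii; }
          }
        y(i, j, c) = best; idx(i, j, c) = bi;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
arma::cube maxpool2_bwd(const arma::cube& dy, const arma::ucube& idx,
                        int H, int W) {
  const int C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* slice = dx.slice_memptr(c);
    for (arma::uword k = 0; k < dy.n_rows * dy.n_cols; ++k)
      slice[idx.slice(c)(k)] += dy.slice(c)(k);
  }
  return dx;
}
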