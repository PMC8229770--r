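// Numerical kernels for the recurrent segmentation network and the surface
// metrics.  Layout conventions (match the R side exactly):
//   * feature maps are H x W x C arma::cubes (column-major, row index fastest);
//   * convolution weights are flattened from an R array of dim
//     (kh, kw, c_in, c_out), i.e. kernel-row index fastest;
//   * convolutions are stride 1 with zero "same" padding and odd kernels.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Patch matrix P: one row per output pixel (r + H*s), one column per
// (i, j, c) kernel tap with index i + kh*(j + kw*c).
static mat im2col(const cube& x, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  mat P(H * W, kh * kw * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int col = i + kh * (j + kw * c);
        const int r0 = std::max(0, ph - i), r1 = std::min(H, H + ph - i);
        const int s0 = std::max(0, pw - j), s1 = std::min(W, W + pw - j);
        if (r1 <= r0) continue;
        for (int s = s0; s < s1; ++s) {
          const double* src = &x(r0 + i - ph, s + j - pw, c);
          double* dst = &P(r0 + H * s, col);
          std::memcpy(dst, src, sizeof(double) * (r1 - r0));
        }
      }
    }
  }
  return P;
}

// Scatter-add transpose of im2col.
static cube col2im(const mat& dP, int H, int W, int C, int kh, int kw) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int col = i + kh * (j + kw * c);
        const int r0 = std::max(0, ph - i), r1 = std::min(H, H + ph - i);
        const int s0 = std::max(0, pw - j), s1 = std::min(W, W + pw - j);
        if (r1 <= r0) continue;
        for (int s = s0; s < s1; ++s) {
          const double* src = &dP(r0 + H * s, col);
          double* dst = &dx(r0 + i - ph, s + j - pw, c);
          for (int r = 0; r < r1 - r0; ++r) dst[r] += src[r];
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
arma::cube conv2d_fwd_cpp(const arma::cube& x, const arma::vec& w,
                          const arma::vec& b, int kh, int kw, int cout) {
  const int H = x.n_rows, W = x.n_cols, cin = x.n_slices;
  mat P = im2col(x, kh, kw);
  const mat Wm(const_cast<double*>(w.memptr()), kh * kw * cin, cout, false, true);
  mat Y = P * Wm;
  Y.each_row() += b.t();
  cube out(H, W, cout);
  std::memcpy(out.memptr(), Y.memptr(), sizeof(double) * H * W * cout);
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
Rcpp::List conv2d_bwd_cpp(const arma::cube& x, const arma::vec& w,
                          const arma::cube& dy, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols, cin = x.n_slices, cout = dy.n_slices;
  mat P = im2col(x, kh, kw);
  const mat dY(const_cast<double*>(dy.memptr()), H * W, cout, false, true);
  const mat Wm(const_cast<double*>(w.memptr()), kh * kw * cin, cout, false, true);
  mat dW = P.t() * dY;
  vec db = sum(dY, 0).t();
  mat dP = dY * Wm.t();
  cube dx = col2im(dP, H, W, cin, kh, kw);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = vec(dW.memptr(), dW.n_elem),
                            Rcpp::Named("db") = db);
}

// 2x2 max pooling, stride 2; records the winning offset (dr + 2*ds) per cell.
// [[Rcpp::export(name = ".maxpool2_fwd")]]
Rcpp::List maxpool2_fwd_cpp(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C), idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int s = 0; s < Wo; ++s) {
      for (int r = 0; r < Ho; ++r) {
        double best = x(2 * r, 2 * s, c);
        int which = 0;
        for (int ds = 0; ds < 2; ++ds) {
          for (int dr = 0; dr < 2; ++dr) {
            const double v = x(2 * r + dr, 2 * s + ds, c);
            if (v > best) { best = v; which = dr + 2 * ds; }
          }
        }
        y(r, s, c) = best;
        idx(r, s, c) = which;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
arma::cube maxpool2_bwd_cpp(const arma::cube& dy, const arma::cube& idx,
                            int H, int W) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int s = 0; s < Wo; ++s) {
      for (int r = 0; r < Ho; ++r) {
        const int which = (int) idx(r, s, c);
        dx(2 * r + which % 2, 2 * s + which / 2, c) += dy(r, s, c);
      }
    }
  }
  return dx;
}

// Nearest-neighbour x2 upsampling and its adjoint (2x2 block sum).
// [[Rcpp::export(name = ".upsample2_fwd")]]
arma::cube upsample2_fwd_cpp(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int s = 0; s < W; ++s)
      for (int r = 0; r < H; ++r) {
        const double v = x(r, s, c);
        y(2 * r, 2 * s, c) = v;
        y(2 * r + 1, 2 * s, c) = v;
        y(2 * r, 2 * s + 1, c) = v;
        y(2 * r + 1, 2 * s + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bwd")]]
arma::cube upsample2_bwd_cpp(const arma::cube& dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  cube dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int s = 0; s < W; ++s)
      for (int r = 0; r < H; ++r)
        dx(r, s, c) = dy(2 * r, 2 * s, c) + dy(2 * r + 1, 2 * s, c) +
                      dy(2 * r, 2 * s + 1, c) + dy(2 * r + 1, 2 * s + 1, c);
  return dx;
}

// For each row of A (n x d), the Euclidean distance to the nearest row of B.
// Exact double loop: surface point sets at phantom/clinical scale are small
// enough that O(n*m) dominates neither training nor evaluation.
// [[Rcpp::export(name = ".nn_min_dists")]]
arma::vec nn_min_dists_cpp(const arma::mat& A, const arma::mat& B) {
  const int n = A.n_rows, m = B.n_rows, d = A.n_cols;
  vec out(n);
  for (int i = 0; i < n; ++i) {
    double best = datum::inf;
    for (int j = 0; j < m; ++j) {
      double acc = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = A(i, k) - B(j, k);
        acc += diff * diff;
      }
      if (acc < best) best = acc;
    }
    out(i) = std::sqrt(best);
  }
  return out;
}
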