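// Minimal stride-1 convolution / pooling kernels used by the network layers.
// Layout conventions (match R's column-major arrays):
//   activations: arma::cube (H, W, C)
//   conv weights: arma::mat (k*k*Cin, Cout), patch index = c*k*k + dj*k + di
// Padding is symmetric zero padding of (k-1)/2, so output size equals input
// size. im2col/col2im move whole submatrix blocks per (di, dj, c) shift.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = (k - 1) / 2;
  mat patches(H * W, k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      const int lo_j = std::max(0, pad - dj);
      const int hi_j = std::min(W - 1, W - 1 + pad - dj);
      if (lo_j > hi_j) continue;
      for (int di = 0; di < k; ++di) {
        const int lo_i = std::max(0, pad - di);
        const int hi_i = std::min(H - 1, H - 1 + pad - di);
        if (lo_i > hi_i) continue;
        const int col = c * k * k + dj * k + di;
        mat view(patches.colptr(col), H, W, false, true);
        view.submat(lo_i, lo_j, hi_i, hi_j) =
          x.slice(c).submat(lo_i + di - pad, lo_j + dj - pad,
                            hi_i + di - pad, hi_j + dj - pad);
      }
    }
  }
  return patches;
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, const int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  mat y = im2col(x, k) * w;
  y.each_row() += b.t();
  cube out(H, W, Cout);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd(const arma::cube& x, const arma::mat& w,
                      const arma::cube& dy, const int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_cols;
  const int pad = (k - 1) / 2;
  const mat dymat(const_cast<double*>(dy.memptr()), H * W, Cout, false,
                  true);
  mat patches = im2col(x, k);
  mat dw = patches.t() * dymat;
  vec db = sum(dymat, 0).t();
  mat dpatches = dymat * w.t();
  cube dx(H, W, Cin, fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      const int lo_j = std::max(0, pad - dj);
      const int hi_j = std::min(W - 1, W - 1 + pad - dj);
      if (lo_j > hi_j) continue;
      for (int di = 0; di < k; ++di) {
        const int lo_i = std::max(0, pad - di);
        const int hi_i = std::min(H - 1, H - 1 + pad - di);
        if (lo_i > hi_i) continue;
        const int col = c * k * k + dj * k + di;
        const mat view(dpatches.colptr(col), H, W, false, true);
        dx.slice(c).submat(lo_i + di - pad, lo_j + dj - pad,
                           hi_i + di - pad, hi_j + dj - pad) +=
          view.submat(lo_i, lo_j, hi_i, hi_j);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// 2x2 max pooling, stride 2. idx holds 1-based linear indices into x per
// output element so the backward pass can route gradients to the argmax.
// [[Rcpp::export]]
Rcpp::List maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  cube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -datum::inf;
        int besti = 0, bestj = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; besti = 2 * i + di; bestj = 2 * j + dj; }
          }
        }
        y(i, j, c) = best;
        idx(i, j, c) = 1 + besti + bestj * H + c * H * W;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd(const arma::cube& dy, const arma::cube& idx,
                        const int H, const int W) {
  const int C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  const uword n = dy.n_elem;
  for (uword t = 0; t < n; ++t)
    dx(static_cast<uword>(idx(t)) - 1) += dy(t);
  return dx;
}
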