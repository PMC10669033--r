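// 3x3 same-padding convolution via im2col + BLAS matmul.
// Activation layout everywhere: column-major array (H, W, N, C) flattened,
// i.e. element (h, w, n, c) sits at h + w*H + n*H*W + c*H*W*N.
// A batch is equivalently a (H*W*N) x C matrix whose rows run h-fastest.
// Weight matrix Wm: (9*Cin) x Cout with row index c*9 + k where
// k encodes the kernel offset (dy = k%3 - 1, dx = k/3 - 1).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static mat im2col3(const vec& Xv, int H, int W, int N, int Cin) {
  const int HW = H * W;
  mat col(static_cast<size_t>(HW) * N, static_cast<size_t>(9) * Cin,
          fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    for (int n = 0; n < N; ++n) {
      const double* xp = Xv.memptr() + (static_cast<size_t>(c) * N + n) * HW;
      for (int k = 0; k < 9; ++k) {
        int dy = k % 3 - 1, dx = k / 3 - 1;
        double* cp = col.colptr(c * 9 + k) + static_cast<size_t>(n) * HW;
        for (int w = 0; w < W; ++w) {
          int ws = w + dx;
          if (ws < 0 || ws >= W) continue;
          int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);
          const double* src = xp + static_cast<size_t>(ws) * H + dy;
          double* dst = cp + static_cast<size_t>(w) * H;
          for (int h = h0; h < h1; ++h) dst[h] = src[h];
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
Rcpp::List conv3_forward(const arma::vec& Xv, int H, int W, int N, int Cin,
                         const arma::mat& Wm, const arma::vec& bias) {
  mat col = im2col3(Xv, H, W, N, Cin);
  mat out = col * Wm;
  out.each_row() += bias.t();
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("col") = col);
}

// [[Rcpp::export]]
Rcpp::List conv3_backward(const arma::mat& col, const arma::mat& Wm,
                          const arma::mat& dOut, int H, int W, int N,
                          int Cin) {
  mat dW = col.t() * dOut;
  vec db = sum(dOut, 0).t();
  mat dcol = dOut * Wm.t();
  const int HW = H * W;
  vec dX(static_cast<size_t>(HW) * N * Cin, fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    for (int n = 0; n < N; ++n) {
      double* xp = dX.memptr() + (static_cast<size_t>(c) * N + n) * HW;
      for (int k = 0; k < 9; ++k) {
        int dy = k % 3 - 1, dx = k / 3 - 1;
        const double* cp = dcol.colptr(c * 9 + k) + static_cast<size_t>(n) * HW;
        for (int w = 0; w < W; ++w) {
          int ws = w + dx;
          if (ws < 0 || ws >= W) continue;
          int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);
          double* dst = xp + static_cast<size_t>(ws) * H + dy;
          const double* src = cp + static_cast<size_t>(w) * H;
          for (int h = h0; h < h1; ++h) dst[h] += src[h];
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
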