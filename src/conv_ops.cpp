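#include <Rcpp.h>
using namespace Rcpp;

// Patch extraction for batched 2-D convolution.
//
// x is an H x W x C x N array (column-major, as R stores it). Returns a
// matrix with one row per output pixel per sample (row index
// h' + Ho*w' + Ho*Wo*n) and one column per kernel tap per input channel
// (column index kh + K*kw + K*K*c). Out-of-image taps are zero (zero
// padding). Convolution is then a single GEMM against a (K*K*C) x F
// weight matrix.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int K, int stride, int pad) {
  const int Ho = (H + 2 * pad - K) / stride + 1;
  const int Wo = (W + 2 * pad - K) / stride + 1;
  const R_xlen_t nrow = (R_xlen_t)Ho * Wo * N;
  const int ncol = K * K * C;
  NumericMatrix out(nrow, ncol);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        const int q = kh + K * kw + K * K * c;
        double* col = op + (R_xlen_t)q * nrow;
        for (int n = 0; n < N; ++n) {
          const double* xn = xp + ((R_xlen_t)n * C + c) * H * W;
          for (int wo = 0; wo < Wo; ++wo) {
            const int w = wo * stride - pad + kw;
            const R_xlen_t rbase = (R_xlen_t)n * Ho * Wo + (R_xlen_t)wo * Ho;
            if (w < 0 || w >= W) continue;
            const double* xcolw = xn + (R_xlen_t)w * H;
            for (int ho = 0; ho < Ho; ++ho) {
              const int h = ho * stride - pad + kh;
              if (h < 0 || h >= H) continue;
              col[rbase + ho] = xcolw[h];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cpp: scatter-adds column gradients back to the input
// array. Used for the gradient with respect to the convolution input.

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int K, int stride, int pad) {
  const int Ho = (H + 2 * pad - K) / stride + 1;
  const int Wo = (W + 2 * pad - K) / stride + 1;
  const R_xlen_t nrow = (R_xlen_t)Ho * Wo * N;
  NumericVector x((R_xlen_t)H * W * C * N);
  const double* cp = cols.begin();
  double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        const int q = kh + K * kw + K * K * c;
        const double* col = cp + (R_xlen_t)q * nrow;
        for (int n = 0; n < N; ++n) {
          double* xn = xp + ((R_xlen_t)n * C + c) * H * W;
          for (int wo = 0; wo < Wo; ++wo) {
            const int w = wo * stride - pad + kw;
            if (w < 0 || w >= W) continue;
            double* xcolw = xn + (R_xlen_t)w * H;
            const R_xlen_t rbase = (R_xlen_t)n * Ho * Wo + (R_xlen_t)wo * Ho;
            for (int ho = 0; ho < Ho; ++ho) {
              const int h = ho * stride - pad + kh;
              if (h < 0 || h >= H) continue;
              xcolw[h] += col[rbase + ho];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  return x;
}
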