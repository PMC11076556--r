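#include <Rcpp.h>
using namespace Rcpp;

// im2col gather for 1-D convolution.
// X: array (B, L, C); returns matrix (B*P) x (k*C) with row index
// (b, p) b-fastest and column index z = (c-1)*k + j, matching the
// weight-matrix layout used by the R-side layers.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector X, int B, int L, int C,
                         int k, int stride, int P) {
  NumericMatrix out(B * P, k * C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < k; ++j) {
      int z = c * k + j;
      for (int p = 0; p < P; ++p) {
        int t = p * stride + j;           // time index in X
        const double *src = &X[(size_t)c * B * L + (size_t)t * B];
        double *dst = &out[(size_t)z * B * P + (size_t)p * B];
        for (int b = 0; b < B; ++b) dst[b] = src[b];
      }
    }
  }
  return out;
}

// Scatter-add inverse of im2col: dY (B*P) x (k*C) -> array (B, L, C).
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix dY, int B, int L, int C,
                         int k, int stride, int P) {
  NumericVector dX((size_t)B * L * C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < k; ++j) {
      int z = c * k + j;
      for (int p = 0; p < P; ++p) {
        int t = p * stride + j;
        double *dst = &dX[(size_t)c * B * L + (size_t)t * B];
        const double *src = &dY[(size_t)z * B * P + (size_t)p * B];
        for (int b = 0; b < B; ++b) dst[b] += src[b];
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(B, L, C);
  return dX;
}

// In-place-style ReLU (returns a modified copy).
// [[Rcpp::export]]
NumericVector relu_cpp(NumericVector x) {
  NumericVector y = clone(x);
  for (R_xlen_t i = 0; i < y.size(); ++i) if (y[i] < 0) y[i] = 0;
  return y;
}
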