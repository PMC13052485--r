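// 1D convolution kernels (im2col + BLAS gemm via Armadillo).
//
// Activation tensors are passed as flat numeric vectors with explicit dims
// (channels, length, batch), matching the column-major R layout. The im2col
// matrix has rows indexed tap-major ((t-1)*C + c) and columns sample-major
// ((n-1)*L_out + j), the layout the R-side weight matrices assume.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_len(int L, int k, int stride, int pad) {
  return (L + 2 * pad - k) / stride + 1;
}

static arma::mat build_cols(const double* x, int C, int L, int N,
                            int k, int stride, int pad) {
  const int Lo = out_len(L, k, stride, pad);
  arma::mat cols(C * k, (arma::uword)Lo * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)n * C * L;
    for (int j = 0; j < Lo; ++j) {
      double* col = cols.colptr((arma::uword)n * Lo + j);
      const int start = j * stride - pad;
      for (int t = 0; t < k; ++t) {
        const int pos = start + t;
        if (pos >= 0 && pos < L) {
          const double* src = xn + (size_t)pos * C;
          double* dst = col + (size_t)t * C;
          for (int c = 0; c < C; ++c) dst[c] = src[c];
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export(name = ".conv1d_forward_cpp")]]
List conv1d_forward_cpp(NumericVector x, IntegerVector xdim,
                        NumericMatrix W, int stride, int pad) {
  const int C = xdim[0], L = xdim[1], N = xdim[2];
  const int k = W.ncol() / C;
  const int Lo = out_len(L, k, stride, pad);
  arma::mat cols = build_cols(x.begin(), C, L, N, k, stride, pad);
  arma::mat Wm(W.begin(), W.nrow(), W.ncol(), false, true);
  arma::mat y = Wm * cols;
  NumericVector yv(y.begin(), y.end());
  yv.attr("dim") = IntegerVector::create(W.nrow(), Lo, N);
  return List::create(_["y"] = yv, _["cols"] = wrap(cols));
}

// [[Rcpp::export(name = ".conv1d_backward_cpp")]]
List conv1d_backward_cpp(NumericVector dy, NumericMatrix cols,
                         NumericMatrix W, IntegerVector xdim,
                         int stride, int pad, bool need_dx) {
  const int C = xdim[0], L = xdim[1], N = xdim[2];
  const int Co = W.nrow();
  const int k = W.ncol() / C;
  const int Lo = out_len(L, k, stride, pad);
  arma::mat dym(dy.begin(), Co, (arma::uword)Lo * N, false, true);
  arma::mat colsm(cols.begin(), cols.nrow(), cols.ncol(), false, true);
  arma::mat Wm(W.begin(), Co, W.ncol(), false, true);
  arma::mat dW = dym * colsm.t();
  NumericVector dxv;
  if (need_dx) {
    arma::mat dcols = Wm.t() * dym;  // (C*k) x (Lo*N)
    dxv = NumericVector((size_t)C * L * N);
    double* dx = dxv.begin();
    for (int n = 0; n < N; ++n) {
      double* xn = dx + (size_t)n * C * L;
      for (int j = 0; j < Lo; ++j) {
        const double* col = dcols.colptr((arma::uword)n * Lo + j);
        const int start = j * stride - pad;
        for (int t = 0; t < k; ++t) {
          const int pos = start + t;
          if (pos >= 0 && pos < L) {
            double* dst = xn + (size_t)pos * C;
            const double* src = col + (size_t)t * C;
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
    dxv.attr("dim") = IntegerVector::create(C, L, N);
  }
  return List::create(_["dW"] = wrap(dW), _["dx"] = dxv);
}
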