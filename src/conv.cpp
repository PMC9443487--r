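// Stride-1 2-D cross-correlation kernels (im2col + BLAS GEMM).
//
// Tensors arrive from R as (channel, height, width, batch) column-major
// arrays; weights as (c_out, c_in, k, k). The unrolled-in-time training
// loop spends nearly all of its arithmetic here, so these paths avoid the
// R allocator and do one large GEMM per call.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Gather x (cin, H, W, N) into columns (cin*k*k, H*W*N) for padding `pad`.
static mat im2col(const double* x, int cin, int H, int W, int N,
                  int k, int pad) {
  const int M = H * W * N;
  mat col(cin * k * k, M, fill::zeros);
  double* c = col.memptr();
  const int rows = cin * k * k;
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)n * cin * H * W;
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double* dst = c + (size_t)rows * (i + H * (j + (size_t)W * n));
        for (int kj = 0; kj < k; ++kj) {
          int sj = j + kj - pad;
          if (sj < 0 || sj >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            int si = i + ki - pad;
            if (si < 0 || si >= H) continue;
            const double* src = xn + cin * (si + (size_t)H * sj);
            std::copy(src, src + cin, dst + cin * (ki + k * kj));
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
Rcpp::NumericVector cpp_conv2d_fwd(const Rcpp::NumericVector& x,
                                   const Rcpp::IntegerVector& xdim,
                                   const Rcpp::NumericVector& w,
                                   const Rcpp::IntegerVector& wdim,
                                   const Rcpp::NumericVector& b,
                                   int pad) {
  const int cin = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  const int cout = wdim[0], k = wdim[2];
  const int M = H * W * N;
  mat col = im2col(x.begin(), cin, H, W, N, k, pad);
  // reorder weights (cout, cin, ki, kj) -> (cout) x (cin*k*k) with rows of
  // col grouped as (cin, ki, kj)
  mat Wm(cout, cin * k * k);
  for (int kj = 0; kj < k; ++kj)
    for (int ki = 0; ki < k; ++ki)
      for (int ci = 0; ci < cin; ++ci) {
        int r = ci + cin * (ki + k * kj);
        for (int co = 0; co < cout; ++co)
          Wm(co, r) = w[co + (size_t)cout * (ci + cin * (ki + k * kj))];
      }
  mat Y = Wm * col;
  Y.each_col() += vec(b.begin(), cout);
  Rcpp::NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = Rcpp::IntegerVector::create(cout, H, W, N);
  return out;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
Rcpp::List cpp_conv2d_bwd(const Rcpp::NumericVector& dy,
                          const Rcpp::NumericVector& x,
                          const Rcpp::IntegerVector& xdim,
                          const Rcpp::NumericVector& w,
                          const Rcpp::IntegerVector& wdim,
                          int pad) {
  const int cin = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  const int cout = wdim[0], k = wdim[2];
  const int M = H * W * N;
  mat dym(const_cast<double*>(dy.begin()), cout, M, false, true);
  vec db = sum(dym, 1);

  mat col = im2col(x.begin(), cin, H, W, N, k, pad);
  mat dWm = dym * col.t();  // cout x (cin*k*k), rows grouped (cin, ki, kj)
  Rcpp::NumericVector dW(cout * cin * k * k);
  for (int kj = 0; kj < k; ++kj)
    for (int ki = 0; ki < k; ++ki)
      for (int ci = 0; ci < cin; ++ci) {
        int r = ci + cin * (ki + k * kj);
        for (int co = 0; co < cout; ++co)
          dW[co + (size_t)cout * (ci + cin * (ki + k * kj))] = dWm(co, r);
      }
  dW.attr("dim") = wdim;

  // dx: scatter dcol back (col2im adjoint of the gather above)
  mat Wm(cout, cin * k * k);
  for (int kj = 0; kj < k; ++kj)
    for (int ki = 0; ki < k; ++ki)
      for (int ci = 0; ci < cin; ++ci) {
        int r = ci + cin * (ki + k * kj);
        for (int co = 0; co < cout; ++co)
          Wm(co, r) = w[co + (size_t)cout * (ci + cin * (ki + k * kj))];
      }
  mat dcol = Wm.t() * dym;  // (cin*k*k) x M
  Rcpp::NumericVector dx(cin * H * W * N);
  double* dxp = dx.begin();
  const double* dc = dcol.memptr();
  const int rows = cin * k * k;
  for (int n = 0; n < N; ++n) {
    double* dxn = dxp + (size_t)n * cin * H * W;
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const double* src0 = dc + (size_t)rows * (i + H * (j + (size_t)W * n));
        for (int kj = 0; kj < k; ++kj) {
          int sj = j + kj - pad;
          if (sj < 0 || sj >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            int si = i + ki - pad;
            if (si < 0 || si >= H) continue;
            double* dst = dxn + cin * (si + (size_t)H * sj);
            const double* src = src0 + cin * (ki + k * kj);
            for (int c = 0; c < cin; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  dx.attr("dim") = xdim;
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") =
                              Rcpp::NumericVector(db.begin(), db.end()));
}
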