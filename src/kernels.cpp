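// Hot numerical kernels for the CNN engine: fused batch-norm forward and
// backward, max-pooling with argmax bookkeeping, ReLU, and the col2im
// scatter-add used by the convolution backward pass.  Everything operates
// on R's column-major layouts; matrix products stay in R/BLAS.

#include <Rcpp.h>
using namespace Rcpp;

// Batch-norm training forward: one pass for per-channel mean/var, then the
// normalized, scaled output.  x is (M x C), column = channel.
// [[Rcpp::export]]
List bn_train_forward_cpp(const NumericMatrix& x, const NumericVector& gamma,
                          const NumericVector& beta, double eps) {
  const int M = x.nrow(), C = x.ncol();
  NumericMatrix y(M, C);
  NumericVector mu(C), ivar(C), var(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    double s = 0.0, ss = 0.0;
    for (int i = 0; i < M; ++i) { s += xc[i]; ss += xc[i] * xc[i]; }
    const double m = s / M;
    double v = ss / M - m * m;
    if (v < 0) v = 0;
    mu[c] = m; var[c] = v;
    const double iv = 1.0 / std::sqrt(v + eps);
    ivar[c] = iv;
    const double a = gamma[c] * iv;
    const double b = beta[c] - m * a;
    double* yc = &y(0, c);
    for (int i = 0; i < M; ++i) yc[i] = a * xc[i] + b;
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["ivar"] = ivar,
                      _["var"] = var);
}

// Inference-mode batch norm: per-channel affine with precomputed
// scale/shift.
// [[Rcpp::export]]
NumericMatrix bn_eval_forward_cpp(const NumericMatrix& x,
                                  const NumericVector& scale,
                                  const NumericVector& shift) {
  const int M = x.nrow(), C = x.ncol();
  NumericMatrix y(M, C);
  for (int c = 0; c < C; ++c) {
    const double a = scale[c], b = shift[c];
    const double* xc = &x(0, c);
    double* yc = &y(0, c);
    for (int i = 0; i < M; ++i) yc[i] = a * xc[i] + b;
  }
  return y;
}

// Batch-norm backward (training statistics).  Recomputes xhat from the
// cached input to avoid storing it.
// [[Rcpp::export]]
List bn_backward_cpp(const NumericMatrix& dy, const NumericMatrix& x,
                     const NumericVector& mu, const NumericVector& ivar,
                     const NumericVector& gamma) {
  const int M = dy.nrow(), C = dy.ncol();
  NumericMatrix dx(M, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dyc = &dy(0, c);
    const double* xc = &x(0, c);
    const double m = mu[c], iv = ivar[c];
    double sdy = 0.0, sdyx = 0.0;
    for (int i = 0; i < M; ++i) {
      const double xh = (xc[i] - m) * iv;
      sdy += dyc[i];
      sdyx += dyc[i] * xh;
    }
    dbeta[c] = sdy;
    dgamma[c] = sdyx;
    const double a = gamma[c] * iv;
    const double t1 = sdy / M, t2 = sdyx / M;
    double* dxc = &dx(0, c);
    for (int i = 0; i < M; ++i) {
      const double xh = (xc[i] - m) * iv;
      dxc[i] = a * (dyc[i] - t1 - xh * t2);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Max pooling over non-overlapping (ph x pw) windows on an (N, H, W, C)
// array; remainder rows/columns are dropped.  `code` records the winning
// in-window offset for the backward scatter.
// [[Rcpp::export]]
List maxpool_forward_cpp(const NumericVector& x, int N, int H, int W, int C,
                         int ph, int pw) {
  const int Ho = H / ph, Wo = W / pw;
  NumericVector out((R_xlen_t)N * Ho * Wo * C);
  IntegerVector code((R_xlen_t)N * Ho * Wo * C);
  const double* xp = x.begin();
  double* op = out.begin();
  int* cp = code.begin();
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t obase = (R_xlen_t)N * (ho + Ho * (wo + (R_xlen_t)Wo * c));
        for (int pi = 0; pi < ph; ++pi)
          for (int pj = 0; pj < pw; ++pj) {
            const int h = ho * ph + pi, w = wo * pw + pj;
            const R_xlen_t ibase = (R_xlen_t)N * (h + H * (w + (R_xlen_t)W * c));
            const int off = pi * pw + pj + 1;
            if (pi == 0 && pj == 0) {
              for (int n = 0; n < N; ++n) {
                op[obase + n] = xp[ibase + n];
                cp[obase + n] = off;
              }
            } else {
              for (int n = 0; n < N; ++n) {
                if (xp[ibase + n] > op[obase + n]) {
                  op[obase + n] = xp[ibase + n];
                  cp[obase + n] = off;
                }
              }
            }
          }
      }
  out.attr("dim") = IntegerVector::create(N, Ho, Wo, C);
  return List::create(_["out"] = out, _["code"] = code);
}

// [[Rcpp::export]]
NumericVector maxpool_backward_cpp(const NumericVector& dout,
                                   const IntegerVector& code,
                                   int N, int H, int W, int C,
                                   int ph, int pw) {
  const int Ho = H / ph, Wo = W / pw;
  NumericVector dx((R_xlen_t)N * H * W * C);   // zero-initialized
  const double* dp = dout.begin();
  const int* cp = code.begin();
  double* xp = dx.begin();
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t obase = (R_xlen_t)N * (ho + Ho * (wo + (R_xlen_t)Wo * c));
        for (int n = 0; n < N; ++n) {
          const int off = cp[obase + n] - 1;
          const int pi = off / pw, pj = off % pw;
          const int h = ho * ph + pi, w = wo * pw + pj;
          xp[(R_xlen_t)N * (h + H * (w + (R_xlen_t)W * c)) + n] = dp[obase + n];
        }
      }
  dx.attr("dim") = IntegerVector::create(N, H, W, C);
  return dx;
}

// col2im scatter-add: dA is (N x HW*K) with column (j, k) mapping to padded
// position idx[j, k] (1-based, length HW*K); accumulates into (N x P).
// [[Rcpp::export]]
NumericMatrix col2im_cpp(const NumericMatrix& dA, const IntegerVector& idx,
                         int P) {
  const int N = dA.nrow();
  const R_xlen_t J = idx.size();
  NumericMatrix dXp(N, P);
  for (R_xlen_t j = 0; j < J; ++j) {
    const double* src = &dA(0, j);
    double* dst = &dXp(0, idx[j] - 1);
    for (int n = 0; n < N; ++n) dst[n] += src[n];
  }
  return dXp;
}

// [[Rcpp::export]]
NumericVector relu_forward_cpp(const NumericVector& x) {
  NumericVector y(clone(x));
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < y.size(); ++i) if (yp[i] < 0) yp[i] = 0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector relu_backward_cpp(const NumericVector& dout,
                                const NumericVector& y) {
  NumericVector dx(clone(dout));
  double* dp = dx.begin();
  const double* yp = y.begin();
  for (R_xlen_t i = 0; i < dx.size(); ++i) if (yp[i] <= 0) dp[i] = 0;
  dx.attr("dim") = dout.attr("dim");
  return dx;
}
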