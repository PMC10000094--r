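// Inner loops of the im2col convolution lowering. The matrix products
// themselves stay in R (BLAS); these kernels only do the gather/scatter
// and layout changes that are slow as vectorized R.

#include <Rcpp.h>
using namespace Rcpp;

// Gather the im2col matrix. X: (S, C, N) feature array; spi: (P, K2)
// spatial indices into 1..S, 0 marking zero padding. Returns (P*N, K2*C).
// [[Rcpp::export]]
NumericMatrix im2col_gather(NumericVector X, IntegerMatrix spi,
                            int S, int C, int N) {
  const int P = spi.nrow(), K2 = spi.ncol();
  NumericMatrix M(P * N, K2 * C);
  const double* x = X.begin();
  double* m = M.begin();
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < K2; ++k) {
      const int col = k + K2 * c;
      double* mcol = m + (R_xlen_t)col * P * N;
      const int* sp = &spi(0, k);
      for (int n = 0; n < N; ++n) {
        const double* xn = x + (R_xlen_t)S * (c + (R_xlen_t)C * n);
        double* dst = mcol + (R_xlen_t)P * n;
        for (int p = 0; p < P; ++p) {
          const int s = sp[p];
          dst[p] = s ? xn[s - 1] : 0.0;
        }
      }
    }
  }
  return M;
}

// Scatter-add the gradient of the im2col matrix back to the input
// layout. dM: (P*N, K2*C); returns (S, C, N).
// [[Rcpp::export]]
NumericVector col2im_scatter(NumericMatrix dM, IntegerMatrix spi,
                             int S, int C, int N) {
  const int P = spi.nrow(), K2 = spi.ncol();
  NumericVector dX(Dimension(S, C, N));
  double* dx = dX.begin();
  const double* dm = dM.begin();
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < K2; ++k) {
      const int col = k + K2 * c;
      const double* mcol = dm + (R_xlen_t)col * P * N;
      const int* sp = &spi(0, k);
      for (int n = 0; n < N; ++n) {
        double* xn = dx + (R_xlen_t)S * (c + (R_xlen_t)C * n);
        const double* src = mcol + (R_xlen_t)P * n;
        for (int p = 0; p < P; ++p) {
          const int s = sp[p];
          if (s) xn[s - 1] += src[p];
        }
      }
    }
  }
  return dX;
}

// (P*N, Cout) matrix -> (P, Cout, N) array.
// [[Rcpp::export]]
NumericVector reshape_pnc(NumericMatrix Z, int P, int N) {
  const int C = Z.ncol();
  NumericVector out(Dimension(P, C, N));
  double* o = out.begin();
  const double* z = Z.begin();
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      const double* src = z + (R_xlen_t)c * P * N + (R_xlen_t)P * n;
      double* dst = o + (R_xlen_t)P * (c + (R_xlen_t)C * n);
      for (int p = 0; p < P; ++p) dst[p] = src[p];
    }
  return out;
}

// (P, Cout, N) array -> (P*N, Cout) matrix.
// [[Rcpp::export]]
NumericMatrix reshape_pcn(NumericVector A, int P, int C, int N) {
  NumericMatrix out(P * N, C);
  double* o = out.begin();
  const double* a = A.begin();
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      const double* src = a + (R_xlen_t)P * (c + (R_xlen_t)C * n);
      double* dst = o + (R_xlen_t)c * P * N + (R_xlen_t)P * n;
      for (int p = 0; p < P; ++p) dst[p] = src[p];
    }
  return out;
}

// Per-channel sums and sums of squares over (S, C, N): one pass.
// [[Rcpp::export]]
List bn_moments(NumericVector X, int S, int C, int N) {
  NumericVector s1(C), s2(C);
  const double* x = X.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x + (R_xlen_t)S * (c + (R_xlen_t)C * n);
      double a = 0, b = 0;
      for (int p = 0; p < S; ++p) { a += xc[p]; b += xc[p] * xc[p]; }
      s1[c] += a; s2[c] += b;
    }
  return List::create(_["s1"] = s1, _["s2"] = s2);
}

// Fused batch-norm forward: Xhat = (X - mu) * invstd, out = gamma * Xhat
// + beta, per channel, one pass.
// [[Rcpp::export]]
List bn_fwd(NumericVector X, NumericVector mu, NumericVector invstd,
            NumericVector gamma, NumericVector beta, int S, int C, int N) {
  NumericVector Xhat(Dimension(S, C, N)), out(Dimension(S, C, N));
  const double* x = X.begin();
  double* xh = Xhat.begin();
  double* o = out.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = (R_xlen_t)S * (c + (R_xlen_t)C * n);
      const double m = mu[c], is = invstd[c], g = gamma[c], bb = beta[c];
      for (int p = 0; p < S; ++p) {
        const double v = (x[off + p] - m) * is;
        xh[off + p] = v;
        o[off + p] = g * v + bb;
      }
    }
  return List::create(_["out"] = out, _["Xhat"] = Xhat);
}

// Fused batch-norm backward (training mode, batch statistics).
// [[Rcpp::export]]
List bn_bwd(NumericVector dOut, NumericVector Xhat, NumericVector invstd,
            NumericVector gamma, int S, int C, int N) {
  NumericVector dgamma(C), dbeta(C);
  const double* do_ = dOut.begin();
  const double* xh = Xhat.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = (R_xlen_t)S * (c + (R_xlen_t)C * n);
      double a = 0, b = 0;
      for (int p = 0; p < S; ++p) {
        a += do_[off + p] * xh[off + p];
        b += do_[off + p];
      }
      dgamma[c] += a; dbeta[c] += b;
    }
  NumericVector dX(Dimension(S, C, N));
  double* dx = dX.begin();
  const double m = (double)S * N;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = (R_xlen_t)S * (c + (R_xlen_t)C * n);
      const double gi = gamma[c] * invstd[c];
      const double mg = dgamma[c] / m, mb = dbeta[c] / m;
      for (int p = 0; p < S; ++p)
        dx[off + p] = gi * (do_[off + p] - mb - xh[off + p] * mg);
    }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// ReLU forward and backward.
// [[Rcpp::export]]
NumericVector relu_fwd(NumericVector X) {
  NumericVector out(clone(X));
  for (double& v : out) if (v < 0) v = 0;
  out.attr("dim") = X.attr("dim");
  return out;
}

// [[Rcpp::export]]
NumericVector relu_bwd(NumericVector dOut, NumericVector out) {
  NumericVector dX(clone(dOut));
  const double* o = out.begin();
  double* d = dX.begin();
  const R_xlen_t n = dX.size();
  for (R_xlen_t i = 0; i < n; ++i) if (o[i] <= 0) d[i] = 0;
  dX.attr("dim") = dOut.attr("dim");
  return dX;
}
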