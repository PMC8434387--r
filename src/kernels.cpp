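// Fused elementwise kernels for the network's hot paths.  The channel-mixing
// products stay in R (BLAS); these kernels fuse the surrounding per-element
// work (tap accumulation of the temporal convolution, batch-norm statistics
// and normalization, time shifts, max pooling) into single passes so the
// training loop is not dominated by intermediate allocations.

#include <Rcpp.h>
using namespace Rcpp;

// P: (3*Cout) x W x N stacked tap products; returns Y[c,w,n] =
// P[Cout+c,w,n] + b[c] + P[c,w-1,n] + P[2*Cout+c,w+1,n] (zero-padded).
// [[Rcpp::export(name = ".conv_tap_add")]]
NumericVector conv_tap_add(const NumericVector& P, const NumericVector& b,
                           int Cout, int W, int N) {
  NumericVector Y(static_cast<R_xlen_t>(Cout) * W * N);
  const double* p = P.begin();
  double* y = Y.begin();
  const double* bb = b.begin();
  const R_xlen_t C3 = 3 * static_cast<R_xlen_t>(Cout);
  for (R_xlen_t n = 0; n < N; ++n) {
    const double* pn = p + n * C3 * W;
    double* yn = y + n * static_cast<R_xlen_t>(Cout) * W;
    for (int w = 0; w < W; ++w) {
      const double* pw = pn + w * C3;
      double* yw = yn + w * static_cast<R_xlen_t>(Cout);
      for (int c = 0; c < Cout; ++c)
        yw[c] = pw[Cout + c] + bb[c];
      if (w > 0) {
        const double* pl = pn + (w - 1) * C3;
        for (int c = 0; c < Cout; ++c) yw[c] += pl[c];
      }
      if (w < W - 1) {
        const double* pr = pn + (w + 1) * C3 + 2 * Cout;
        for (int c = 0; c < Cout; ++c) yw[c] += pr[c];
      }
    }
  }
  return Y;
}

// Both time shifts of X (C x W x N) in one pass: left[c,w,n] = X[c,w-1,n],
// right[c,w,n] = X[c,w+1,n], zero-padded.
// [[Rcpp::export(name = ".shift_both")]]
List shift_both(const NumericVector& X, int C, int W, int N) {
  R_xlen_t sz = static_cast<R_xlen_t>(C) * W * N;
  NumericVector L(sz), R_(sz);
  const double* x = X.begin();
  double* l = L.begin();
  double* r = R_.begin();
  const R_xlen_t plane = static_cast<R_xlen_t>(C) * W;
  for (R_xlen_t n = 0; n < N; ++n) {
    const double* xn = x + n * plane;
    double* ln = l + n * plane;
    double* rn = r + n * plane;
    std::copy(xn, xn + plane - C, ln + C);          // left shift
    std::copy(xn + C, xn + plane, rn);              // right shift
  }
  return List::create(_["left"] = L, _["right"] = R_);
}

// Training-mode batch norm over rows of the C x m matrix X: returns the
// per-channel batch mean and population variance, xhat and y in one pass.
// [[Rcpp::export(name = ".bn_train_fwd")]]
List bn_train_fwd(const NumericMatrix& X, const NumericVector& gamma,
                  const NumericVector& beta, double eps) {
  const int C = X.nrow();
  const R_xlen_t m = X.ncol();
  NumericVector mu(C), var(C), inv(C);
  const double* x = X.begin();
  for (R_xlen_t j = 0; j < m; ++j) {
    const double* col = x + j * C;
    for (int c = 0; c < C; ++c) {
      mu[c] += col[c];
      var[c] += col[c] * col[c];
    }
  }
  for (int c = 0; c < C; ++c) {
    mu[c] /= m;
    var[c] = var[c] / m - mu[c] * mu[c];
    if (var[c] < 0) var[c] = 0;
    inv[c] = 1.0 / std::sqrt(var[c] + eps);
  }
  NumericMatrix xhat(C, m), y(C, m);
  double* xh = xhat.begin();
  double* yy = y.begin();
  for (R_xlen_t j = 0; j < m; ++j) {
    const double* col = x + j * C;
    double* xhc = xh + j * C;
    double* yc = yy + j * C;
    for (int c = 0; c < C; ++c) {
      xhc[c] = (col[c] - mu[c]) * inv[c];
      yc[c] = gamma[c] * xhc[c] + beta[c];
    }
  }
  return List::create(_["mean"] = mu, _["var"] = var, _["inv"] = inv,
                      _["xhat"] = xhat, _["y"] = y);
}

// Backward of training-mode batch norm, fused:
// dX = (gamma*inv/m) * (m*dY - dbeta - xhat*dgamma).
// [[Rcpp::export(name = ".bn_train_bwd")]]
List bn_train_bwd(const NumericMatrix& dY, const NumericMatrix& xhat,
                  const NumericVector& inv, const NumericVector& gamma) {
  const int C = dY.nrow();
  const R_xlen_t m = dY.ncol();
  NumericVector dgamma(C), dbeta(C);
  const double* dy = dY.begin();
  const double* xh = xhat.begin();
  for (R_xlen_t j = 0; j < m; ++j) {
    const double* dyc = dy + j * C;
    const double* xhc = xh + j * C;
    for (int c = 0; c < C; ++c) {
      dbeta[c] += dyc[c];
      dgamma[c] += dyc[c] * xhc[c];
    }
  }
  NumericMatrix dX(C, m);
  double* dx = dX.begin();
  std::vector<double> scale(C);
  for (int c = 0; c < C; ++c) scale[c] = gamma[c] * inv[c] / m;
  for (R_xlen_t j = 0; j < m; ++j) {
    const double* dyc = dy + j * C;
    const double* xhc = xh + j * C;
    double* dxc = dx + j * C;
    for (int c = 0; c < C; ++c)
      dxc[c] = scale[c] * (m * dyc[c] - dbeta[c] - xhc[c] * dgamma[c]);
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Max pooling along time (kernel 2, stride 2) with argmax mask; ties go to
// the earlier timestep.
// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd_cpp(const NumericVector& X, int C, int W, int N) {
  const int Wo = W / 2;
  R_xlen_t sz = static_cast<R_xlen_t>(C) * Wo * N;
  NumericVector Y(sz);
  LogicalVector first(sz);
  const double* x = X.begin();
  double* y = Y.begin();
  int* f = first.begin();
  const R_xlen_t plane_in = static_cast<R_xlen_t>(C) * W;
  const R_xlen_t plane_out = static_cast<R_xlen_t>(C) * Wo;
  for (R_xlen_t n = 0; n < N; ++n) {
    const double* xn = x + n * plane_in;
    double* yn = y + n * plane_out;
    int* fn = f + n * plane_out;
    for (int w = 0; w < Wo; ++w) {
      const double* a = xn + 2 * w * C;
      const double* bcol = a + C;
      double* yw = yn + w * static_cast<R_xlen_t>(C);
      int* fw = fn + w * static_cast<R_xlen_t>(C);
      for (int c = 0; c < C; ++c) {
        if (a[c] >= bcol[c]) { yw[c] = a[c]; fw[c] = 1; }
        else { yw[c] = bcol[c]; fw[c] = 0; }
      }
    }
  }
  return List::create(_["out"] = Y, _["first"] = first);
}

// Scatter pooled gradients back to the pre-pooling layout.
// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd_cpp(const NumericVector& dY,
                               const LogicalVector& first,
                               int C, int W, int N) {
  const int Wo = W / 2;
  NumericVector dX(static_cast<R_xlen_t>(C) * W * N);
  const double* dy = dY.begin();
  const int* f = first.begin();
  double* dx = dX.begin();
  const R_xlen_t plane_in = static_cast<R_xlen_t>(C) * W;
  const R_xlen_t plane_out = static_cast<R_xlen_t>(C) * Wo;
  for (R_xlen_t n = 0; n < N; ++n) {
    const double* dyn = dy + n * plane_out;
    const int* fn = f + n * plane_out;
    double* dxn = dx + n * plane_in;
    for (int w = 0; w < Wo; ++w) {
      const double* dyw = dyn + w * static_cast<R_xlen_t>(C);
      const int* fw = fn + w * static_cast<R_xlen_t>(C);
      double* a = dxn + 2 * w * C;
      double* bcol = a + C;
      for (int c = 0; c < C; ++c) {
        if (fw[c]) a[c] = dyw[c]; else bcol[c] = dyw[c];
      }
    }
  }
  return dX;
}
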