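#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Hot inner kernels of the network engine. R arrays are column-major:
// a (B, L, C) array indexes as b + B*(l + L*c); a (B, H, W, C) array as
// b + B*(h + H*(w + W*c)). The GEMMs themselves stay in R (BLAS).

// im2col for dilated 1D "same" convolution; out-of-range taps contribute 0.
// [[Rcpp::export]]
NumericMatrix im2col1d_cpp(NumericVector x, int B, int L, int C, int k, int dil) {
  int p = dil * (k - 1) / 2;
  NumericMatrix out(B * L, k * C);
  for (int j = 0; j < k; ++j) {
    int off = j * dil - p;
    for (int c = 0; c < C; ++c) {
      double *dst = &out(0, j * C + c);
      const double *src = &x[(size_t)B * L * c];
      for (int l = 0; l < L; ++l) {
        int s = l + off;
        if (s >= 0 && s < L)
          std::memcpy(dst + (size_t)B * l, src + (size_t)B * s, B * sizeof(double));
      }
    }
  }
  return out;
}

// transpose of im2col1d: scatter-add column gradients back to the input
// [[Rcpp::export]]
NumericVector col2im1d_cpp(NumericMatrix dXc, int B, int L, int C, int k, int dil) {
  int p = dil * (k - 1) / 2;
  NumericVector dx((size_t)B * L * C);
  for (int j = 0; j < k; ++j) {
    int off = j * dil - p;
    for (int c = 0; c < C; ++c) {
      const double *src = &dXc(0, j * C + c);
      double *dst = &dx[(size_t)B * L * c];
      for (int l = 0; l < L; ++l) {
        int s = l + off;
        if (s < 0 || s >= L) continue;
        const double *a = src + (size_t)B * l;
        double *d = dst + (size_t)B * s;
        for (int b = 0; b < B; ++b) d[b] += a[b];
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
NumericMatrix im2col2d_cpp(NumericVector x, int B, int H, int W, int C,
                           int k, int dil) {
  int p = dil * (k - 1) / 2;
  NumericMatrix out((size_t)B * H * W, k * k * C);
  int t = 0;
  for (int jw = 0; jw < k; ++jw) for (int jh = 0; jh < k; ++jh, ++t) {
    int oh = jh * dil - p, ow = jw * dil - p;
    for (int c = 0; c < C; ++c) {
      double *dst = &out(0, t * C + c);
      const double *src = &x[(size_t)B * H * W * c];
      for (int w = 0; w < W; ++w) {
        int sw = w + ow;
        if (sw < 0 || sw >= W) continue;
        for (int h = 0; h < H; ++h) {
          int sh = h + oh;
          if (sh < 0 || sh >= H) continue;
          std::memcpy(dst + (size_t)B * (h + (size_t)H * w),
                      src + (size_t)B * (sh + (size_t)H * sw),
                      B * sizeof(double));
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im2d_cpp(NumericMatrix dXc, int B, int H, int W, int C,
                           int k, int dil) {
  int p = dil * (k - 1) / 2;
  NumericVector dx((size_t)B * H * W * C);
  int t = 0;
  for (int jw = 0; jw < k; ++jw) for (int jh = 0; jh < k; ++jh, ++t) {
    int oh = jh * dil - p, ow = jw * dil - p;
    for (int c = 0; c < C; ++c) {
      const double *src = &dXc(0, t * C + c);
      double *dst = &dx[(size_t)B * H * W * c];
      for (int w = 0; w < W; ++w) {
        int sw = w + ow;
        if (sw < 0 || sw >= W) continue;
        for (int h = 0; h < H; ++h) {
          int sh = h + oh;
          if (sh < 0 || sh >= H) continue;
          const double *a = src + (size_t)B * (h + (size_t)H * w);
          double *d = dst + (size_t)B * (sh + (size_t)H * sw);
          for (int b = 0; b < B; ++b) d[b] += a[b];
        }
      }
    }
  }
  return dx;
}

// z * scale[col] + shift[col] in one pass (bias add, batch-norm affine)
// [[Rcpp::export]]
NumericMatrix affine_cols_cpp(NumericMatrix z, NumericVector scale,
                              NumericVector shift) {
  size_t n = z.nrow();
  int m = z.ncol();
  NumericMatrix out(z.nrow(), m);
  for (int j = 0; j < m; ++j) {
    double s = scale[j], t = shift[j];
    const double *a = &z(0, j);
    double *d = &out(0, j);
    for (size_t i = 0; i < n; ++i) d[i] = a[i] * s + t;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix add_cols_cpp(NumericMatrix z, NumericVector shift) {
  size_t n = z.nrow();
  int m = z.ncol();
  NumericMatrix out(z.nrow(), m);
  for (int j = 0; j < m; ++j) {
    double t = shift[j];
    const double *a = &z(0, j);
    double *d = &out(0, j);
    for (size_t i = 0; i < n; ++i) d[i] = a[i] + t;
  }
  return out;
}

// batch-norm input gradient:
// dx = invstd[col] * (dxhat - c1[col] - xhat * c2[col])
// [[Rcpp::export]]
NumericMatrix bn_backward_dx_cpp(NumericMatrix dxhat, NumericMatrix xhat,
                                 NumericVector c1, NumericVector c2,
                                 NumericVector invstd) {
  size_t n = dxhat.nrow();
  int m = dxhat.ncol();
  NumericMatrix out(dxhat.nrow(), m);
  for (int j = 0; j < m; ++j) {
    double a1 = c1[j], a2 = c2[j], s = invstd[j];
    const double *dh = &dxhat(0, j);
    const double *xh = &xhat(0, j);
    double *d = &out(0, j);
    for (size_t i = 0; i < n; ++i) d[i] = s * (dh[i] - a1 - xh[i] * a2);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector relu_fwd_cpp(NumericVector z) {
  NumericVector out(z.size());
  for (R_xlen_t i = 0; i < z.size(); ++i) out[i] = z[i] > 0 ? z[i] : 0;
  if (z.hasAttribute("dim")) out.attr("dim") = z.attr("dim");
  return out;
}

// gradient through ReLU given the post-activation values
// [[Rcpp::export]]
NumericVector relu_bwd_cpp(NumericVector dz, NumericVector post) {
  NumericVector out(dz.size());
  for (R_xlen_t i = 0; i < dz.size(); ++i) out[i] = post[i] > 0 ? dz[i] : 0;
  if (dz.hasAttribute("dim")) out.attr("dim") = dz.attr("dim");
  return out;
}
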