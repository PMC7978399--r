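// Patch-matrix (im2col) gather and its scatter-add adjoint (col2im).
// These two memory-movement primitives carry the convolution and
// transposed-convolution layers; the matrix products themselves run on
// R's BLAS. Zero padding is handled implicitly by bounds checks.

#include <Rcpp.h>
using namespace Rcpp;

// x: (H, W, C) array; returns (outH*outW) x (k*k*C) patch matrix whose
// column order (kr fastest, then kc, then channel) matches the
// vectorisation of a (k, k, C, ...) weight array.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C, int k,
                         int stride, int pt, int pl, int outH, int outW) {
  NumericMatrix cols(outH * outW, k * k * C);
  const double* xp = x.begin();
  double* cp = cols.begin();
  const int n_out = outH * outW;
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (R_xlen_t)c * H * W;
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        const int col = (c * k + kc) * k + kr;
        double* out = cp + (R_xlen_t)col * n_out;
        for (int oj = 0; oj < outW; ++oj) {
          const int cidx = oj * stride + kc - pl;
          double* o = out + (R_xlen_t)oj * outH;
          if (cidx < 0 || cidx >= W) {
            for (int oi = 0; oi < outH; ++oi) o[oi] = 0.0;
            continue;
          }
          const double* src = xc + (R_xlen_t)cidx * H;
          for (int oi = 0; oi < outH; ++oi) {
            const int ridx = oi * stride + kr - pt;
            o[oi] = (ridx < 0 || ridx >= H) ? 0.0 : src[ridx];
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of cpp_im2col: scatter-adds a (outH*outW) x (k*k*C)
// contribution matrix back onto an (H, W, C) array.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dcols, int H, int W, int C, int k,
                         int stride, int pt, int pl, int outH, int outW) {
  NumericVector dx((R_xlen_t)H * W * C);
  double* xp = dx.begin();
  const double* cp = dcols.begin();
  const int n_out = outH * outW;
  for (int c = 0; c < C; ++c) {
    double* xc = xp + (R_xlen_t)c * H * W;
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        const int col = (c * k + kc) * k + kr;
        const double* in = cp + (R_xlen_t)col * n_out;
        for (int oj = 0; oj < outW; ++oj) {
          const int cidx = oj * stride + kc - pl;
          if (cidx < 0 || cidx >= W) continue;
          double* dst = xc + (R_xlen_t)cidx * H;
          const double* i = in + (R_xlen_t)oj * outH;
          for (int oi = 0; oi < outH; ++oi) {
            const int ridx = oi * stride + kr - pt;
            if (ridx >= 0 && ridx < H) dst[ridx] += i[oi];
          }
        }
      }
    }
  }
  return dx;
}

// Spatial batch normalisation over an (n, C) matrix view of one slice
// (minibatch 1): per-channel standardisation by batch statistics
// (training) or running statistics. Returns the output, xhat and istd.
// [[Rcpp::export]]
List cpp_batchnorm_forward(NumericMatrix x, NumericVector gamma,
                           NumericVector beta, NumericVector rmean,
                           NumericVector rvar, bool batch_stats, double eps) {
  const int n = x.nrow(), C = x.ncol();
  NumericMatrix out(n, C), xhat(n, C);
  NumericVector mu(C), var(C), istd(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    double m, v;
    if (batch_stats) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += xc[i];
      m = s / n;
      double ss = 0.0;
      for (int i = 0; i < n; ++i) { double d = xc[i] - m; ss += d * d; }
      v = ss / n;
    } else {
      m = rmean[c]; v = rvar[c];
    }
    mu[c] = m; var[c] = v;
    const double is = 1.0 / std::sqrt(v + eps);
    istd[c] = is;
    const double g = gamma[c], b = beta[c];
    double* xh = &xhat(0, c);
    double* o = &out(0, c);
    for (int i = 0; i < n; ++i) {
      xh[i] = (xc[i] - m) * is;
      o[i] = g * xh[i] + b;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["istd"] = istd,
                      _["mu"] = mu, _["var"] = var);
}

// [[Rcpp::export]]
List cpp_batchnorm_backward(NumericMatrix dout, NumericMatrix xhat,
                            NumericVector istd, NumericVector gamma) {
  const int n = dout.nrow(), C = dout.ncol();
  NumericMatrix dx(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dm = &dout(0, c);
    const double* xh = &xhat(0, c);
    double sg = 0.0, sb = 0.0;
    for (int i = 0; i < n; ++i) { sg += dm[i] * xh[i]; sb += dm[i]; }
    dgamma[c] = sg; dbeta[c] = sb;
    const double g = gamma[c], is = istd[c];
    const double m1 = g * sb / n, m2 = g * sg / n;
    double* d = &dx(0, c);
    for (int i = 0; i < n; ++i)
      d[i] = (g * dm[i] - m1 - xh[i] * m2) * is;
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
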