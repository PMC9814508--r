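// Convolution, depthwise-convolution, pooling and batch-norm kernels for the
// model engine. Activations are stored as (N * H * W) x C matrices:
// sample-major rows, column-major spatial positions within a sample
// (row = n*H*W + w*H + h), channels in columns. Convolutions use "same"
// padding; pooling uses ceil division with truncated edge windows (same
// padding, stride = pool size).
//
// Inputs and outputs cross the R boundary as NumericMatrix (R-allocated
// storage) with zero-copy Armadillo views on top, so large activations are
// never duplicated at the interface. Per-sample im2col buffers are reused
// across the batch.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int in, int stride) {
  return (in + stride - 1) / stride; // ceil
}

static inline arma::mat view(NumericMatrix m) {
  return arma::mat(m.begin(), m.nrow(), m.ncol(), false, true);
}

// im2col for ONE sample into a preallocated (Ho*Wo) x (kh*kw*C) buffer.
// Padding slots are identical across samples, so the buffer is zeroed once
// by the caller and only valid regions are rewritten per sample.
static void im2col_one(const arma::mat& X, size_t x_off, int H, int W, int C,
                       int kh, int kw, int sh, int sw, arma::mat& P) {
  const int Ho = out_dim(H, sh), Wo = out_dim(W, sw);
  const int pad_h = std::max((Ho - 1) * sh + kh - H, 0) / 2;
  const int pad_w = std::max((Wo - 1) * sw + kw - W, 0) / 2;
  for (int c = 0; c < C; ++c) {
    const double* xn = X.colptr(c) + x_off;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        double* pc = P.colptr(c * kh * kw + j * kh + i);
        const int ho_lo = std::max(0, (pad_h - i + sh - 1) / sh);
        const int ho_hi = std::min(Ho, (H - 1 - i + pad_h) / sh + 1);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * sw + j - pad_w;
          if (wi < 0 || wi >= W) continue;
          const double* src = xn + static_cast<size_t>(wi) * H
                              + ho_lo * sh + i - pad_h;
          double* dst = pc + static_cast<size_t>(wo) * Ho + ho_lo;
          if (sh == 1) {
            std::memcpy(dst, src, sizeof(double) * (ho_hi - ho_lo));
          } else {
            for (int ho = ho_lo; ho < ho_hi; ++ho) {
              *dst++ = *src;
              src += sh;
            }
          }
        }
      }
    }
  }
}

// adjoint of im2col_one: scatter-add the patch buffer into one sample of dX
static void col2im_one(const arma::mat& dP, arma::mat& dX, size_t x_off,
                       int H, int W, int C, int kh, int kw, int sh, int sw) {
  const int Ho = out_dim(H, sh), Wo = out_dim(W, sw);
  const int pad_h = std::max((Ho - 1) * sh + kh - H, 0) / 2;
  const int pad_w = std::max((Wo - 1) * sw + kw - W, 0) / 2;
  for (int c = 0; c < C; ++c) {
    double* xn = dX.colptr(c) + x_off;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const double* pc = dP.colptr(c * kh * kw + j * kh + i);
        const int ho_lo = std::max(0, (pad_h - i + sh - 1) / sh);
        const int ho_hi = std::min(Ho, (H - 1 - i + pad_h) / sh + 1);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * sw + j - pad_w;
          if (wi < 0 || wi >= W) continue;
          double* dst = xn + static_cast<size_t>(wi) * H
                        + ho_lo * sh + i - pad_h;
          const double* src = pc + static_cast<size_t>(wo) * Ho + ho_lo;
          if (sh == 1) {
            const int len = ho_hi - ho_lo;
            for (int t = 0; t < len; ++t) dst[t] += src[t];
          } else {
            for (int ho = ho_lo; ho < ho_hi; ++ho) {
              *dst += *src++;
              dst += sh;
            }
          }
        }
      }
    }
  }
}

// standalone batched im2col (exposed so tests can check the convolution
// against direct oracles)
// [[Rcpp::export(name = "cpp_im2col")]]
NumericMatrix cpp_im2col(NumericMatrix Xr, int H, int W, int N,
                         int kh, int kw, int sh, int sw) {
  const arma::mat X = view(Xr);
  const int C = X.n_cols;
  const int Ho = out_dim(H, sh), Wo = out_dim(W, sw);
  NumericMatrix Pr(static_cast<R_xlen_t>(N) * Ho * Wo, kh * kw * C);
  arma::mat P = view(Pr);
  arma::mat buf(static_cast<arma::uword>(Ho) * Wo, kh * kw * C,
                arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    im2col_one(X, static_cast<size_t>(n) * H * W, H, W, C, kh, kw, sh, sw,
               buf);
    P.rows(static_cast<arma::uword>(n) * Ho * Wo,
           static_cast<arma::uword>(n + 1) * Ho * Wo - 1) = buf;
  }
  return Pr;
}

// Forward convolution: per-sample im2col into a reused buffer + GEMM.
// [[Rcpp::export(name = "cpp_conv2d_fw")]]
List cpp_conv2d_fw(NumericMatrix Xr, int H, int W, int N,
                   const arma::mat& Wm, const arma::vec& b,
                   int kh, int kw, int sh, int sw) {
  const arma::mat X = view(Xr);
  const int C = X.n_cols, F = Wm.n_cols;
  if ((int)Wm.n_rows != kh * kw * C) stop("conv2d: weight shape mismatch");
  const int Ho = out_dim(H, sh), Wo = out_dim(W, sw);
  NumericMatrix Yr(static_cast<R_xlen_t>(N) * Ho * Wo, F);
  arma::mat Y = view(Yr);
  arma::mat P(static_cast<arma::uword>(Ho) * Wo, kh * kw * C,
              arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    im2col_one(X, static_cast<size_t>(n) * H * W, H, W, C, kh, kw, sh, sw, P);
    Y.rows(static_cast<arma::uword>(n) * Ho * Wo,
           static_cast<arma::uword>(n + 1) * Ho * Wo - 1) = P * Wm;
  }
  Y.each_row() += b.t();
  return List::create(_["y"] = Yr, _["ho"] = Ho, _["wo"] = Wo);
}

// Backward convolution; patch buffers are rebuilt per sample (cheaper than
// holding batch-sized copies).
// [[Rcpp::export(name = "cpp_conv2d_bw")]]
List cpp_conv2d_bw(NumericMatrix Xr, int H, int W, int N,
                   const arma::mat& Wm, NumericMatrix dYr,
                   int kh, int kw, int sh, int sw) {
  const arma::mat X = view(Xr);
  const arma::mat dY = view(dYr);
  const int C = X.n_cols;
  const int Ho = out_dim(H, sh), Wo = out_dim(W, sw);
  NumericMatrix dXr(Xr.nrow(), C); // R allocates zeroed storage
  arma::mat dX = view(dXr);
  arma::mat dW(Wm.n_rows, Wm.n_cols, arma::fill::zeros);
  arma::mat P(static_cast<arma::uword>(Ho) * Wo, kh * kw * C,
              arma::fill::zeros);
  arma::mat dP(static_cast<arma::uword>(Ho) * Wo, kh * kw * C);
  for (int n = 0; n < N; ++n) {
    const size_t x_off = static_cast<size_t>(n) * H * W;
    const arma::mat dYn = dY.rows(static_cast<arma::uword>(n) * Ho * Wo,
                                  static_cast<arma::uword>(n + 1) * Ho * Wo
                                  - 1);
    im2col_one(X, x_off, H, W, C, kh, kw, sh, sw, P);
    dW += P.t() * dYn;
    dP = dYn * Wm.t();
    col2im_one(dP, dX, x_off, H, W, C, kh, kw, sh, sw);
  }
  arma::rowvec db = arma::sum(dY, 0);
  return List::create(_["dx"] = dXr, _["dw"] = dW,
                      _["db"] = arma::vec(db.t()));
}

// Depthwise convolution (channel multiplier 1), stride 1, same padding.
// Weights: (kh*kw) x C, one bias per channel.
// [[Rcpp::export(name = "cpp_depthwise_fw")]]
NumericMatrix cpp_depthwise_fw(NumericMatrix Xr, int H, int W, int N,
                               const arma::mat& Wm, const arma::vec& b,
                               int kh, int kw) {
  const arma::mat X = view(Xr);
  const int C = X.n_cols;
  if ((int)Wm.n_rows != kh * kw || (int)Wm.n_cols != C)
    stop("depthwise: weight shape mismatch");
  const int pad_h = (kh - 1) / 2, pad_w = (kw - 1) / 2;
  NumericMatrix Yr(Xr.nrow(), C);
  arma::mat Y = view(Yr);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    double* yc = Y.colptr(c);
    const double bc = b(c);
    std::fill(yc, yc + X.n_rows, bc);
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const double wgt = Wm(j * kh + i, c);
        const int ho_lo = std::max(0, pad_h - i);
        const int ho_hi = std::min(H, H + pad_h - i);
        for (int n = 0; n < N; ++n) {
          const double* xn = xc + static_cast<size_t>(n) * H * W;
          double* yn = yc + static_cast<size_t>(n) * H * W;
          for (int wo = 0; wo < W; ++wo) {
            const int wi = wo + j - pad_w;
            if (wi < 0 || wi >= W) continue;
            const double* src = xn + static_cast<size_t>(wi) * H
                                + ho_lo + i - pad_h;
            double* dst = yn + static_cast<size_t>(wo) * H + ho_lo;
            const int len = ho_hi - ho_lo;
            for (int t = 0; t < len; ++t) dst[t] += wgt * src[t];
          }
        }
      }
    }
  }
  return Yr;
}

// [[Rcpp::export(name = "cpp_depthwise_bw")]]
List cpp_depthwise_bw(NumericMatrix Xr, int H, int W, int N,
                      const arma::mat& Wm, NumericMatrix dYr,
                      int kh, int kw) {
  const arma::mat X = view(Xr);
  const arma::mat dY = view(dYr);
  const int C = X.n_cols;
  const int pad_h = (kh - 1) / 2, pad_w = (kw - 1) / 2;
  NumericMatrix dXr(Xr.nrow(), C);
  arma::mat dX = view(dXr);
  arma::mat dW(kh * kw, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    double* dxc = dX.colptr(c);
    const double* dyc = dY.colptr(c);
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const double wgt = Wm(j * kh + i, c);
        const int ho_lo = std::max(0, pad_h - i);
        const int ho_hi = std::min(H, H + pad_h - i);
        double acc = 0.0;
        for (int n = 0; n < N; ++n) {
          const size_t off = static_cast<size_t>(n) * H * W;
          for (int wo = 0; wo < W; ++wo) {
            const int wi = wo + j - pad_w;
            if (wi < 0 || wi >= W) continue;
            const double* xs = xc + off + static_cast<size_t>(wi) * H
                               + ho_lo + i - pad_h;
            double* dxs = dxc + off + static_cast<size_t>(wi) * H
                          + ho_lo + i - pad_h;
            const double* g = dyc + off + static_cast<size_t>(wo) * H + ho_lo;
            const int len = ho_hi - ho_lo;
            for (int t = 0; t < len; ++t) {
              acc += g[t] * xs[t];
              dxs[t] += g[t] * wgt;
            }
          }
        }
        dW(j * kh + i, c) = acc;
      }
    }
  }
  arma::rowvec db = arma::sum(dY, 0);
  return List::create(_["dx"] = dXr, _["dw"] = dW,
                      _["db"] = arma::vec(db.t()));
}

// Max pooling, stride = pool size, same padding (ceil division; edge windows
// truncated). Returns pooled matrix and 1-based argmax rows into X.
// [[Rcpp::export(name = "cpp_maxpool_fw")]]
List cpp_maxpool_fw(NumericMatrix Xr, int H, int W, int N,
                    int ph, int pw) {
  const arma::mat X = view(Xr);
  const int C = X.n_cols;
  const int Ho = out_dim(H, ph), Wo = out_dim(W, pw);
  NumericMatrix Yr(static_cast<R_xlen_t>(N) * Ho * Wo, C);
  IntegerMatrix Ar(static_cast<R_xlen_t>(N) * Ho * Wo, C);
  arma::mat Y = view(Yr);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    double* yc = Y.colptr(c);
    int* ac = &Ar(0, c);
    for (int n = 0; n < N; ++n) {
      const size_t off = static_cast<size_t>(n) * H * W;
      const size_t offo = static_cast<size_t>(n) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        const int w0 = wo * pw, w1 = std::min(w0 + pw, W);
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = ho * ph, h1 = std::min(h0 + ph, H);
          double best = -std::numeric_limits<double>::infinity();
          size_t best_row = off + static_cast<size_t>(w0) * H + h0;
          for (int wi = w0; wi < w1; ++wi) {
            const double* col = xc + off + static_cast<size_t>(wi) * H;
            for (int hi = h0; hi < h1; ++hi) {
              if (col[hi] > best) {
                best = col[hi];
                best_row = off + static_cast<size_t>(wi) * H + hi;
              }
            }
          }
          yc[offo + static_cast<size_t>(wo) * Ho + ho] = best;
          ac[offo + static_cast<size_t>(wo) * Ho + ho] =
            static_cast<int>(best_row) + 1;
        }
      }
    }
  }
  return List::create(_["y"] = Yr, _["argmax"] = Ar,
                      _["ho"] = Ho, _["wo"] = Wo);
}

// [[Rcpp::export(name = "cpp_maxpool_bw")]]
NumericMatrix cpp_maxpool_bw(NumericMatrix dYr, IntegerMatrix Ar,
                             int n_rows_in) {
  const arma::mat dY = view(dYr);
  const int C = dY.n_cols;
  NumericMatrix dXr(n_rows_in, C);
  arma::mat dX = view(dXr);
  for (int c = 0; c < C; ++c) {
    double* dxc = dX.colptr(c);
    const double* dyc = dY.colptr(c);
    const int* ac = &Ar(0, c);
    const arma::uword M = dY.n_rows;
    for (arma::uword r = 0; r < M; ++r) {
      dxc[ac[r] - 1] += dyc[r];
    }
  }
  return dXr;
}

// Batch-norm training forward: per-column batch statistics and the affine
// output in single passes. The normalised activations are not materialised;
// the backward pass recomputes them from the cached input and statistics.
// [[Rcpp::export(name = "cpp_bn_fw")]]
List cpp_bn_fw(NumericMatrix Xr, const arma::vec& gamma,
               const arma::vec& beta, double eps) {
  const arma::mat X = view(Xr);
  const int C = X.n_cols;
  const arma::uword M = X.n_rows;
  NumericVector mu(C), v(C), inv_sd(C);
  NumericMatrix Yr(Xr.nrow(), C);
  arma::mat Y = view(Yr);
  for (int c = 0; c < C; ++c) {
    const double* x = X.colptr(c);
    double s = 0.0, s2 = 0.0;
    for (arma::uword r = 0; r < M; ++r) { s += x[r]; s2 += x[r] * x[r]; }
    const double m = s / M;
    const double var = s2 / M - m * m;
    const double a = 1.0 / std::sqrt(var + eps);
    mu[c] = m; v[c] = var; inv_sd[c] = a;
    const double ga = gamma(c) * a;
    const double bt = beta(c) - ga * m;
    double* y = Y.colptr(c);
    for (arma::uword r = 0; r < M; ++r) y[r] = ga * x[r] + bt;
  }
  return List::create(_["y"] = Yr, _["mu"] = mu, _["v"] = v,
                      _["inv_sd"] = inv_sd);
}

// [[Rcpp::export(name = "cpp_bn_bw")]]
List cpp_bn_bw(NumericMatrix Xr, NumericMatrix dYr, const arma::vec& gamma,
               const arma::vec& mu, const arma::vec& inv_sd) {
  const arma::mat X = view(Xr);
  const arma::mat dY = view(dYr);
  const int C = X.n_cols;
  const arma::uword M = X.n_rows;
  NumericVector dgamma(C), dbeta(C);
  NumericMatrix dXr(Xr.nrow(), C);
  arma::mat dX = view(dXr);
  for (int c = 0; c < C; ++c) {
    const double* x = X.colptr(c);
    const double* dy = dY.colptr(c);
    const double a = inv_sd(c), m = mu(c);
    double sg = 0.0, sb = 0.0;
    for (arma::uword r = 0; r < M; ++r) {
      sg += dy[r] * (x[r] - m) * a;
      sb += dy[r];
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    const double g = gamma(c);
    const double m1 = g * sb / M, m2 = g * sg / M;
    double* dx = dX.colptr(c);
    for (arma::uword r = 0; r < M; ++r) {
      dx[r] = a * (g * dy[r] - m1 - (x[r] - m) * a * m2);
    }
  }
  return List::create(_["dx"] = dXr, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// column-wise affine y = x * a[col] + b[col] (inference batch norm, biases)
// [[Rcpp::export(name = "cpp_col_affine")]]
NumericMatrix cpp_col_affine(NumericMatrix Xr, const arma::vec& a,
                             const arma::vec& b) {
  const arma::mat X = view(Xr);
  NumericMatrix Yr(Xr.nrow(), Xr.ncol());
  arma::mat Y = view(Yr);
  for (arma::uword c = 0; c < X.n_cols; ++c) {
    const double* x = X.colptr(c);
    double* y = Y.colptr(c);
    const double ac = a(c), bc = b(c);
    for (arma::uword r = 0; r < X.n_rows; ++r) y[r] = ac * x[r] + bc;
  }
  return Yr;
}

// [[Rcpp::export(name = "cpp_relu_fw")]]
NumericMatrix cpp_relu_fw(NumericMatrix Xr) {
  NumericMatrix Yr(Xr.nrow(), Xr.ncol());
  const double* x = Xr.begin();
  double* y = Yr.begin();
  const R_xlen_t n = Xr.size();
  for (R_xlen_t i = 0; i < n; ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  return Yr;
}

// [[Rcpp::export(name = "cpp_relu_bw")]]
NumericMatrix cpp_relu_bw(NumericMatrix dYr, NumericMatrix Yr) {
  NumericMatrix dXr(dYr.nrow(), dYr.ncol());
  const double* dy = dYr.begin();
  const double* y = Yr.begin();
  double* dx = dXr.begin();
  const R_xlen_t n = dYr.size();
  for (R_xlen_t i = 0; i < n; ++i) dx[i] = y[i] > 0 ? dy[i] : 0.0;
  return dXr;
}
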