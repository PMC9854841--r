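// Low-level CPU kernels for the residual network: 2-D convolution via
// im2col + BLAS gemm, batch normalisation, and max pooling, each with the
// backward pass needed for training. Tensor layout throughout is the native
// R column-major array (H, W, C, N); convolution weights are (kH, kW, Cin, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static NumericVector alloc4d(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// col is K x P with K = kH*kW*C (row index kh + kw*kH + c*kH*kW) and
// P = oH*oW (column index oh + ow*oH). Out-of-frame taps read as zero.
static void im2col(const double* x, int H, int W, int C,
                   int kH, int kW, int stride, int pad,
                   int oH, int oW, arma::mat& col) {
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kw = 0; kw < kW; ++kw) {
      for (int kh = 0; kh < kH; ++kh) {
        const int r = kh + kw * kH + c * kH * kW;
        for (int ow = 0; ow < oW; ++ow) {
          const int iw = ow * stride - pad + kw;
          if (iw < 0 || iw >= W) continue;
          for (int oh = 0; oh < oH; ++oh) {
            const int ih = oh * stride - pad + kh;
            if (ih < 0 || ih >= H) continue;
            col(r, oh + ow * oH) = xc[ih + (size_t)iw * H];
          }
        }
      }
    }
  }
}

// Scatter-add of a column matrix back onto the input image (transpose of
// im2col); overlapping taps accumulate.
static void col2im_add(const arma::mat& col, double* dx, int H, int W, int C,
                       int kH, int kW, int stride, int pad,
                       int oH, int oW) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int kw = 0; kw < kW; ++kw) {
      for (int kh = 0; kh < kH; ++kh) {
        const int r = kh + kw * kH + c * kH * kW;
        for (int ow = 0; ow < oW; ++ow) {
          const int iw = ow * stride - pad + kw;
          if (iw < 0 || iw >= W) continue;
          for (int oh = 0; oh < oH; ++oh) {
            const int ih = oh * stride - pad + kh;
            if (ih < 0 || ih >= H) continue;
            xc[ih + (size_t)iw * H] += col(r, oh + ow * oH);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv_forward(NumericVector x, NumericVector w,
                              int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kH = wd[0], kW = wd[1], Ci = wd[2], Co = wd[3];
  if (Ci != C)
    stop("channel mismatch: input has %d channels but weight expects %d", C, Ci);
  const int oH = (H + 2 * pad - kH) / stride + 1;
  const int oW = (W + 2 * pad - kW) / stride + 1;
  const int K = kH * kW * C, P = oH * oW;
  arma::mat Wm(w.begin(), K, Co, false, true);
  NumericVector y = alloc4d(oH, oW, Co, N);
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C,
           kH, kW, stride, pad, oH, oW, col);
    arma::mat out(y.begin() + (size_t)n * P * Co, P, Co, false, true);
    out = col.t() * Wm;
  }
  return y;
}

// Images are processed in chunks so that the K x (P*chunk) column buffer
// stays modest while the weight-gradient gemm still amortises over many
// output positions (a per-image gemm would rewrite the K x Co accumulator
// once per image, which dominates at small spatial sizes).
// [[Rcpp::export]]
List nn_conv_backward(NumericVector x, NumericVector w, NumericVector dy,
                      int stride, int pad, bool need_dx) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kH = wd[0], kW = wd[1], Co = wd[3];
  const int oH = (H + 2 * pad - kH) / stride + 1;
  const int oW = (W + 2 * pad - kW) / stride + 1;
  const int K = kH * kW * C, P = oH * oW;
  arma::mat Wm(w.begin(), K, Co, false, true);
  NumericVector dwv = alloc4d(kH, kW, C, Co);
  arma::mat dW(dwv.begin(), K, Co, false, true);
  NumericVector dxv;
  if (need_dx) dxv = alloc4d(H, W, C, N);
  int chunk = std::max(1, (int)(8000000 / ((size_t)K * P)));
  if (chunk > N) chunk = N;
  arma::mat col(K, (size_t)P * chunk);
  arma::mat dyc((size_t)P * chunk, Co);
  for (int n0 = 0; n0 < N; n0 += chunk) {
    const int nc = std::min(chunk, N - n0);
    for (int j = 0; j < nc; ++j) {
      arma::mat sub(col.colptr((size_t)j * P), K, P, false, true);
      im2col(x.begin() + (size_t)(n0 + j) * H * W * C, H, W, C,
             kH, kW, stride, pad, oH, oW, sub);
      dyc.rows((size_t)j * P, (size_t)j * P + P - 1) =
        arma::mat(dy.begin() + (size_t)(n0 + j) * P * Co, P, Co, false, true);
    }
    if (nc == chunk) {
      dW += col * dyc;
      if (need_dx) {
        arma::mat dcol = Wm * dyc.t();
        for (int j = 0; j < nc; ++j)
          col2im_add(dcol.cols((size_t)j * P, (size_t)j * P + P - 1),
                     dxv.begin() + (size_t)(n0 + j) * H * W * C,
                     H, W, C, kH, kW, stride, pad, oH, oW);
      }
    } else {
      arma::mat colp = col.cols(0, (size_t)nc * P - 1);
      arma::mat dyp = dyc.rows(0, (size_t)nc * P - 1);
      dW += colp * dyp;
      if (need_dx) {
        arma::mat dcol = Wm * dyp.t();
        for (int j = 0; j < nc; ++j)
          col2im_add(dcol.cols((size_t)j * P, (size_t)j * P + P - 1),
                     dxv.begin() + (size_t)(n0 + j) * H * W * C,
                     H, W, C, kH, kW, stride, pad, oH, oW);
      }
    }
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv);
}

// Fused Adam update, in place: the caller owns p, m and v exclusively
// (the training loop deep-copies trainable tensors before the first step).
// [[Rcpp::export]]
void nn_adam_inplace(NumericVector p, NumericVector g, NumericVector m,
                     NumericVector v, double lr, double b1, double b2,
                     double eps, double bc1, double bc2) {
  const R_xlen_t n = p.size();
  double* pp = p.begin(); const double* gp = g.begin();
  double* mp = m.begin(); double* vp = v.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    mp[i] = b1 * mp[i] + (1 - b1) * gp[i];
    vp[i] = b2 * vp[i] + (1 - b2) * gp[i] * gp[i];
    pp[i] -= lr * (mp[i] / bc1) / (std::sqrt(vp[i] / bc2) + eps);
  }
}

// Per-channel statistics are taken over (H, W, N); population variance.
// In training mode running statistics are updated with the usual
// exponential moving average; in inference mode they are consumed as-is.
// [[Rcpp::export]]
List nn_bn_forward(NumericVector x, NumericVector gamma, NumericVector beta,
                   NumericVector rmean, NumericVector rvar,
                   bool training, double momentum, double eps) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W, CHW = HW * C;
  const double M = (double)HW * N;
  NumericVector y = alloc4d(H, W, C, N);
  NumericVector mean_used(C), invstd(C), new_rm(C), new_rv(C);
  for (int c = 0; c < C; ++c) {
    double m, v;
    if (training) {
      double s = 0.0, ss = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + (size_t)n * CHW + c * HW;
        for (size_t i = 0; i < HW; ++i) { s += xc[i]; ss += xc[i] * xc[i]; }
      }
      m = s / M;
      v = ss / M - m * m;
      if (v < 0) v = 0;
      new_rm[c] = (1.0 - momentum) * rmean[c] + momentum * m;
      new_rv[c] = (1.0 - momentum) * rvar[c] + momentum * v;
    } else {
      m = rmean[c];
      v = rvar[c];
      new_rm[c] = rmean[c];
      new_rv[c] = rvar[c];
    }
    const double is = 1.0 / std::sqrt(v + eps);
    mean_used[c] = m;
    invstd[c] = is;
    const double a = gamma[c] * is, b = beta[c] - a * m;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + (size_t)n * CHW + c * HW;
      double* yc = y.begin() + (size_t)n * CHW + c * HW;
      for (size_t i = 0; i < HW; ++i) yc[i] = a * xc[i] + b;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean_used, _["invstd"] = invstd,
                      _["running_mean"] = new_rm, _["running_var"] = new_rv);
}

// [[Rcpp::export]]
List nn_bn_backward(NumericVector x, NumericVector dy, NumericVector gamma,
                    NumericVector save_mean, NumericVector save_invstd) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W, CHW = HW * C;
  const double M = (double)HW * N;
  NumericVector dx = alloc4d(H, W, C, N), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double m = save_mean[c], is = save_invstd[c];
    double s1 = 0.0, s2 = 0.0;  // sum(dy), sum(dy * xhat)
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + (size_t)n * CHW + c * HW;
      const double* dc = dy.begin() + (size_t)n * CHW + c * HW;
      for (size_t i = 0; i < HW; ++i) {
        s1 += dc[i];
        s2 += dc[i] * (xc[i] - m) * is;
      }
    }
    dgamma[c] = s2;
    dbeta[c] = s1;
    const double g = gamma[c] * is;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + (size_t)n * CHW + c * HW;
      const double* dc = dy.begin() + (size_t)n * CHW + c * HW;
      double* ox = dx.begin() + (size_t)n * CHW + c * HW;
      for (size_t i = 0; i < HW; ++i) {
        const double xhat = (xc[i] - m) * is;
        ox[i] = g * (dc[i] - s1 / M - xhat * s2 / M);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Ties resolve to the first tap in scan order; padded positions never win.
// [[Rcpp::export]]
List nn_maxpool_forward(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int oH = (H + 2 * pad - k) / stride + 1;
  const int oW = (W + 2 * pad - k) / stride + 1;
  NumericVector y = alloc4d(oH, oW, C, N);
  IntegerVector idx = alloc4i(oH, oW, C, N);  // 0-based flat index into x
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int ow = 0; ow < oW; ++ow) {
        for (int oh = 0; oh < oH; ++oh) {
          double best = -std::numeric_limits<double>::infinity();
          int bi = -1;
          for (int kw = 0; kw < k; ++kw) {
            const int iw = ow * stride - pad + kw;
            if (iw < 0 || iw >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int ih = oh * stride - pad + kh;
              if (ih < 0 || ih >= H) continue;
              const double v = xc[ih + (size_t)iw * H];
              if (v > best) { best = v; bi = ih + iw * H; }
            }
          }
          o = (size_t)oh + (size_t)ow * oH + ((size_t)n * C + c) * oH * oW;
          y[o] = best;
          idx[o] = (int)(base + bi);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool_backward(NumericVector dy, IntegerVector idx,
                                  IntegerVector xdim) {
  NumericVector dx = alloc4d(xdim[0], xdim[1], xdim[2], xdim[3]);
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) dx[idx[i]] += dy[i];
  return dx;
}
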