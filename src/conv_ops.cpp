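// Convolution primitives for the scalable network.
// Tensor layout everywhere: H x W x C x N R arrays (column-major, H fastest).
// Weight layout: kh x kw x Cin x Cout (plain conv), kh x kw x C (depthwise).
// Standard convolution is im2col + GEMM; depthwise is direct loops.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline IntegerVector dims_of(const NumericVector& x) {
  return as<IntegerVector>(x.attr("dim"));
}

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Build the im2col matrix for image n: rows r = i + kh*(j + kw*c),
// cols p = oh + Ho*ow. Out-of-bounds taps are zero.
static void im2col(const double* xn, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& M) {
  M.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = xn + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        double* Mr = M.memptr() + r;             // row r, stride M.n_rows
        for (int ow = 0; ow < Wo; ++ow) {
          const int wsrc = ow * stride - pad + j;
          if (wsrc < 0 || wsrc >= W) continue;
          const double* xcol = xc + (size_t)wsrc * H;
          for (int oh = 0; oh < Ho; ++oh) {
            const int hsrc = oh * stride - pad + i;
            if (hsrc < 0 || hsrc >= H) continue;
            Mr[(size_t)(oh + Ho * ow) * M.n_rows] = xcol[hsrc];
          }
        }
      }
    }
  }
}

// Scatter-add the im2col gradient back onto the input image.
static void col2im(const arma::mat& dM, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* dxn) {
  for (int c = 0; c < C; ++c) {
    double* dxc = dxn + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        const double* Mr = dM.memptr() + r;
        for (int ow = 0; ow < Wo; ++ow) {
          const int wsrc = ow * stride - pad + j;
          if (wsrc < 0 || wsrc >= W) continue;
          double* dxcol = dxc + (size_t)wsrc * H;
          for (int oh = 0; oh < Ho; ++oh) {
            const int hsrc = oh * stride - pad + i;
            if (hsrc < 0 || hsrc >= H) continue;
            dxcol[hsrc] += Mr[(size_t)(oh + Ho * ow) * dM.n_rows];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericVector w,
                        int stride, int pad) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d_fw: channel mismatch");
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout,
                     false, true);
  if (kh == 1 && kw == 1 && stride == 1 && pad == 0) {
    for (int n = 0; n < N; ++n) {
      const arma::mat Xn(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                         H * W, C, false, true);
      arma::mat Yn(y.begin() + (size_t)n * Ho * Wo * Cout, Ho * Wo, Cout,
                   false, true);
      Yn = Xn * Wm;
    }
    return y;
  }
  arma::mat M(kh * kw * Cin, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad,
           Ho, Wo, M);
    arma::mat Yn(y.begin() + (size_t)n * Ho * Wo * Cout, Ho * Wo, Cout,
                 false, true);
    Yn = M.t() * Wm;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
               int stride, int pad) {
  IntegerVector xd = dims_of(x), wd = dims_of(w), yd = dims_of(dy);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  NumericVector dx(static_cast<R_xlen_t>(H) * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw(static_cast<R_xlen_t>(kh) * kw * Cin * Cout);
  dw.attr("dim") = wd;
  const arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout,
                     false, true);
  arma::mat dWm(dw.begin(), kh * kw * Cin, Cout, false, true);
  if (kh == 1 && kw == 1 && stride == 1 && pad == 0) {
    for (int n = 0; n < N; ++n) {
      const arma::mat Xn(const_cast<double*>(x.begin()) + (size_t)n * H * W * C,
                         H * W, C, false, true);
      const arma::mat dYn(const_cast<double*>(dy.begin()) + (size_t)n * Ho * Wo * Cout,
                          Ho * Wo, Cout, false, true);
      arma::mat dXn(dx.begin() + (size_t)n * H * W * C, H * W, C, false, true);
      dXn = dYn * Wm.t();
      dWm += Xn.t() * dYn;
    }
    return List::create(_["dx"] = dx, _["dw"] = dw);
  }
  arma::mat M(kh * kw * Cin, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad,
           Ho, Wo, M);
    const arma::mat dYn(const_cast<double*>(dy.begin()) + (size_t)n * Ho * Wo * Cout,
                        Ho * Wo, Cout, false, true);
    dWm += M * dYn;
    arma::mat dM = Wm * dYn.t();
    col2im(dM, H, W, C, kh, kw, stride, pad, Ho, Wo,
           dx.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// [[Rcpp::export]]
NumericVector dwconv2d_fw(NumericVector x, NumericVector w,
                          int stride, int pad) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  if (wd[2] != C) stop("dwconv2d_fw: channel mismatch");
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)(n * C + c) * H * W;
      const double* wc = w.begin() + (size_t)c * kh * kw;
      double* yc = y.begin() + (size_t)(n * C + c) * Ho * Wo;
      for (int ow = 0; ow < Wo; ++ow) {
        for (int oh = 0; oh < Ho; ++oh) {
          double acc = 0.0;
          const int h0 = oh * stride - pad, w0 = ow * stride - pad;
          for (int j = 0; j < kw; ++j) {
            const int wsrc = w0 + j;
            if (wsrc < 0 || wsrc >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int hsrc = h0 + i;
              if (hsrc < 0 || hsrc >= H) continue;
              acc += xc[hsrc + (size_t)wsrc * H] * wc[i + kh * j];
            }
          }
          yc[oh + (size_t)ow * Ho] = acc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List dwconv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
                 int stride, int pad) {
  IntegerVector xd = dims_of(x), wd = dims_of(w), yd = dims_of(dy);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  const int Ho = yd[0], Wo = yd[1];
  NumericVector dx(static_cast<R_xlen_t>(H) * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw(static_cast<R_xlen_t>(kh) * kw * C);
  dw.attr("dim") = wd;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)(n * C + c) * H * W;
      const double* wc = w.begin() + (size_t)c * kh * kw;
      const double* dyc = dy.begin() + (size_t)(n * C + c) * Ho * Wo;
      double* dxc = dx.begin() + (size_t)(n * C + c) * H * W;
      double* dwc = dw.begin() + (size_t)c * kh * kw;
      for (int ow = 0; ow < Wo; ++ow) {
        for (int oh = 0; oh < Ho; ++oh) {
          const double g = dyc[oh + (size_t)ow * Ho];
          if (g == 0.0) continue;
          const int h0 = oh * stride - pad, w0 = ow * stride - pad;
          for (int j = 0; j < kw; ++j) {
            const int wsrc = w0 + j;
            if (wsrc < 0 || wsrc >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int hsrc = h0 + i;
              if (hsrc < 0 || hsrc >= H) continue;
              dxc[hsrc + (size_t)wsrc * H] += g * wc[i + kh * j];
              dwc[i + kh * j] += g * xc[hsrc + (size_t)wsrc * H];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}
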