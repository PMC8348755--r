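// Fused elementwise/reduction layers: batch normalization, swish,
// squeeze-excitation channel gating. These avoid the large temporary
// allocations an R-level implementation would make on 4D activations.

#include <Rcpp.h>
using namespace Rcpp;

static inline void get_dims(const NumericVector& x, int& hw, int& C, int& N) {
  IntegerVector d = as<IntegerVector>(x.attr("dim"));
  hw = d[0] * d[1];
  C = d[2];
  N = d[3];
}

// [[Rcpp::export]]
List bn_train_fw(NumericVector x, NumericVector g, NumericVector b,
                 double eps) {
  int hw, C, N;
  get_dims(x, hw, C, N);
  NumericVector mu(C), var(C);
  const double m = (double)hw * N;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)(n * C + c) * hw;
      double s = 0, s2 = 0;
      for (int i = 0; i < hw; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      mu[c] += s; var[c] += s2;
    }
  }
  NumericVector istd(C);
  for (int c = 0; c < C; ++c) {
    mu[c] /= m;
    var[c] = std::max(var[c] / m - mu[c] * mu[c], 0.0);
    istd[c] = 1.0 / std::sqrt(var[c] + eps);
  }
  NumericVector y(x.size()), xhat(x.size());
  y.attr("dim") = x.attr("dim");
  xhat.attr("dim") = x.attr("dim");
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)(n * C + c) * hw;
      const double* xc = x.begin() + off;
      double* yc = y.begin() + off;
      double* hc = xhat.begin() + off;
      const double mc = mu[c], ic = istd[c], gc = g[c], bc = b[c];
      for (int i = 0; i < hw; ++i) {
        hc[i] = (xc[i] - mc) * ic;
        yc[i] = hc[i] * gc + bc;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["istd"] = istd,
                      _["mean"] = mu, _["var"] = var);
}

// [[Rcpp::export]]
NumericVector bn_infer_fw(NumericVector x, NumericVector g, NumericVector b,
                          NumericVector mean, NumericVector var, double eps) {
  int hw, C, N;
  get_dims(x, hw, C, N);
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)(n * C + c) * hw;
      const double* xc = x.begin() + off;
      double* yc = y.begin() + off;
      const double ic = 1.0 / std::sqrt(var[c] + eps);
      const double sc = g[c] * ic, sh = b[c] - mean[c] * sc;
      for (int i = 0; i < hw; ++i) yc[i] = xc[i] * sc + sh;
    }
  }
  return y;
}

// [[Rcpp::export]]
List bn_train_bw(NumericVector xhat, NumericVector istd, NumericVector g,
                 NumericVector dy) {
  int hw, C, N;
  get_dims(xhat, hw, C, N);
  const double m = (double)hw * N;
  NumericVector dg(C), db(C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)(n * C + c) * hw;
      const double* hc = xhat.begin() + off;
      const double* dc = dy.begin() + off;
      double s1 = 0, s2 = 0;
      for (int i = 0; i < hw; ++i) { s1 += dc[i]; s2 += dc[i] * hc[i]; }
      db[c] += s1; dg[c] += s2;
    }
  }
  NumericVector dx(xhat.size());
  dx.attr("dim") = xhat.attr("dim");
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)(n * C + c) * hw;
      const double* hc = xhat.begin() + off;
      const double* dc = dy.begin() + off;
      double* xc = dx.begin() + off;
      const double k = g[c] * istd[c];
      const double m1 = db[c] / m, m2 = dg[c] / m;
      for (int i = 0; i < hw; ++i) {
        xc[i] = k * (dc[i] - m1 - hc[i] * m2);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dg"] = dg, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector swish_fw_cpp(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    y[i] = x[i] / (1.0 + std::exp(-x[i]));
  }
  return y;
}

// [[Rcpp::export]]
NumericVector swish_bw_cpp(NumericVector x, NumericVector dy) {
  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double s = 1.0 / (1.0 + std::exp(-x[i]));
    dx[i] = dy[i] * s * (1.0 + x[i] * (1.0 - s));
  }
  return dx;
}

// Multiply every (H, W) plane of v by the per-(channel, image) gate.
// [[Rcpp::export]]
NumericVector channel_gate_fw(NumericVector v, NumericMatrix gate) {
  int hw, C, N;
  get_dims(v, hw, C, N);
  NumericVector y(v.size());
  y.attr("dim") = v.attr("dim");
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)(n * C + c) * hw;
      const double gcn = gate(c, n);
      const double* vc = v.begin() + off;
      double* yc = y.begin() + off;
      for (int i = 0; i < hw; ++i) yc[i] = vc[i] * gcn;
    }
  }
  return y;
}

// Per-(channel, image) sum of elementwise products (the gate gradient).
// [[Rcpp::export]]
NumericMatrix channel_dot(NumericVector a, NumericVector b) {
  int hw, C, N;
  get_dims(a, hw, C, N);
  NumericMatrix out(C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)(n * C + c) * hw;
      const double* ac = a.begin() + off;
      const double* bc = b.begin() + off;
      double s = 0;
      for (int i = 0; i < hw; ++i) s += ac[i] * bc[i];
      out(c, n) = s;
    }
  }
  return out;
}
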