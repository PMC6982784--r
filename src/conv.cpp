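// Primitive layers of the hourglass network: 2-D convolution
// (cross-correlation) with reflection padding, per-channel batch
// normalisation, and leaky ReLU. Feature maps are H x W x C arrays
// (column-major, as R stores them); convolution weights are
// k x k x Cin x Cout arrays. Convolution builds an im2col patch matrix so
// the contraction is a single BLAS matmul; the backward pass rebuilds the
// patch matrix and scatter-adds the input gradient through the same
// reflected index map.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Reflect an out-of-range index into [0, n) without repeating the edge
// sample (PyTorch ReflectionPad2d convention).
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

// Output side length for 'same'-style padding p = (k-1)/2.
static inline int out_len(int n, int k, int stride) {
  int p = (k - 1) / 2;
  return (n + 2 * p - k) / stride + 1;
}

// Patch matrix: rows index output pixels (io + Ho*jo), columns index
// (ki, kj, ci) in R's column-major weight order ki + k*kj + k*k*ci.
static arma::mat build_patches(const double* x, int H, int W, int Cin,
                               int k, int stride, int Ho, int Wo) {
  const int p = (k - 1) / 2;
  arma::mat P(static_cast<size_t>(Ho) * Wo, static_cast<size_t>(k) * k * Cin);
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + static_cast<size_t>(ci) * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const size_t col = ki + k * kj + static_cast<size_t>(k) * k * ci;
        double* Pcol = P.colptr(col);
        for (int jo = 0; jo < Wo; ++jo) {
          const int rj = reflect_idx(jo * stride - p + kj, W);
          const double* xcol = xc + static_cast<size_t>(rj) * H;
          double* Prow = Pcol + static_cast<size_t>(jo) * Ho;
          for (int io = 0; io < Ho; ++io) {
            Prow[io] = xcol[reflect_idx(io * stride - p + ki, H)];
          }
        }
      }
    }
  }
  return P;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int k = wd[0], Cout = wd[3];
  if (wd[1] != k) stop("non-square kernel");
  if (wd[2] != Cin) stop("weight/input channel mismatch");
  const int Ho = out_len(H, k, stride), Wo = out_len(W, k, stride);

  arma::mat P = build_patches(x.begin(), H, W, Cin, k, stride, Ho, Wo);
  arma::mat Wm(w.begin(), static_cast<size_t>(k) * k * Cin, Cout, false);
  NumericVector out(static_cast<R_xlen_t>(Ho) * Wo * Cout);
  arma::mat Y(out.begin(), static_cast<size_t>(Ho) * Wo, Cout, false);
  Y = P * Wm;
  Y.each_row() += arma::rowvec(b.begin(), Cout);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int k = wd[0], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  const int p = (k - 1) / 2;

  arma::mat P = build_patches(x.begin(), H, W, Cin, k, stride, Ho, Wo);
  arma::mat dY(dy.begin(), static_cast<size_t>(Ho) * Wo, Cout, false);
  arma::mat Wm(w.begin(), static_cast<size_t>(k) * k * Cin, Cout, false);

  NumericVector dwv(w.size());
  arma::mat dW(dwv.begin(), static_cast<size_t>(k) * k * Cin, Cout, false);
  dW = P.t() * dY;
  dwv.attr("dim") = wd;
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat dP = dY * Wm.t();

  NumericVector dx(static_cast<R_xlen_t>(H) * W * Cin);
  double* dxp = dx.begin();
  for (int ci = 0; ci < Cin; ++ci) {
    double* dxc = dxp + static_cast<size_t>(ci) * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const size_t col = ki + k * kj + static_cast<size_t>(k) * k * ci;
        const double* dPcol = dP.colptr(col);
        for (int jo = 0; jo < Wo; ++jo) {
          const int rj = reflect_idx(jo * stride - p + kj, W);
          double* dxcol = dxc + static_cast<size_t>(rj) * H;
          const double* dProw = dPcol + static_cast<size_t>(jo) * Ho;
          for (int io = 0; io < Ho; ++io) {
            dxcol[reflect_idx(io * stride - p + ki, H)] += dProw[io];
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, Cin);
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Per-channel (spatial) batch normalisation, population statistics,
// eps 1e-5. Returns the output plus the normalised activations and inverse
// standard deviations needed by the backward pass.
// [[Rcpp::export(name = ".bn_fwd")]]
List bn_fwd(NumericVector x, NumericVector g, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  const int n = xd[0] * xd[1], C = xd[2];
  NumericVector out(x.size()), xhat(x.size()), invstd(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + static_cast<size_t>(c) * n;
    double* oc = out.begin() + static_cast<size_t>(c) * n;
    double* hc = xhat.begin() + static_cast<size_t>(c) * n;
    double mu = 0, ss = 0;
    for (int i = 0; i < n; ++i) mu += xc[i];
    mu /= n;
    for (int i = 0; i < n; ++i) { double d = xc[i] - mu; ss += d * d; }
    const double is = 1.0 / std::sqrt(ss / n + 1e-5);
    invstd[c] = is;
    const double gc = g[c], bc = b[c];
    for (int i = 0; i < n; ++i) {
      const double h = (xc[i] - mu) * is;
      hc[i] = h;
      oc[i] = gc * h + bc;
    }
  }
  out.attr("dim") = xd;
  return List::create(_["out"] = out, _["xhat"] = xhat, _["invstd"] = invstd);
}

// [[Rcpp::export(name = ".bn_bwd")]]
List bn_bwd(NumericVector xhat, NumericVector invstd, NumericVector g,
            NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  const int n = yd[0] * yd[1], C = yd[2];
  NumericVector dx(dy.size()), dg(C), db(C);
  for (int c = 0; c < C; ++c) {
    const double* hc = xhat.begin() + static_cast<size_t>(c) * n;
    const double* dyc = dy.begin() + static_cast<size_t>(c) * n;
    double* dxc = dx.begin() + static_cast<size_t>(c) * n;
    double s1 = 0, s2 = 0;
    for (int i = 0; i < n; ++i) {
      s1 += dyc[i];
      s2 += dyc[i] * hc[i];
    }
    dg[c] = s2;
    db[c] = s1;
    const double gc = g[c], is = invstd[c];
    const double m1 = s1 / n, m2 = s2 / n;
    for (int i = 0; i < n; ++i) {
      dxc[i] = (gc * dyc[i] - gc * m1 - hc[i] * gc * m2) * is;
    }
  }
  dx.attr("dim") = yd;
  return List::create(_["dx"] = dx, _["dg"] = dg, _["db"] = db);
}

// [[Rcpp::export(name = ".lrelu_fwd")]]
NumericVector lrelu_fwd(NumericVector x, double slope) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    out[i] = x[i] > 0 ? x[i] : slope * x[i];
  }
  out.attr("dim") = x.attr("dim");
  return out;
}

// dx from the cached *output*: out > 0 iff x > 0 (slope > 0).
// [[Rcpp::export(name = ".lrelu_bwd")]]
NumericVector lrelu_bwd(NumericVector out, NumericVector dy, double slope) {
  NumericVector dx(dy.size());
  for (R_xlen_t i = 0; i < dy.size(); ++i) {
    dx[i] = out[i] > 0 ? dy[i] : slope * dy[i];
  }
  dx.attr("dim") = dy.attr("dim");
  return dx;
}
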