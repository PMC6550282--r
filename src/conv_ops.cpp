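// Low-level CPU kernels for the network engine: batched im2col/col2im
// convolution (forward, backward-data, backward-weights) and 2x2 pooling.
// The whole minibatch is lowered into one matrix so each convolution is a
// single large GEMM.
// Layout conventions (R column-major):
//   activations: array(H, W, C, N)
//   weights:     array(k, k, C_in, C_out)
// im2col row index = ki + k*kj + k*k*c  (matches R flattening of (k,k,C)).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int H, int k, int s, int p) {
  return (H + 2 * p - k) / s + 1;
}

// fill rows [n*Ho*Wo, (n+1)*Ho*Wo) of Kt (patches x kkC) from sample x;
// both the reads from x and the writes into Kt's columns are contiguous.
static void im2col_one(const double* x, int H, int W, int C,
                       int k, int s, int p, arma::mat& Kt,
                       int Ho, int Wo, size_t row0) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int col = ki + k * kj + k * k * c;
        double* kc = Kt.colptr(col) + row0;
        for (int wo = 0; wo < Wo; ++wo) {
          int wj = wo * s + kj - p;
          double* kr = kc + (size_t)Ho * wo;
          if (wj < 0 || wj >= W) {
            for (int ho = 0; ho < Ho; ++ho) kr[ho] = 0.0;
            continue;
          }
          const double* xcol = xc + (size_t)H * wj;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * s + ki - p;
            kr[ho] = (hi >= 0 && hi < H) ? xcol[hi] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_one(const arma::mat& Gt, int H, int W, int C,
                       int k, int s, int p, double* dx,
                       int Ho, int Wo, size_t row0) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int col = ki + k * kj + k * k * c;
        const double* gc = Gt.colptr(col) + row0;
        for (int wo = 0; wo < Wo; ++wo) {
          int wj = wo * s + kj - p;
          if (wj < 0 || wj >= W) continue;
          double* xcol = xc + (size_t)H * wj;
          const double* gr = gc + (size_t)Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * s + ki - p;
            if (hi >= 0 && hi < H) xcol[hi] += gr[ho];
          }
        }
      }
    }
  }
}

static arma::mat dy_to_mat(const NumericVector& dy, int Ho, int Wo, int F, int N);

// combined backward for a stride-2 transposed convolution: one im2col of dy
// serves both the input gradient (a standard convolution of dy with W) and
// the weight gradient.
// [[Rcpp::export]]
List nn_convT_bwd(NumericVector dy, NumericVector w, NumericVector x,
                  int stride, int pad) {
  IntegerVector yd = dy.attr("dim"), wd = w.attr("dim"), xd = x.attr("dim");
  int H = yd[0], W = yd[1], C = yd[2], N = yd[3];  // dy: convT output side
  int k = wd[0], F = wd[3];                        // w: (k,k,C,F), F = in_ch
  int Ho = xd[0], Wo = xd[1];                      // x: convT input side
  size_t hw = (size_t)Ho * Wo;
  arma::mat Kt(hw * N, k * k * C);
  for (int n = 0; n < N; ++n)
    im2col_one(dy.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad,
               Kt, Ho, Wo, hw * n);
  arma::mat Wm(w.begin(), k * k * C, F, false, true);
  arma::mat Y = Kt * Wm;                 // dx as (hw*N x F)
  NumericVector dxv(hw * (size_t)F * N);
  dxv.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  double* o = dxv.begin();
  for (int f = 0; f < F; ++f) {
    const double* yc = Y.colptr(f);
    for (int n = 0; n < N; ++n) {
      double* oc = o + ((size_t)n * F + f) * hw;
      const double* yr = yc + hw * n;
      for (size_t i = 0; i < hw; ++i) oc[i] = yr[i];
    }
  }
  arma::mat xYt = dy_to_mat(x, Ho, Wo, F, N);
  arma::mat dW = Kt.t() * xYt;           // (kkC x F)
  // bias of the transposed convolution: per-channel sum of dy
  NumericVector db(C);
  size_t hwY = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    double sacc = 0;
    for (int n = 0; n < N; ++n) {
      const double* gc = dy.begin() + ((size_t)n * C + c) * hwY;
      for (size_t i = 0; i < hwY; ++i) sacc += gc[i];
    }
    db[c] = sacc;
  }
  NumericVector dWr(dW.begin(), dW.end());
  dWr.attr("dim") = IntegerVector::create(k, k, C, F);
  return List::create(_["dx"] = dxv, _["dW"] = dWr, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector nn_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                          int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], F = wd[3];
  if (wd[2] != C) stop("channel mismatch in conv forward");
  int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  size_t hw = (size_t)Ho * Wo;
  arma::mat Kt(hw * N, k * k * C);
  for (int n = 0; n < N; ++n)
    im2col_one(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad,
               Kt, Ho, Wo, hw * n);
  arma::mat Wm(w.begin(), k * k * C, F, false, true);
  arma::mat Y = Kt * Wm;  // (hw*N x F)
  NumericVector out(hw * (size_t)F * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  double* o = out.begin();
  for (int f = 0; f < F; ++f) {
    const double* yc = Y.colptr(f);
    double bf = b[f];
    for (int n = 0; n < N; ++n) {
      double* oc = o + ((size_t)n * F + f) * hw;
      const double* yr = yc + hw * n;
      for (size_t i = 0; i < hw; ++i) oc[i] = yr[i] + bf;
    }
  }
  return out;
}

// assemble (hw*N x F) matrix from a (Ho, Wo, F, N) gradient array
static arma::mat dy_to_mat(const NumericVector& dy, int Ho, int Wo, int F, int N) {
  size_t hw = (size_t)Ho * Wo;
  arma::mat dYt(hw * N, F);
  const double* g = dy.begin();
  for (int f = 0; f < F; ++f) {
    double* dc = dYt.colptr(f);
    for (int n = 0; n < N; ++n)
      memcpy(dc + hw * n, g + ((size_t)n * F + f) * hw, hw * sizeof(double));
  }
  return dYt;
}

// [[Rcpp::export]]
List nn_conv_bwd_w(NumericVector x, NumericVector dy, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = yd[0], Wo = yd[1], F = yd[2];
  size_t hw = (size_t)Ho * Wo;
  arma::mat Kt(hw * N, k * k * C);
  for (int n = 0; n < N; ++n)
    im2col_one(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad,
               Kt, Ho, Wo, hw * n);
  arma::mat dYt = dy_to_mat(dy, Ho, Wo, F, N);
  arma::mat dW = Kt.t() * dYt;        // (kkC x F)
  arma::vec db = arma::sum(dYt, 0).t();
  NumericVector dWr(dW.begin(), dW.end());
  dWr.attr("dim") = IntegerVector::create(k, k, C, F);
  return List::create(_["dW"] = dWr, _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
NumericVector nn_conv_bwd_data(NumericVector dy, NumericVector w,
                               int stride, int pad, int H, int W) {
  IntegerVector yd = dy.attr("dim"), wd = w.attr("dim");
  int Ho = yd[0], Wo = yd[1], F = yd[2], N = yd[3];
  int k = wd[0], C = wd[2];
  if (wd[3] != F) stop("channel mismatch in conv backward-data");
  size_t hw = (size_t)Ho * Wo;
  arma::mat Wm(w.begin(), k * k * C, F, false, true);
  arma::mat dYt = dy_to_mat(dy, Ho, Wo, F, N);
  arma::mat Gt = dYt * Wm.t();  // (hw*N x kkC)
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    col2im_one(Gt, H, W, C, k, stride, pad,
               dx.begin() + (size_t)n * H * W * C, Ho, Wo, hw * n);
  return dx;
}

// 2x2 pooling, stride 2, floor output dims. mode: 0 = max, 1 = average.
// [[Rcpp::export]]
List nn_pool_fwd(NumericVector x, int mode) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector out((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(mode == 0 ? (size_t)Ho * Wo * C * N : 0);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      double* oc = out.begin() + ((size_t)n * C + c) * Ho * Wo;
      int* ic = mode == 0 ? idx.begin() + ((size_t)n * C + c) * Ho * Wo : NULL;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          int h0 = 2 * ho, w0 = 2 * wo;
          double v00 = xc[h0 + (size_t)H * w0], v10 = xc[h0 + 1 + (size_t)H * w0];
          double v01 = xc[h0 + (size_t)H * (w0 + 1)], v11 = xc[h0 + 1 + (size_t)H * (w0 + 1)];
          if (mode == 1) {
            oc[ho + (size_t)Ho * wo] = 0.25 * (v00 + v10 + v01 + v11);
          } else {
            double best = v00; int bi = 0;
            if (v10 > best) { best = v10; bi = 1; }
            if (v01 > best) { best = v01; bi = 2; }
            if (v11 > best) { best = v11; bi = 3; }
            oc[ho + (size_t)Ho * wo] = best;
            ic[ho + (size_t)Ho * wo] = bi;
          }
        }
    }
  if (mode == 0) {
    idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
    return List::create(_["y"] = out, _["idx"] = idx);
  }
  return List::create(_["y"] = out);
}

// [[Rcpp::export]]
NumericVector nn_pool_bwd(NumericVector dy, Nullable<IntegerVector> idx_,
                          int H, int W, int mode) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  IntegerVector idx;
  if (mode == 0) idx = idx_.get();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = dx.begin() + ((size_t)n * C + c) * H * W;
      const double* gc = dy.begin() + ((size_t)n * C + c) * Ho * Wo;
      const int* ic = mode == 0 ? idx.begin() + ((size_t)n * C + c) * Ho * Wo : NULL;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double g = gc[ho + (size_t)Ho * wo];
          int h0 = 2 * ho, w0 = 2 * wo;
          if (mode == 1) {
            double q = 0.25 * g;
            xc[h0 + (size_t)H * w0] += q;
            xc[h0 + 1 + (size_t)H * w0] += q;
            xc[h0 + (size_t)H * (w0 + 1)] += q;
            xc[h0 + 1 + (size_t)H * (w0 + 1)] += q;
          } else {
            int bi = ic[ho + (size_t)Ho * wo];
            int hh = h0 + (bi & 1), ww = w0 + (bi >> 1);
            xc[hh + (size_t)H * ww] += g;
          }
        }
    }
  return dx;
}

// batch-norm helpers: per-channel moments and normalisation for (H,W,C,N)
// arrays, avoiding R-level aperm/sweep copies.

// [[Rcpp::export]]
List nn_bn_stats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t hw = (size_t)H * W;
  NumericVector m(C), v(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * hw;
      for (size_t i = 0; i < hw; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    }
    double mu = s / (hw * N);
    m[c] = mu;
    double var = s2 / (hw * N) - mu * mu;
    v[c] = var > 0 ? var : 0;
  }
  return List::create(_["mean"] = m, _["var"] = v);
}

// y = (x - m[c]) * a[c] + b[c]  (channelwise affine)
// [[Rcpp::export]]
NumericVector nn_bn_apply(NumericVector x, NumericVector m, NumericVector a,
                          NumericVector b) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t hw = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * hw;
      double* yc = y.begin() + ((size_t)n * C + c) * hw;
      double mc = m[c], ac = a[c], bc = b[c];
      for (size_t i = 0; i < hw; ++i) yc[i] = (xc[i] - mc) * ac + bc;
    }
  return y;
}

// channelwise sums of dy and dy*xh, plus channel means
// [[Rcpp::export]]
List nn_bn_bwd_stats(NumericVector dy, NumericVector xh) {
  IntegerVector xd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t hw = (size_t)H * W;
  NumericVector s_dy(C), s_dyxh(C);
  for (int c = 0; c < C; ++c) {
    double a = 0, b = 0;
    for (int n = 0; n < N; ++n) {
      const double* gc = dy.begin() + ((size_t)n * C + c) * hw;
      const double* hc = xh.begin() + ((size_t)n * C + c) * hw;
      for (size_t i = 0; i < hw; ++i) { a += gc[i]; b += gc[i] * hc[i]; }
    }
    s_dy[c] = a; s_dyxh[c] = b;
  }
  return List::create(_["sum_dy"] = s_dy, _["sum_dyxh"] = s_dyxh);
}

// dx = (dy - mean_dy[c] - xh * mean_dyxh[c]) * a[c]
// [[Rcpp::export]]
NumericVector nn_bn_bwd_apply(NumericVector dy, NumericVector xh,
                              NumericVector m_dy, NumericVector m_dyxh,
                              NumericVector a) {
  IntegerVector xd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t hw = (size_t)H * W;
  NumericVector dx(dy.size());
  dx.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gc = dy.begin() + ((size_t)n * C + c) * hw;
      const double* hc = xh.begin() + ((size_t)n * C + c) * hw;
      double* oc = dx.begin() + ((size_t)n * C + c) * hw;
      double md = m_dy[c], mh = m_dyxh[c], ac = a[c];
      for (size_t i = 0; i < hw; ++i) oc[i] = (gc[i] - md - hc[i] * mh) * ac;
    }
  return dx;
}
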