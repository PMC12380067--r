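// Convolution and pooling kernels for the dual-branch decoder.
// Activation layout throughout: column-major array (W, H, C, N) with W the
// fastest-varying (time / spectrogram-frame) axis. Weight layout:
// (KW, KH, Cin, Cout). Stride is 1 for convolutions; pooling is
// non-overlapping with stride equal to the pool size.
//
// Convolutions go through one batched im2col (rows = position x sample,
// cols = kernel tap x input map) and a single BLAS gemm; valid output
// ranges per kernel tap are computed analytically so zero padding is
// skipped rather than scanned.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int* d) {
  IntegerVector dd = x.attr("dim");
  if (dd.size() != 4) stop("expected a 4-D array");
  for (int i = 0; i < 4; ++i) d[i] = dd[i];
}

// valid output range [lo, hi] along one axis for a given kernel tap
static inline void valid_range(int k, int d, int p, int s, int in_n,
                               int out_n, int* lo, int* hi) {
  int off = p - k * d;                 // in = out*s - off
  *lo = off <= 0 ? 0 : (off + s - 1) / s;
  int top = in_n - 1 + off;
  *hi = top < 0 ? -1 : std::min(out_n - 1, top / s);
}

// Batched im2col: out is (Wo*Ho*N) x (KW*KH*Cin); row index is
// ow + Wo*oh + Wo*Ho*n.
static void im2col_all(const double* x, int W, int H, int C, int N,
                       int KW, int KH, int dw, int dh, int pw, int ph,
                       int sw, int sh, int Wo, int Ho, arma::mat& col) {
  const int P = Wo * Ho;
  col.zeros();
  for (int ci = 0; ci < C; ++ci) {
    for (int kh = 0; kh < KH; ++kh) {
      for (int kw = 0; kw < KW; ++kw) {
        int k = kw + KW * (kh + KH * ci);
        double* dst = col.colptr(k);
        int ow_lo, ow_hi;
        valid_range(kw, dw, pw, sw, W, Wo, &ow_lo, &ow_hi);
        if (ow_lo > ow_hi) continue;
        for (int n = 0; n < N; ++n) {
          const double* xc = x + ((size_t)n * C + ci) * W * H;
          for (int oh = 0; oh < Ho; ++oh) {
            int ih = oh * sh - ph + kh * dh;
            if (ih < 0 || ih >= H) continue;
            const double* xrow = xc + (size_t)ih * W +
              (ow_lo * sw - pw + kw * dw);
            double* drow = dst + (size_t)n * P + (size_t)oh * Wo + ow_lo;
            int len = ow_hi - ow_lo + 1;
            if (sw == 1) std::copy(xrow, xrow + len, drow);
            else for (int t = 0; t < len; ++t) drow[t] = xrow[(size_t)t * sw];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector bias,
                        int dh, int dw, int ph, int pw, int sh, int sw) {
  int xd[4], wd[4];
  get_dims4(x, xd); get_dims4(w, wd);
  int W = xd[0], H = xd[1], C = xd[2], N = xd[3];
  int KW = wd[0], KH = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch in conv2d");
  int Wo = (W + 2 * pw - (dw * (KW - 1) + 1)) / sw + 1;
  int Ho = (H + 2 * ph - (dh * (KH - 1) + 1)) / sh + 1;
  if (Wo < 1 || Ho < 1) stop("conv2d output would be empty");
  int P = Wo * Ho, K = KW * KH * Cin;
  arma::mat wmat(const_cast<double*>(w.begin()), K, Cout, false, true);
  static thread_local arma::mat col;
  col.set_size((size_t)P * N, K);
  im2col_all(x.begin(), W, H, C, N, KW, KH, dw, dh, pw, ph, sw, sh, Wo, Ho,
             col);
  arma::mat out = col * wmat;                       // (P*N) x Cout
  NumericVector y((size_t)P * Cout * N);
  y.attr("dim") = IntegerVector::create(Wo, Ho, Cout, N);
  // reorder (p, n) x c -> (p, c, n)
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < Cout; ++c) {
      const double* src = out.colptr(c) + (size_t)n * P;
      double* dst = y.begin() + ((size_t)n * Cout + c) * P;
      double bc = bias[c];
      for (int p = 0; p < P; ++p) dst[p] = src[p] + bc;
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
               int dh, int dw, int ph, int pw, int sh, int sw) {
  int xd[4], wd[4], gd[4];
  get_dims4(x, xd); get_dims4(w, wd); get_dims4(gy, gd);
  int W = xd[0], H = xd[1], C = xd[2], N = xd[3];
  int KW = wd[0], KH = wd[1], Cin = wd[2], Cout = wd[3];
  int Wo = gd[0], Ho = gd[1];
  int P = Wo * Ho, K = KW * KH * Cin;
  arma::mat wmat(const_cast<double*>(w.begin()), K, Cout, false, true);
  // gather gy into (P*N) x Cout
  static thread_local arma::mat gout;
  gout.set_size((size_t)P * N, Cout);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < Cout; ++c) {
      const double* src = gy.begin() + ((size_t)n * Cout + c) * P;
      std::copy(src, src + P, gout.colptr(c) + (size_t)n * P);
    }
  }
  static thread_local arma::mat col;
  col.set_size((size_t)P * N, K);
  im2col_all(x.begin(), W, H, C, N, KW, KH, dw, dh, pw, ph, sw, sh, Wo, Ho,
             col);
  arma::mat gwmat = col.t() * gout;                 // K x Cout
  arma::rowvec gb = arma::sum(gout, 0);
  static thread_local arma::mat gcol;
  gcol.set_size((size_t)P * N, K);
  gcol = gout * wmat.t();                           // (P*N) x K
  NumericVector gx((size_t)W * H * C * N);
  gx.attr("dim") = IntegerVector::create(W, H, C, N);
  for (int ci = 0; ci < C; ++ci) {
    for (int kh = 0; kh < KH; ++kh) {
      for (int kw = 0; kw < KW; ++kw) {
        int k = kw + KW * (kh + KH * ci);
        const double* src0 = gcol.colptr(k);
        int ow_lo, ow_hi;
        valid_range(kw, dw, pw, sw, W, Wo, &ow_lo, &ow_hi);
        if (ow_lo > ow_hi) continue;
        for (int n = 0; n < N; ++n) {
          double* gxc = gx.begin() + ((size_t)n * C + ci) * W * H;
          for (int oh = 0; oh < Ho; ++oh) {
            int ih = oh * sh - ph + kh * dh;
            if (ih < 0 || ih >= H) continue;
            const double* src = src0 + (size_t)n * P + (size_t)oh * Wo + ow_lo;
            double* dst = gxc + (size_t)ih * W + (ow_lo * sw - pw + kw * dw);
            int len = ow_hi - ow_lo + 1;
            for (int t = 0; t < len; ++t) dst[(size_t)t * sw] += src[t];
          }
        }
      }
    }
  }
  NumericVector gwv(gwmat.begin(), gwmat.end());
  gwv.attr("dim") = IntegerVector::create(KW, KH, Cin, Cout);
  return List::create(_["gx"] = gx, _["gw"] = gwv,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// [[Rcpp::export]]
List maxpool_fw(NumericVector x, int ph, int pw) {
  int xd[4];
  get_dims4(x, xd);
  int W = xd[0], H = xd[1], C = xd[2], N = xd[3];
  int Wo = W / pw, Ho = H / ph;
  if (Wo < 1 || Ho < 1) stop("pool size larger than input");
  NumericVector y((size_t)Wo * Ho * C * N);
  y.attr("dim") = IntegerVector::create(Wo, Ho, C, N);
  IntegerVector idx((size_t)Wo * Ho * C * N);  // 0-based index into x
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)(c + (size_t)C * n) * W * H;
      size_t base = (size_t)(c + (size_t)C * n) * W * H;
      for (int oh = 0; oh < Ho; ++oh) {
        for (int ow = 0; ow < Wo; ++ow) {
          double best = -std::numeric_limits<double>::infinity();
          size_t besti = 0;
          for (int kh = 0; kh < ph; ++kh) {
            size_t ih = (size_t)oh * ph + kh;
            for (int kw = 0; kw < pw; ++kw) {
              size_t iw = (size_t)ow * pw + kw;
              double v = xc[iw + ih * W];
              if (v > best) { best = v; besti = base + iw + ih * W; }
            }
          }
          size_t yo = (size_t)ow + Wo * ((size_t)oh + Ho * (c + (size_t)C * n));
          y[yo] = best;
          idx[yo] = (int)besti;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bw(IntegerVector idx, NumericVector gy,
                         IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  return gx;
}
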