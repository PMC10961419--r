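#include <Rcpp.h>
using namespace Rcpp;

// Activation layout throughout: column-major array with dim c(C, H, W, N),
// i.e. linear index c + C*(h + H*(w + W*n)), all 0-based here.
// im2col rows are ordered (c fastest, then ki, then kj) so that an R weight
// array of dim c(Cin, kh, kw, Cout) reshapes directly to the matching matrix.

static inline int out_extent(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// [[Rcpp::export]]
NumericMatrix im2col_chw(const NumericVector& x, int C, int H, int W, int N,
                         int kh, int kw, int sh, int sw, int ph, int pw) {
  const int oh = out_extent(H, kh, sh, ph), ow = out_extent(W, kw, sw, pw);
  NumericMatrix cols(C * kh * kw, oh * ow * N);
  double* cp = cols.begin();
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int oj = 0; oj < ow; ++oj) {
      for (int oi = 0; oi < oh; ++oi) {
        const long col = (long)oi + (long)oh * (oj + (long)ow * n);
        double* dst = cp + col * (long)(C * kh * kw);
        for (int kj = 0; kj < kw; ++kj) {
          const int w = oj * sw - pw + kj;
          for (int ki = 0; ki < kh; ++ki) {
            const int h = oi * sh - ph + ki;
            double* d = dst + (long)C * (ki + kh * kj);
            if (h >= 0 && h < H && w >= 0 && w < W) {
              const double* s = xp + (long)C * (h + (long)H * (w + (long)W * n));
              for (int c = 0; c < C; ++c) d[c] = s[c];
            } else {
              for (int c = 0; c < C; ++c) d[c] = 0.0;
            }
          }
        }
      }
    }
  }
  return cols;
}

// Reverse of im2col: scatter-add patch columns back onto the input grid.
// [[Rcpp::export]]
NumericVector col2im_chw(const NumericMatrix& cols, int C, int H, int W, int N,
                         int kh, int kw, int sh, int sw, int ph, int pw) {
  const int oh = out_extent(H, kh, sh, ph), ow = out_extent(W, kw, sw, pw);
  NumericVector x((long)C * H * W * N);
  double* xp = x.begin();
  const double* cp = cols.begin();
  for (int n = 0; n < N; ++n) {
    for (int oj = 0; oj < ow; ++oj) {
      for (int oi = 0; oi < oh; ++oi) {
        const long col = (long)oi + (long)oh * (oj + (long)ow * n);
        const double* src = cp + col * (long)(C * kh * kw);
        for (int kj = 0; kj < kw; ++kj) {
          const int w = oj * sw - pw + kj;
          if (w < 0 || w >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int h = oi * sh - ph + ki;
            if (h < 0 || h >= H) continue;
            const double* s = src + (long)C * (ki + kh * kj);
            double* d = xp + (long)C * (h + (long)H * (w + (long)W * n));
            for (int c = 0; c < C; ++c) d[c] += s[c];
          }
        }
      }
    }
  }
  return x;
}

// Depthwise convolution; weight layout dim c(kh, kw, C).
// [[Rcpp::export]]
NumericVector dwconv_fwd(const NumericVector& x, const NumericVector& w,
                         int C, int H, int W, int N,
                         int kh, int kw, int sh, int sw, int ph, int pw) {
  const int oh = out_extent(H, kh, sh, ph), ow = out_extent(W, kw, sw, pw);
  NumericVector out((long)C * oh * ow * N);
  double* op = out.begin();
  const double* xp = x.begin();
  const double* wp = w.begin();
  for (int n = 0; n < N; ++n) {
    for (int oj = 0; oj < ow; ++oj) {
      for (int oi = 0; oi < oh; ++oi) {
        double* dst = op + (long)C * (oi + (long)oh * (oj + (long)ow * n));
        for (int kj = 0; kj < kw; ++kj) {
          const int ww = oj * sw - pw + kj;
          if (ww < 0 || ww >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int hh = oi * sh - ph + ki;
            if (hh < 0 || hh >= H) continue;
            const double* s = xp + (long)C * (hh + (long)H * (ww + (long)W * n));
            // weight layout is (kh, kw, C): w[ki + kh*(kj + kw*c)]
            for (int c = 0; c < C; ++c)
              dst[c] += s[c] * wp[ki + kh * (kj + kw * c)];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector dwconv_bwd_input(const NumericVector& gout, const NumericVector& w,
                               int C, int H, int W, int N,
                               int kh, int kw, int sh, int sw, int ph, int pw) {
  const int oh = out_extent(H, kh, sh, ph), ow = out_extent(W, kw, sw, pw);
  NumericVector gx((long)C * H * W * N);
  double* gp = gx.begin();
  const double* op = gout.begin();
  const double* wp = w.begin();
  for (int n = 0; n < N; ++n) {
    for (int oj = 0; oj < ow; ++oj) {
      for (int oi = 0; oi < oh; ++oi) {
        const double* g = op + (long)C * (oi + (long)oh * (oj + (long)ow * n));
        for (int kj = 0; kj < kw; ++kj) {
          const int ww = oj * sw - pw + kj;
          if (ww < 0 || ww >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int hh = oi * sh - ph + ki;
            if (hh < 0 || hh >= H) continue;
            double* d = gp + (long)C * (hh + (long)H * (ww + (long)W * n));
            for (int c = 0; c < C; ++c)
              d[c] += g[c] * wp[ki + kh * (kj + kw * c)];
          }
        }
      }
    }
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector dwconv_bwd_weight(const NumericVector& x, const NumericVector& gout,
                                int C, int H, int W, int N,
                                int kh, int kw, int sh, int sw, int ph, int pw) {
  const int oh = out_extent(H, kh, sh, ph), ow = out_extent(W, kw, sw, pw);
  NumericVector gw((long)kh * kw * C);
  double* wp = gw.begin();
  const double* xp = x.begin();
  const double* op = gout.begin();
  for (int n = 0; n < N; ++n) {
    for (int oj = 0; oj < ow; ++oj) {
      for (int oi = 0; oi < oh; ++oi) {
        const double* g = op + (long)C * (oi + (long)oh * (oj + (long)ow * n));
        for (int kj = 0; kj < kw; ++kj) {
          const int ww = oj * sw - pw + kj;
          if (ww < 0 || ww >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int hh = oi * sh - ph + ki;
            if (hh < 0 || hh >= H) continue;
            const double* s = xp + (long)C * (hh + (long)H * (ww + (long)W * n));
            for (int c = 0; c < C; ++c)
              wp[ki + kh * (kj + kw * c)] += g[c] * s[c];
          }
        }
      }
    }
  }
  return gw;
}

// Max pooling; padding cells count as -Inf. Returns the pooled map plus the
// 1-based linear index of each winning input cell (0 when the window saw
// only padding) for the backward scatter.
// [[Rcpp::export]]
List maxpool_fwd(const NumericVector& x, int C, int H, int W, int N,
                 int kh, int kw, int sh, int sw, int ph, int pw) {
  const int oh = out_extent(H, kh, sh, ph), ow = out_extent(W, kw, sw, pw);
  NumericVector out((long)C * oh * ow * N);
  IntegerVector arg((long)C * oh * ow * N);
  const double* xp = x.begin();
  double* op = out.begin();
  int* ap = arg.begin();
  for (int n = 0; n < N; ++n) {
    for (int oj = 0; oj < ow; ++oj) {
      for (int oi = 0; oi < oh; ++oi) {
        const long base = (long)C * (oi + (long)oh * (oj + (long)ow * n));
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf;
          long bidx = -1;
          for (int kj = 0; kj < kw; ++kj) {
            const int ww = oj * sw - pw + kj;
            if (ww < 0 || ww >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int hh = oi * sh - ph + ki;
              if (hh < 0 || hh >= H) continue;
              const long idx = c + (long)C * (hh + (long)H * (ww + (long)W * n));
              if (xp[idx] > best) { best = xp[idx]; bidx = idx; }
            }
          }
          op[base + c] = (bidx >= 0) ? best : 0.0;
          ap[base + c] = (bidx >= 0) ? (int)(bidx + 1) : 0;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd(const NumericVector& gout, const IntegerVector& argmax,
                          int C, int H, int W, int N) {
  NumericVector gx((long)C * H * W * N);
  double* gp = gx.begin();
  const double* op = gout.begin();
  const int* ap = argmax.begin();
  const long M = gout.size();
  for (long i = 0; i < M; ++i)
    if (ap[i] > 0) gp[ap[i] - 1] += op[i];
  return gx;
}
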