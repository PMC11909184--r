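#include <Rcpp.h>
using namespace Rcpp;

// Dense single-threaded conv/pool kernels for the hashing encoder.
// Array layout is R column-major with dim (H, W, C, B) for activations and
// (kh, kw, Cin, Cout) for filters, so the innermost loops run down columns.

static inline int outLen(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// [[Rcpp::export]]
NumericVector conv2dForwardC(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             NumericVector bias, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cin = wdim[2], Cout = wdim[3];
  if (Cin != C) stop("filter input channels do not match activations");
  const int Ho = outLen(H, kh, stride, pad), Wo = outLen(W, kw, stride, pad);
  NumericVector out((R_xlen_t)Ho * Wo * Cout * B);
  const double *xp = x.begin(), *wp = w.begin();
  double *op = out.begin();
  for (int b = 0; b < B; ++b) {
    const double *xb = xp + (R_xlen_t)H * W * C * b;
    for (int co = 0; co < Cout; ++co) {
      const double bv = bias[co];
      const double *wc = wp + (R_xlen_t)kh * kw * Cin * co;
      for (int wo = 0; wo < Wo; ++wo) {
        const int w0 = wo * stride - pad;
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = ho * stride - pad;
          double acc = bv;
          for (int ci = 0; ci < Cin; ++ci) {
            const double *xc = xb + (R_xlen_t)H * W * ci;
            const double *wk = wc + (R_xlen_t)kh * kw * ci;
            for (int kj = 0; kj < kw; ++kj) {
              const int wi = w0 + kj;
              if (wi < 0 || wi >= W) continue;
              const double *xcol = xc + (R_xlen_t)H * wi;
              const double *wcol = wk + (R_xlen_t)kh * kj;
              for (int ki = 0; ki < kh; ++ki) {
                const int hi = h0 + ki;
                if (hi < 0 || hi >= H) continue;
                acc += xcol[hi] * wcol[ki];
              }
            }
          }
          op[ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * (co + (R_xlen_t)Cout * b))] = acc;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  return out;
}

// [[Rcpp::export]]
List conv2dBackwardC(NumericVector x, IntegerVector xdim,
                     NumericVector w, IntegerVector wdim,
                     NumericVector gout, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cin = wdim[2], Cout = wdim[3];
  const int Ho = outLen(H, kh, stride, pad), Wo = outLen(W, kw, stride, pad);
  NumericVector gx((R_xlen_t)H * W * C * B);
  NumericVector gw((R_xlen_t)kh * kw * Cin * Cout);
  NumericVector gb(Cout);
  const double *xp = x.begin(), *wp = w.begin(), *gp = gout.begin();
  double *gxp = gx.begin(), *gwp = gw.begin(), *gbp = gb.begin();
  for (int b = 0; b < B; ++b) {
    const double *xb = xp + (R_xlen_t)H * W * C * b;
    double *gxb = gxp + (R_xlen_t)H * W * C * b;
    for (int co = 0; co < Cout; ++co) {
      const double *wc = wp + (R_xlen_t)kh * kw * Cin * co;
      double *gwc = gwp + (R_xlen_t)kh * kw * Cin * co;
      for (int wo = 0; wo < Wo; ++wo) {
        const int w0 = wo * stride - pad;
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = ho * stride - pad;
          const double g = gp[ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * (co + (R_xlen_t)Cout * b))];
          if (g == 0.0) continue;
          gbp[co] += g;
          for (int ci = 0; ci < Cin; ++ci) {
            const double *xc = xb + (R_xlen_t)H * W * ci;
            double *gxc = gxb + (R_xlen_t)H * W * ci;
            const double *wk = wc + (R_xlen_t)kh * kw * ci;
            double *gwk = gwc + (R_xlen_t)kh * kw * ci;
            for (int kj = 0; kj < kw; ++kj) {
              const int wi = w0 + kj;
              if (wi < 0 || wi >= W) continue;
              for (int ki = 0; ki < kh; ++ki) {
                const int hi = h0 + ki;
                if (hi < 0 || hi >= H) continue;
                const R_xlen_t xi = hi + (R_xlen_t)H * wi;
                const R_xlen_t wiidx = ki + (R_xlen_t)kh * kj;
                gxc[xi] += wk[wiidx] * g;
                gwk[wiidx] += xc[xi] * g;
              }
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  gw.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List maxPoolForwardC(NumericVector x, IntegerVector xdim, int size, int stride) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  const int Ho = (H - size) / stride + 1, Wo = (W - size) / stride + 1;
  NumericVector out((R_xlen_t)Ho * Wo * C * B);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * B); // 1-based linear index into x
  const double *xp = x.begin();
  double *op = out.begin();
  int *ip = idx.begin();
  R_xlen_t o = 0;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = (R_xlen_t)H * W * (c + (R_xlen_t)C * b);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = ho * stride, w0 = wo * stride;
          double best = R_NegInf;
          R_xlen_t besti = base + h0 + (R_xlen_t)H * w0;
          for (int kj = 0; kj < size; ++kj) {
            const int wi = w0 + kj;
            if (wi >= W) continue;
            for (int ki = 0; ki < size; ++ki) {
              const int hi = h0 + ki;
              if (hi >= H) continue;
              const R_xlen_t xi = base + hi + (R_xlen_t)H * wi;
              if (xp[xi] > best) { best = xp[xi]; besti = xi; }
            }
          }
          // output laid out (Ho, Wo, C, B): recompute target slot
          const R_xlen_t oi = ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * (c + (R_xlen_t)C * b));
          op[oi] = best;
          ip[oi] = (int)(besti + 1);
          ++o;
        }
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxPoolBackwardC(NumericVector gout, IntegerVector idx, IntegerVector xdim) {
  NumericVector gx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  double *gxp = gx.begin();
  const double *gp = gout.begin();
  const int *ip = idx.begin();
  const R_xlen_t n = gout.size();
  for (R_xlen_t i = 0; i < n; ++i) gxp[ip[i] - 1] += gp[i];
  gx.attr("dim") = xdim;
  return gx;
}
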