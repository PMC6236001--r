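#include <Rcpp.h>
using namespace Rcpp;

// Strided 2-D cross-correlation over a batch.
// x: H x W x C x N, w: KH x KW x C x Z, b: length Z.
// Padding amounts are explicit per side so that both the symmetric
// (explicit N) and the asymmetric ("same", TensorFlow-style) schemes
// reduce to one kernel.
// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w, NumericVector b,
                                 int stride, int pt, int pb, int pl, int pr) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  if (xd.size() != 4 || wd.size() != 4) stop("conv2d expects 4-d input and filters");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int KH = wd[0], KW = wd[1], Z = wd[3];
  if (wd[2] != C)
    stop("ChannelMismatch: filter depth %d != input depth %d", (int)wd[2], C);
  if (H + pt + pb < KH || W + pl + pr < KW) stop("NonPositiveOutput");
  const int HO = 1 + (H + pt + pb - KH) / stride;
  const int WO = 1 + (W + pl + pr - KW) / stride;

  NumericVector y(static_cast<R_xlen_t>(HO) * WO * Z * N);
  y.attr("dim") = IntegerVector::create(HO, WO, Z, N);
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  double* yp = REAL(y);

  for (int n = 0; n < N; ++n)
    for (int z = 0; z < Z; ++z)
      for (int ow = 0; ow < WO; ++ow) {
        const int wi0 = ow * stride - pl;
        for (int oh = 0; oh < HO; ++oh) {
          const int hi0 = oh * stride - pt;
          double acc = b[z];
          for (int c = 0; c < C; ++c) {
            const double* xc = xp + static_cast<R_xlen_t>(H) * (W * (c + static_cast<R_xlen_t>(C) * n));
            const double* wc = wp + static_cast<R_xlen_t>(KH) * (KW * (c + static_cast<R_xlen_t>(C) * z));
            for (int kw = 0; kw < KW; ++kw) {
              const int wi = wi0 + kw;
              if (wi < 0 || wi >= W) continue;
              const double* xcol = xc + static_cast<R_xlen_t>(H) * wi;
              const double* wcol = wc + static_cast<R_xlen_t>(KH) * kw;
              for (int kh = 0; kh < KH; ++kh) {
                const int hi = hi0 + kh;
                if (hi < 0 || hi >= H) continue;
                acc += xcol[hi] * wcol[kh];
              }
            }
          }
          yp[oh + static_cast<R_xlen_t>(HO) * (ow + static_cast<R_xlen_t>(WO) * (z + static_cast<R_xlen_t>(Z) * n))] = acc;
        }
      }
  return y;
}

// Gradients of conv2d_forward_cpp w.r.t. input, filters and bias.
// dy: HO x WO x Z x N (same shape the forward produced).
// [[Rcpp::export]]
List conv2d_backward_cpp(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pt, int pl) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int KH = wd[0], KW = wd[1], Z = wd[3];
  const int HO = yd[0], WO = yd[1];

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Z);

  const double* xp = REAL(x);
  const double* wp = REAL(w);
  const double* dyp = REAL(dy);
  double* dxp = REAL(dx);
  double* dwp = REAL(dw);
  double* dbp = REAL(db);

  for (int n = 0; n < N; ++n)
    for (int z = 0; z < Z; ++z)
      for (int ow = 0; ow < WO; ++ow) {
        const int wi0 = ow * stride - pl;
        for (int oh = 0; oh < HO; ++oh) {
          const int hi0 = oh * stride - pt;
          const double g = dyp[oh + static_cast<R_xlen_t>(HO) * (ow + static_cast<R_xlen_t>(WO) * (z + static_cast<R_xlen_t>(Z) * n))];
          if (g == 0.0) continue;
          dbp[z] += g;
          for (int c = 0; c < C; ++c) {
            const R_xlen_t xoff = static_cast<R_xlen_t>(H) * (W * (c + static_cast<R_xlen_t>(C) * n));
            const R_xlen_t woff = static_cast<R_xlen_t>(KH) * (KW * (c + static_cast<R_xlen_t>(C) * z));
            for (int kw = 0; kw < KW; ++kw) {
              const int wi = wi0 + kw;
              if (wi < 0 || wi >= W) continue;
              for (int kh = 0; kh < KH; ++kh) {
                const int hi = hi0 + kh;
                if (hi < 0 || hi >= H) continue;
                const R_xlen_t xi = xoff + static_cast<R_xlen_t>(H) * wi + hi;
                const R_xlen_t wi_ = woff + static_cast<R_xlen_t>(KH) * kw + kh;
                dxp[xi] += g * wp[wi_];
                dwp[wi_] += g * xp[xi];
              }
            }
          }
        }
      }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
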