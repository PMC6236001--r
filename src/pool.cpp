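#include <Rcpp.h>
using namespace Rcpp;

// Pooling over H x W x C x N maps with "same"-style explicit padding.
// Padded positions are excluded from the region: max is taken over in-bounds
// elements, the average denominator counts only in-bounds elements, and the
// stochastic multinomial is formed over in-bounds elements only (zeros from
// padding would bias all three).
//
// mode: 0 = max, 1 = average, 2 = stochastic sample (training; draws from
// the multinomial p_i = x_i / sum(x), consuming R's RNG stream), 3 =
// stochastic expectation (inference; sum p_i * x_i).
//
// Returns the pooled map plus, for modes 0 and 2, the 1-based linear index
// of the selected element within each input H x W plane (NA-like -1 when a
// stochastic region is all zero), which the backward pass routes gradient to.
// [[Rcpp::export]]
List pool2d_forward_cpp(NumericVector x, int kernel, int stride,
                        int pt, int pl, int mode) {
  IntegerVector xd = x.attr("dim");
  if (xd.size() != 4) stop("pool2d expects a 4-d map");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int HO = (H + stride - 1) / stride;  // ceil(H / stride): same padding
  const int WO = (W + stride - 1) / stride;

  NumericVector y(static_cast<R_xlen_t>(HO) * WO * C * N);
  y.attr("dim") = IntegerVector::create(HO, WO, C, N);
  IntegerVector idx;
  const bool track = (mode == 0 || mode == 2);
  if (track) {
    idx = IntegerVector(y.size());
    idx.attr("dim") = IntegerVector::create(HO, WO, C, N);
  }
  const double* xp = REAL(x);
  double* yp = REAL(y);

  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* plane = xp + static_cast<R_xlen_t>(H) * W * (c + static_cast<R_xlen_t>(C) * n);
      for (int ow = 0; ow < WO; ++ow) {
        const int wi0 = ow * stride - pl;
        for (int oh = 0; oh < HO; ++oh) {
          const int hi0 = oh * stride - pt;
          double out = 0.0;
          int sel = -1;
          if (mode == 0) {
            double best = R_NegInf;
            for (int kh = 0; kh < kernel; ++kh) {
              const int hi = hi0 + kh;
              if (hi < 0 || hi >= H) continue;
              for (int kw = 0; kw < kernel; ++kw) {
                const int wi = wi0 + kw;
                if (wi < 0 || wi >= W) continue;
                const double v = plane[hi + static_cast<R_xlen_t>(H) * wi];
                if (v > best) { best = v; sel = hi + H * wi + 1; }
              }
            }
            out = best;
          } else if (mode == 1) {
            double s = 0.0; int cnt = 0;
            for (int kh = 0; kh < kernel; ++kh) {
              const int hi = hi0 + kh;
              if (hi < 0 || hi >= H) continue;
              for (int kw = 0; kw < kernel; ++kw) {
                const int wi = wi0 + kw;
                if (wi < 0 || wi >= W) continue;
                s += plane[hi + static_cast<R_xlen_t>(H) * wi];
                ++cnt;
              }
            }
            out = s / cnt;
          } else {
            // stochastic: needs non-negative activations (post-ReLU contract)
            double s = 0.0;
            for (int kh = 0; kh < kernel; ++kh) {
              const int hi = hi0 + kh;
              if (hi < 0 || hi >= H) continue;
              for (int kw = 0; kw < kernel; ++kw) {
                const int wi = wi0 + kw;
                if (wi < 0 || wi >= W) continue;
                const double v = plane[hi + static_cast<R_xlen_t>(H) * wi];
                if (v < 0) stop("NegativeActivation: stochastic pooling requires non-negative inputs");
                s += v;
              }
            }
            if (s <= 0.0) {
              out = 0.0;  // all-zero region convention
            } else if (mode == 3) {
              double e = 0.0;
              for (int kh = 0; kh < kernel; ++kh) {
                const int hi = hi0 + kh;
                if (hi < 0 || hi >= H) continue;
                for (int kw = 0; kw < kernel; ++kw) {
                  const int wi = wi0 + kw;
                  if (wi < 0 || wi >= W) continue;
                  const double v = plane[hi + static_cast<R_xlen_t>(H) * wi];
                  e += v * v;
                }
              }
              out = e / s;
            } else {
              // scan order: row by row, left to right within each row
              const double u = unif_rand() * s;
              double acc = 0.0;
              for (int kh = 0; kh < kernel && sel < 0; ++kh) {
                const int hi = hi0 + kh;
                if (hi < 0 || hi >= H) continue;
                for (int kw = 0; kw < kernel; ++kw) {
                  const int wi = wi0 + kw;
                  if (wi < 0 || wi >= W) continue;
                  acc += plane[hi + static_cast<R_xlen_t>(H) * wi];
                  if (acc >= u) { sel = hi + H * wi + 1; break; }
                }
              }
              if (sel < 0) {
                // numerical slack: fall back to the last in-bounds element
                for (int kh = kernel - 1; kh >= 0 && sel < 0; --kh) {
                  const int hi = hi0 + kh;
                  if (hi < 0 || hi >= H) continue;
                  for (int kw = kernel - 1; kw >= 0; --kw) {
                    const int wi = wi0 + kw;
                    if (wi < 0 || wi >= W) continue;
                    sel = hi + H * wi + 1;
                    break;
                  }
                }
              }
              out = plane[sel - 1];
            }
          }
          const R_xlen_t oi = oh + static_cast<R_xlen_t>(HO) * (ow + static_cast<R_xlen_t>(WO) * (c + static_cast<R_xlen_t>(C) * n));
          yp[oi] = out;
          if (track) idx[oi] = sel;
        }
      }
    }
  if (track) return List::create(_["y"] = y, _["idx"] = idx);
  return List::create(_["y"] = y);
}

// Backward pass. For max / stochastic-sample the gradient is routed to the
// recorded element; for average it is spread uniformly over the in-bounds
// elements of each region.
// [[Rcpp::export]]
NumericVector pool2d_backward_cpp(NumericVector dy, IntegerVector xdim,
                                  Nullable<IntegerVector> idx_, int kernel,
                                  int stride, int pt, int pl, int mode) {
  IntegerVector yd = dy.attr("dim");
  const int HO = yd[0], WO = yd[1], C = yd[2], N = yd[3];
  const int H = xdim[0], W = xdim[1];
  NumericVector dx(static_cast<R_xlen_t>(H) * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* dyp = REAL(dy);
  double* dxp = REAL(dx);

  if (mode == 0 || mode == 2) {
    IntegerVector idx(idx_);
    for (R_xlen_t i = 0; i < dy.size(); ++i) {
      const int sel = idx[i];
      if (sel < 1) continue;  // all-zero stochastic region: no gradient
      const R_xlen_t plane = i / (static_cast<R_xlen_t>(HO) * WO);
      dxp[plane * H * W + (sel - 1)] += dyp[i];
    }
  } else if (mode == 1) {
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        double* dplane = dxp + static_cast<R_xlen_t>(H) * W * (c + static_cast<R_xlen_t>(C) * n);
        for (int ow = 0; ow < WO; ++ow) {
          const int wi0 = ow * stride - pl;
          for (int oh = 0; oh < HO; ++oh) {
            const int hi0 = oh * stride - pt;
            int cnt = 0;
            for (int kh = 0; kh < kernel; ++kh) {
              const int hi = hi0 + kh;
              if (hi < 0 || hi >= H) continue;
              for (int kw = 0; kw < kernel; ++kw) {
                const int wi = wi0 + kw;
                if (wi >= 0 && wi < W) ++cnt;
              }
            }
            const double g = dyp[oh + static_cast<R_xlen_t>(HO) * (ow + static_cast<R_xlen_t>(WO) * (c + static_cast<R_xlen_t>(C) * n))] / cnt;
            for (int kh = 0; kh < kernel; ++kh) {
              const int hi = hi0 + kh;
              if (hi < 0 || hi >= H) continue;
              for (int kw = 0; kw < kernel; ++kw) {
                const int wi = wi0 + kw;
                if (wi < 0 || wi >= W) continue;
                dplane[hi + static_cast<R_xlen_t>(H) * wi] += g;
              }
            }
          }
        }
      }
  } else {
    stop("no backward pass for stochastic-expectation pooling");
  }
  return dx;
}
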