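// Low-level array kernels for the network and preprocessing code.
// All image-like arrays are column-major R arrays laid out (H, W, C, N);
// convolution weights are (kh, kw, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static NumericVector arr4(int a, int b, int c, int n) {
  NumericVector v((R_xlen_t)a * b * c * n);
  v.attr("dim") = IntegerVector::create(a, b, c, n);
  return v;
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H,W,C,N) array");
  return d;
}

// im2col for one sample. col is (Ho*Wo) x (kh*kw*Cin); the column ordering
// matches the column-major layout of a (kh,kw,Cin) weight block so that
// y = col * matrix(w, kh*kw*Cin, Cout).
static void im2col(const double* x, int H, int W, int Cin, int kh, int kw,
                   int stride, int dil, int pad, int replicate,
                   int Ho, int Wo, arma::mat& col) {
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + (size_t)H * W * ci;
    for (int kc = 0; kc < kw; ++kc) {
      for (int kr = 0; kr < kh; ++kr) {
        int j = kr + kh * (kc + kw * ci);
        double* out = col.colptr(j);
        for (int wo = 0; wo < Wo; ++wo) {
          int wsrc = wo * stride - pad + kc * dil;
          for (int ho = 0; ho < Ho; ++ho) {
            int hsrc = ho * stride - pad + kr * dil;
            int hh = hsrc, ww = wsrc;
            double v;
            if (replicate) {
              hh = clampi(hh, 0, H - 1);
              ww = clampi(ww, 0, W - 1);
              v = xc[hh + (size_t)H * ww];
            } else {
              v = (hh < 0 || hh >= H || ww < 0 || ww >= W)
                    ? 0.0 : xc[hh + (size_t)H * ww];
            }
            out[ho + (size_t)Ho * wo] = v;
          }
        }
      }
    }
  }
}

// adjoint of im2col: scatter-add col gradients back onto the input
static void col2im(const arma::mat& gcol, int H, int W, int Cin, int kh, int kw,
                   int stride, int dil, int pad, int replicate,
                   int Ho, int Wo, double* gx) {
  for (int ci = 0; ci < Cin; ++ci) {
    double* gxc = gx + (size_t)H * W * ci;
    for (int kc = 0; kc < kw; ++kc) {
      for (int kr = 0; kr < kh; ++kr) {
        int j = kr + kh * (kc + kw * ci);
        const double* gj = gcol.colptr(j);
        for (int wo = 0; wo < Wo; ++wo) {
          int wsrc = wo * stride - pad + kc * dil;
          for (int ho = 0; ho < Ho; ++ho) {
            int hsrc = ho * stride - pad + kr * dil;
            int hh = hsrc, ww = wsrc;
            if (replicate) {
              hh = clampi(hh, 0, H - 1);
              ww = clampi(ww, 0, W - 1);
            } else if (hh < 0 || hh >= H || ww < 0 || ww >= W) {
              continue;
            }
            gxc[hh + (size_t)H * ww] += gj[ho + (size_t)Ho * wo];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 Nullable<NumericVector> bias,
                                 int stride, int dil, int pad, int replicate) {
  IntegerVector dx = dims4(x);
  IntegerVector dw = w.attr("dim");
  int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  int kh = dw[0], kw = dw[1], Cout = dw[3];
  if (dw[2] != Cin) stop("conv2d: channel mismatch");
  int Ho = (H + 2 * pad - dil * (kh - 1) - 1) / stride + 1;
  int Wo = (W + 2 * pad - dil * (kw - 1) - 1) / stride + 1;
  NumericVector y = arr4(Ho, Wo, Cout, N);
  arma::mat Wm(w.begin(), (size_t)kh * kw * Cin, Cout, false, true);
  arma::mat col((size_t)Ho * Wo, (size_t)kh * kw * Cin);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * Cin * n;
    im2col(xn, H, W, Cin, kh, kw, stride, dil, pad, replicate, Ho, Wo, col);
    arma::mat yn(y.begin() + (size_t)Ho * Wo * Cout * n,
                 (size_t)Ho * Wo, Cout, false, true);
    yn = col * Wm;
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    size_t plane = (size_t)Ho * Wo;
    for (int n = 0; n < N; ++n)
      for (int co = 0; co < Cout; ++co) {
        double bv = b[co];
        double* p = y.begin() + plane * (co + (size_t)Cout * n);
        for (size_t i = 0; i < plane; ++i) p[i] += bv;
      }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector gy,
                         int stride, int dil, int pad, int replicate) {
  IntegerVector dx = dims4(x);
  IntegerVector dw = w.attr("dim");
  IntegerVector dy = dims4(gy);
  int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  int kh = dw[0], kw = dw[1], Cout = dw[3];
  int Ho = dy[0], Wo = dy[1];
  NumericVector gx = arr4(H, W, Cin, N);
  NumericVector gw = arr4(kh, kw, Cin, Cout);
  NumericVector gb(Cout);
  arma::mat Wm(w.begin(), (size_t)kh * kw * Cin, Cout, false, true);
  arma::mat Gw(gw.begin(), (size_t)kh * kw * Cin, Cout, false, true);
  arma::mat col((size_t)Ho * Wo, (size_t)kh * kw * Cin);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * Cin * n;
    im2col(xn, H, W, Cin, kh, kw, stride, dil, pad, replicate, Ho, Wo, col);
    arma::mat gyn(gy.begin() + (size_t)Ho * Wo * Cout * n,
                  (size_t)Ho * Wo, Cout, false, true);
    Gw += col.t() * gyn;
    arma::mat gcol = gyn * Wm.t();
    col2im(gcol, H, W, Cin, kh, kw, stride, dil, pad, replicate, Ho, Wo,
           gx.begin() + (size_t)H * W * Cin * n);
    for (int co = 0; co < Cout; ++co)
      gb[co] += arma::accu(gyn.col(co));
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// transposed 2x2 stride-2 convolution: non-overlapping 2x2 output blocks
// [[Rcpp::export]]
NumericVector cpp_convt2x2_forward(NumericVector x, NumericVector w,
                                   Nullable<NumericVector> bias) {
  IntegerVector dx = dims4(x);
  IntegerVector dw = w.attr("dim");
  int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  int Cout = dw[3];
  if (dw[0] != 2 || dw[1] != 2 || dw[2] != Cin) stop("convt2x2: bad weight shape");
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y = arr4(Ho, Wo, Cout, N);
  double b0;
  NumericVector b;
  bool has_b = bias.isNotNull();
  if (has_b) b = NumericVector(bias);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double* yp = y.begin() + (size_t)Ho * Wo * (co + (size_t)Cout * n);
      b0 = has_b ? b[co] : 0.0;
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) yp[i] = b0;
      for (int ci = 0; ci < Cin; ++ci) {
        const double* xp = x.begin() + (size_t)H * W * (ci + (size_t)Cin * n);
        const double* wp = w.begin() + 4 * ((size_t)ci + (size_t)Cin * co);
        // w index (a,b) = a + 2*b
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            double v = xp[i + (size_t)H * j];
            size_t o = (size_t)2 * i + (size_t)Ho * (2 * j);
            yp[o]          += v * wp[0];
            yp[o + 1]      += v * wp[1];
            yp[o + Ho]     += v * wp[2];
            yp[o + Ho + 1] += v * wp[3];
          }
      }
    }
  return y;
}

// [[Rcpp::export]]
List cpp_convt2x2_backward(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector dx = dims4(x);
  IntegerVector dw = w.attr("dim");
  int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  int Cout = dw[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx = arr4(H, W, Cin, N);
  NumericVector gw = arr4(2, 2, Cin, Cout);
  NumericVector gb(Cout);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* gp = gy.begin() + (size_t)Ho * Wo * (co + (size_t)Cout * n);
      double s = 0.0;
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) s += gp[i];
      gb[co] += s;
      for (int ci = 0; ci < Cin; ++ci) {
        const double* xp = x.begin() + (size_t)H * W * (ci + (size_t)Cin * n);
        double* gxp = gx.begin() + (size_t)H * W * (ci + (size_t)Cin * n);
        const double* wp = w.begin() + 4 * ((size_t)ci + (size_t)Cin * co);
        double* gwp = gw.begin() + 4 * ((size_t)ci + (size_t)Cin * co);
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            size_t o = (size_t)2 * i + (size_t)Ho * (2 * j);
            double g00 = gp[o], g10 = gp[o + 1];
            double g01 = gp[o + Ho], g11 = gp[o + Ho + 1];
            double v = xp[i + (size_t)H * j];
            gxp[i + (size_t)H * j] +=
              g00 * wp[0] + g10 * wp[1] + g01 * wp[2] + g11 * wp[3];
            gwp[0] += v * g00; gwp[1] += v * g10;
            gwp[2] += v * g01; gwp[3] += v * g11;
          }
      }
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// depthwise 3x3 convolution, stride 1, zero padding 1
// [[Rcpp::export]]
NumericVector cpp_dwconv_forward(NumericVector x, NumericVector w,
                                 Nullable<NumericVector> bias) {
  IntegerVector dx = dims4(x);
  IntegerVector dw = w.attr("dim"); // (3,3,C)
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  if (dw[0] != 3 || dw[1] != 3 || dw[2] != C) stop("dwconv: bad weight shape");
  NumericVector y = arr4(H, W, C, N);
  NumericVector b;
  bool has_b = bias.isNotNull();
  if (has_b) b = NumericVector(bias);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yp = y.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* wp = w.begin() + 9 * (size_t)c;
      double bv = has_b ? b[c] : 0.0;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          double acc = bv;
          for (int kc = 0; kc < 3; ++kc) {
            int jj = j + kc - 1;
            if (jj < 0 || jj >= W) continue;
            for (int kr = 0; kr < 3; ++kr) {
              int ii = i + kr - 1;
              if (ii < 0 || ii >= H) continue;
              acc += xp[ii + (size_t)H * jj] * wp[kr + 3 * kc];
            }
          }
          yp[i + (size_t)H * j] = acc;
        }
    }
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv_backward(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector dx = dims4(x);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  NumericVector gx = arr4(H, W, C, N);
  NumericVector gw(Dimension(3, 3, C));
  NumericVector gb(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* gxp = gx.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* gp = gy.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* wp = w.begin() + 9 * (size_t)c;
      double* gwp = gw.begin() + 9 * (size_t)c;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          double g = gp[i + (size_t)H * j];
          gb[c] += g;
          for (int kc = 0; kc < 3; ++kc) {
            int jj = j + kc - 1;
            if (jj < 0 || jj >= W) continue;
            for (int kr = 0; kr < 3; ++kr) {
              int ii = i + kr - 1;
              if (ii < 0 || ii >= H) continue;
              gxp[ii + (size_t)H * jj] += g * wp[kr + 3 * kc];
              gwp[kr + 3 * kc] += g * xp[ii + (size_t)H * jj];
            }
          }
        }
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// deformable 3x3 convolution, stride 1, dilation d, zero padding d.
// offsets: (H, W, 18, N) ordered (dy,dx) per tap, tap k = kr + 3*kc.
// Bilinear sampling; positions outside the frame contribute zero, matching
// zero-padded convolution when all offsets vanish.
// [[Rcpp::export]]
NumericVector cpp_dconv_forward(NumericVector x, NumericVector offs,
                                NumericVector w, Nullable<NumericVector> bias,
                                int dil) {
  IntegerVector dx = dims4(x);
  int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  IntegerVector dw = w.attr("dim");
  int Cout = dw[3];
  if (dw[0] != 3 || dw[1] != 3 || dw[2] != Cin) stop("dconv: bad weight shape");
  NumericVector y = arr4(H, W, Cout, N);
  NumericVector b;
  bool has_b = bias.isNotNull();
  if (has_b) b = NumericVector(bias);
  std::vector<double> samp((size_t)9 * Cin);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * Cin * n;
    const double* on = offs.begin() + (size_t)H * W * 18 * n;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        // gather bilinear samples for all taps/channels
        for (int k = 0; k < 9; ++k) {
          int kr = k % 3, kc = k / 3;
          double dy = on[i + (size_t)H * (j + (size_t)W * (2 * k))];
          double dxo = on[i + (size_t)H * (j + (size_t)W * (2 * k + 1))];
          double py = i + (kr - 1) * dil + dy;
          double px = j + (kc - 1) * dil + dxo;
          int y0 = (int)std::floor(py), x0 = (int)std::floor(px);
          double ay = py - y0, ax = px - x0;
          for (int ci = 0; ci < Cin; ++ci) {
            const double* xc = xn + (size_t)H * W * ci;
            double v = 0.0;
            for (int cy = 0; cy <= 1; ++cy)
              for (int cx = 0; cx <= 1; ++cx) {
                int yy = y0 + cy, xx = x0 + cx;
                if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
                double wgt = (cy ? ay : 1 - ay) * (cx ? ax : 1 - ax);
                v += wgt * xc[yy + (size_t)H * xx];
              }
            samp[k + 9 * (size_t)ci] = v;
          }
        }
        for (int co = 0; co < Cout; ++co) {
          const double* wp = w.begin() + (size_t)9 * Cin * co;
          double acc = has_b ? b[co] : 0.0;
          for (size_t t = 0; t < (size_t)9 * Cin; ++t) acc += samp[t] * wp[t];
          y[i + (size_t)H * (j + (size_t)W * (co + (size_t)Cout * n))] = acc;
        }
      }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_dconv_backward(NumericVector x, NumericVector offs, NumericVector w,
                        NumericVector gy, int dil) {
  IntegerVector dx = dims4(x);
  int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  IntegerVector dw = w.attr("dim");
  int Cout = dw[3];
  NumericVector gx = arr4(H, W, Cin, N);
  NumericVector go = arr4(H, W, 18, N);
  NumericVector gw = arr4(3, 3, Cin, Cout);
  NumericVector gb(Cout);
  std::vector<double> samp((size_t)9 * Cin), gsamp((size_t)9 * Cin);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * Cin * n;
    const double* on = offs.begin() + (size_t)H * W * 18 * n;
    double* gxn = gx.begin() + (size_t)H * W * Cin * n;
    double* gon = go.begin() + (size_t)H * W * 18 * n;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        for (int k = 0; k < 9; ++k) {
          int kr = k % 3, kc = k / 3;
          double dy = on[i + (size_t)H * (j + (size_t)W * (2 * k))];
          double dxo = on[i + (size_t)H * (j + (size_t)W * (2 * k + 1))];
          double py = i + (kr - 1) * dil + dy;
          double px = j + (kc - 1) * dil + dxo;
          int y0 = (int)std::floor(py), x0 = (int)std::floor(px);
          double ay = py - y0, ax = px - x0;
          for (int ci = 0; ci < Cin; ++ci) {
            const double* xc = xn + (size_t)H * W * ci;
            double v = 0.0;
            for (int cy = 0; cy <= 1; ++cy)
              for (int cx = 0; cx <= 1; ++cx) {
                int yy = y0 + cy, xx = x0 + cx;
                if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
                double wgt = (cy ? ay : 1 - ay) * (cx ? ax : 1 - ax);
                v += wgt * xc[yy + (size_t)H * xx];
              }
            samp[k + 9 * (size_t)ci] = v;
          }
        }
        // gradient wrt samples and weights/bias
        std::fill(gsamp.begin(), gsamp.end(), 0.0);
        for (int co = 0; co < Cout; ++co) {
          double g = gy[i + (size_t)H * (j + (size_t)W * (co + (size_t)Cout * n))];
          gb[co] += g;
          const double* wp = w.begin() + (size_t)9 * Cin * co;
          double* gwp = gw.begin() + (size_t)9 * Cin * co;
          for (size_t t = 0; t < (size_t)9 * Cin; ++t) {
            gsamp[t] += g * wp[t];
            gwp[t] += g * samp[t];
          }
        }
        // push sample gradients to input and offsets
        for (int k = 0; k < 9; ++k) {
          int kr = k % 3, kc = k / 3;
          double dy = on[i + (size_t)H * (j + (size_t)W * (2 * k))];
          double dxo = on[i + (size_t)H * (j + (size_t)W * (2 * k + 1))];
          double py = i + (kr - 1) * dil + dy;
          double px = j + (kc - 1) * dil + dxo;
          int y0 = (int)std::floor(py), x0 = (int)std::floor(px);
          double ay = py - y0, ax = px - x0;
          double gdy = 0.0, gdx = 0.0;
          for (int ci = 0; ci < Cin; ++ci) {
            double gs = gsamp[k + 9 * (size_t)ci];
            if (gs == 0.0) continue;
            const double* xc = xn + (size_t)H * W * ci;
            double* gxc = gxn + (size_t)H * W * ci;
            double v00 = 0, v01 = 0, v10 = 0, v11 = 0;
            for (int cy = 0; cy <= 1; ++cy)
              for (int cx = 0; cx <= 1; ++cx) {
                int yy = y0 + cy, xx = x0 + cx;
                if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
                double wgt = (cy ? ay : 1 - ay) * (cx ? ax : 1 - ax);
                gxc[yy + (size_t)H * xx] += gs * wgt;
                double val = xc[yy + (size_t)H * xx];
                if (cy == 0 && cx == 0) v00 = val;
                else if (cy == 1 && cx == 0) v10 = val;
                else if (cy == 0 && cx == 1) v01 = val;
                else v11 = val;
              }
            gdy += gs * ((v10 - v00) * (1 - ax) + (v11 - v01) * ax);
            gdx += gs * ((v01 - v00) * (1 - ay) + (v11 - v10) * ay);
          }
          gon[i + (size_t)H * (j + (size_t)W * (2 * k))] += gdy;
          gon[i + (size_t)H * (j + (size_t)W * (2 * k + 1))] += gdx;
        }
      }
  }
  return List::create(_["gx"] = gx, _["go"] = go, _["gw"] = gw, _["gb"] = gb);
}

// bilinear resize with half-pixel centers, on (H,W,C,N)
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, int oh, int ow) {
  IntegerVector dx = dims4(x);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  NumericVector y = arr4(oh, ow, C, N);
  double sy = (double)H / oh, sx = (double)W / ow;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yp = y.begin() + (size_t)oh * ow * (c + (size_t)C * n);
      for (int j = 0; j < ow; ++j) {
        double px = (j + 0.5) * sx - 0.5;
        if (px < 0) px = 0; if (px > W - 1) px = W - 1;
        int x0 = (int)std::floor(px); int x1 = std::min(x0 + 1, W - 1);
        double ax = px - x0;
        for (int i = 0; i < oh; ++i) {
          double py = (i + 0.5) * sy - 0.5;
          if (py < 0) py = 0; if (py > H - 1) py = H - 1;
          int y0 = (int)std::floor(py); int y1 = std::min(y0 + 1, H - 1);
          double ay = py - y0;
          yp[i + (size_t)oh * j] =
            (1 - ay) * ((1 - ax) * xp[y0 + (size_t)H * x0] + ax * xp[y0 + (size_t)H * x1]) +
            ay * ((1 - ax) * xp[y1 + (size_t)H * x0] + ax * xp[y1 + (size_t)H * x1]);
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_backward(NumericVector gy, int H, int W) {
  IntegerVector dy = dims4(gy);
  int oh = dy[0], ow = dy[1], C = dy[2], N = dy[3];
  NumericVector gx = arr4(H, W, C, N);
  double sy = (double)H / oh, sx = (double)W / ow;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gp = gy.begin() + (size_t)oh * ow * (c + (size_t)C * n);
      double* gxp = gx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int j = 0; j < ow; ++j) {
        double px = (j + 0.5) * sx - 0.5;
        if (px < 0) px = 0; if (px > W - 1) px = W - 1;
        int x0 = (int)std::floor(px); int x1 = std::min(x0 + 1, W - 1);
        double ax = px - x0;
        for (int i = 0; i < oh; ++i) {
          double py = (i + 0.5) * sy - 0.5;
          if (py < 0) py = 0; if (py > H - 1) py = H - 1;
          int y0 = (int)std::floor(py); int y1 = std::min(y0 + 1, H - 1);
          double ay = py - y0;
          double g = gp[i + (size_t)oh * j];
          gxp[y0 + (size_t)H * x0] += g * (1 - ay) * (1 - ax);
          gxp[y0 + (size_t)H * x1] += g * (1 - ay) * ax;
          gxp[y1 + (size_t)H * x0] += g * ay * (1 - ax);
          gxp[y1 + (size_t)H * x1] += g * ay * ax;
        }
      }
    }
  return gx;
}

static inline double cubic_w(double t) {
  // Keys kernel, a = -0.5 (standard bicubic)
  const double a = -0.5;
  t = std::fabs(t);
  if (t <= 1.0) return (a + 2) * t * t * t - (a + 3) * t * t + 1;
  if (t < 2.0) return a * t * t * t - 5 * a * t * t + 8 * a * t - 4 * a;
  return 0.0;
}

// bicubic resize on (H,W,C), half-pixel centers, edge clamped
// [[Rcpp::export]]
NumericVector cpp_resize_bicubic(NumericVector x, int oh, int ow) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected (H,W,C)");
  int H = d[0], W = d[1], C = d[2];
  NumericVector y(Dimension(oh, ow, C));
  double sy = (double)H / oh, sx = (double)W / ow;
  for (int c = 0; c < C; ++c) {
    const double* xp = x.begin() + (size_t)H * W * c;
    double* yp = y.begin() + (size_t)oh * ow * c;
    for (int j = 0; j < ow; ++j) {
      double px = (j + 0.5) * sx - 0.5;
      int x0 = (int)std::floor(px);
      double wx[4];
      for (int t = 0; t < 4; ++t) wx[t] = cubic_w(px - (x0 - 1 + t));
      for (int i = 0; i < oh; ++i) {
        double py = (i + 0.5) * sy - 0.5;
        int y0 = (int)std::floor(py);
        double wy[4];
        for (int t = 0; t < 4; ++t) wy[t] = cubic_w(py - (y0 - 1 + t));
        double acc = 0.0;
        for (int b = 0; b < 4; ++b) {
          int xx = clampi(x0 - 1 + b, 0, W - 1);
          double rowacc = 0.0;
          for (int a2 = 0; a2 < 4; ++a2) {
            int yy = clampi(y0 - 1 + a2, 0, H - 1);
            rowacc += wy[a2] * xp[yy + (size_t)H * xx];
          }
          acc += wx[b] * rowacc;
        }
        yp[i + (size_t)oh * j] = acc;
      }
    }
  }
  return y;
}

// generic warp: out(i,j) sampled at (map_r(i,j), map_c(i,j)) from (H,W,C) img
// mode 0 = nearest, 1 = bilinear; border replicate-clamped
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector img, NumericMatrix map_r,
                       NumericMatrix map_c, int mode) {
  IntegerVector d = img.attr("dim");
  if (d.size() != 3) stop("expected (H,W,C)");
  int H = d[0], W = d[1], C = d[2];
  int oh = map_r.nrow(), ow = map_r.ncol();
  NumericVector y(Dimension(oh, ow, C));
  for (int c = 0; c < C; ++c) {
    const double* xp = img.begin() + (size_t)H * W * c;
    double* yp = y.begin() + (size_t)oh * ow * c;
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        double py = map_r(i, j), px = map_c(i, j);
        if (mode == 0) {
          int yy = clampi((int)std::lround(py), 0, H - 1);
          int xx = clampi((int)std::lround(px), 0, W - 1);
          yp[i + (size_t)oh * j] = xp[yy + (size_t)H * xx];
        } else {
          if (py < 0) py = 0; if (py > H - 1) py = H - 1;
          if (px < 0) px = 0; if (px > W - 1) px = W - 1;
          int y0 = (int)std::floor(py); int y1 = std::min(y0 + 1, H - 1);
          int x0 = (int)std::floor(px); int x1 = std::min(x0 + 1, W - 1);
          double ay = py - y0, ax = px - x0;
          yp[i + (size_t)oh * j] =
            (1 - ay) * ((1 - ax) * xp[y0 + (size_t)H * x0] + ax * xp[y0 + (size_t)H * x1]) +
            ay * ((1 - ax) * xp[y1 + (size_t)H * x0] + ax * xp[y1 + (size_t)H * x1]);
        }
      }
  }
  return y;
}

// 8-connectivity labeling of a binary matrix (flood fill)
// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + H * j);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % H, pj = p / H;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
            if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + H * qj);
            }
          }
      }
    }
  return lab;
}

// for each row of P (n x 2), Euclidean distance to the nearest row of G
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix P, NumericMatrix G) {
  int n = P.nrow(), m = G.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    double py = P(i, 0), px = P(i, 1);
    for (int j = 0; j < m; ++j) {
      double dy = py - G(j, 0), dx = px - G(j, 1);
      double d2 = dy * dy + dx * dx;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// ---- fused network primitives (hot path) ----------------------------------

// per-channel mean/var over (H, W, N)
// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t plane = (size_t)H * W;
  NumericVector mu(C), va(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    double m = s / (plane * N);
    mu[c] = m;
    double v = s2 / (plane * N) - m * m;
    va[c] = v > 0 ? v : 0;
  }
  return List::create(_["mean"] = mu, _["var"] = va);
}

// y = gamma * (x - mu) * istd + beta, per channel
// [[Rcpp::export]]
NumericVector cpp_bn_apply(NumericVector x, NumericVector gamma,
                           NumericVector beta, NumericVector mu,
                           NumericVector istd) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t plane = (size_t)H * W;
  NumericVector y = arr4(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + plane * (c + (size_t)C * n);
      double* q = y.begin() + plane * (c + (size_t)C * n);
      double a = gamma[c] * istd[c];
      double b = beta[c] - a * mu[c];
      for (size_t i = 0; i < plane; ++i) q[i] = a * p[i] + b;
    }
  return y;
}

// gradients of batch norm; training mode couples samples via batch stats
// [[Rcpp::export]]
List cpp_bn_backward(NumericVector x, NumericVector gamma, NumericVector mu,
                     NumericVector istd, NumericVector gy, bool training) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t plane = (size_t)H * W;
  double m = (double)plane * N;
  NumericVector gx = arr4(H, W, C, N);
  NumericVector ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0, sgx = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + plane * (c + (size_t)C * n);
      const double* g = gy.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) {
        double xh = (p[i] - mu[c]) * istd[c];
        sg += g[i];
        sgx += g[i] * xh;
      }
    }
    ggamma[c] = sgx;
    gbeta[c] = sg;
    double a = gamma[c] * istd[c];
    double gmean = sg / m, gxh = sgx / m;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + plane * (c + (size_t)C * n);
      const double* g = gy.begin() + plane * (c + (size_t)C * n);
      double* q = gx.begin() + plane * (c + (size_t)C * n);
      if (training) {
        for (size_t i = 0; i < plane; ++i) {
          double xh = (p[i] - mu[c]) * istd[c];
          q[i] = a * (g[i] - gmean - xh * gxh);
        }
      } else {
        for (size_t i = 0; i < plane; ++i) q[i] = a * g[i];
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta);
}

// exact GELU x * Phi(x)
// [[Rcpp::export]]
NumericVector cpp_gelu_forward(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double inv_sqrt2 = 0.7071067811865475;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = x[i];
    y[i] = v * 0.5 * (1.0 + std::erf(v * inv_sqrt2));
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_gelu_backward(NumericVector x, NumericVector gy) {
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  const double inv_sqrt2 = 0.7071067811865475;
  const double inv_sqrt2pi = 0.3989422804014327;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = x[i];
    double phi = 0.5 * (1.0 + std::erf(v * inv_sqrt2));
    double dens = inv_sqrt2pi * std::exp(-0.5 * v * v);
    gx[i] = gy[i] * (phi + v * dens);
  }
  return gx;
}

// x (H,W,C,N) times a (H,W,1,N), broadcast across channels
// [[Rcpp::export]]
NumericVector cpp_bcast_mul(NumericVector x, NumericVector a) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t plane = (size_t)H * W;
  NumericVector y = arr4(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    const double* ap = a.begin() + plane * n;
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + plane * (c + (size_t)C * n);
      double* q = y.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) q[i] = p[i] * ap[i];
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_bcast_mul_backward(NumericVector x, NumericVector a,
                            NumericVector gy) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t plane = (size_t)H * W;
  NumericVector gx = arr4(H, W, C, N);
  NumericVector ga = arr4(H, W, 1, N);
  for (int n = 0; n < N; ++n) {
    const double* ap = a.begin() + plane * n;
    double* gap = ga.begin() + plane * n;
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + plane * (c + (size_t)C * n);
      const double* g = gy.begin() + plane * (c + (size_t)C * n);
      double* q = gx.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) {
        q[i] = g[i] * ap[i];
        gap[i] += g[i] * p[i];
      }
    }
  }
  return List::create(_["gx"] = gx, _["ga"] = ga);
}

// channel average and max (with argmax) in one pass
// [[Rcpp::export]]
List cpp_chan_summary(NumericVector x) {
  IntegerVector d = dims4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t plane = (size_t)H * W;
  NumericVector avg = arr4(H, W, 1, N);
  NumericVector mx = arr4(H, W, 1, N);
  IntegerVector idx((R_xlen_t)plane * N);
  for (int n = 0; n < N; ++n) {
    double* ap = avg.begin() + plane * n;
    double* mp = mx.begin() + plane * n;
    int* ip = idx.begin() + plane * n;
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + plane * (c + (size_t)C * n);
      if (c == 0) {
        for (size_t i = 0; i < plane; ++i) {
          ap[i] = p[i]; mp[i] = p[i]; ip[i] = 0;
        }
      } else {
        for (size_t i = 0; i < plane; ++i) {
          ap[i] += p[i];
          if (p[i] > mp[i]) { mp[i] = p[i]; ip[i] = c; }
        }
      }
    }
    for (size_t i = 0; i < plane; ++i) ap[i] /= C;
  }
  return List::create(_["avg"] = avg, _["max"] = mx, _["argmax"] = idx);
}

// scatter gradients of (avg, max) summaries back across channels
// [[Rcpp::export]]
NumericVector cpp_chan_summary_backward(NumericVector gavg,
                                        Nullable<NumericVector> gmax,
                                        Nullable<IntegerVector> argmax,
                                        int C) {
  IntegerVector d = dims4(gavg);
  int H = d[0], W = d[1], N = d[3];
  size_t plane = (size_t)H * W;
  NumericVector gx = arr4(H, W, C, N);
  bool has_max = gmax.isNotNull();
  NumericVector gm;
  IntegerVector im;
  if (has_max) { gm = NumericVector(gmax); im = IntegerVector(argmax); }
  for (int n = 0; n < N; ++n) {
    const double* ga = gavg.begin() + plane * n;
    for (int c = 0; c < C; ++c) {
      double* q = gx.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) q[i] = ga[i] / C;
    }
    if (has_max) {
      const double* g = gm.begin() + plane * n;
      const int* ii = im.begin() + plane * n;
      for (size_t i = 0; i < plane; ++i)
        gx[i + plane * (ii[i] + (size_t)C * n)] += g[i];
    }
  }
  return gx;
}

// channel concatenation of a list of (H,W,Ci,N) arrays
// [[Rcpp::export]]
NumericVector cpp_concat_ch(List xs) {
  int L = xs.size();
  std::vector<NumericVector> v(L);
  std::vector<int> cs(L);
  int H = 0, W = 0, N = 0, Ctot = 0;
  for (int l = 0; l < L; ++l) {
    v[l] = as<NumericVector>(xs[l]);
    IntegerVector d = dims4(v[l]);
    if (l == 0) { H = d[0]; W = d[1]; N = d[3]; }
    else if (d[0] != H || d[1] != W || d[3] != N)
      stop("concat: spatial/batch mismatch");
    cs[l] = d[2];
    Ctot += d[2];
  }
  size_t plane = (size_t)H * W;
  NumericVector y = arr4(H, W, Ctot, N);
  for (int n = 0; n < N; ++n) {
    int at = 0;
    for (int l = 0; l < L; ++l) {
      const double* src = v[l].begin() + plane * (size_t)cs[l] * n;
      double* dst = y.begin() + plane * (at + (size_t)Ctot * n);
      std::copy(src, src + plane * cs[l], dst);
      at += cs[l];
    }
  }
  return y;
}

// split channel-concatenated gradient back into parts
// [[Rcpp::export]]
List cpp_split_ch(NumericVector g, IntegerVector cs) {
  IntegerVector d = dims4(g);
  int H = d[0], W = d[1], Ctot = d[2], N = d[3];
  size_t plane = (size_t)H * W;
  int L = cs.size();
  List out(L);
  std::vector<NumericVector> v(L);
  for (int l = 0; l < L; ++l) v[l] = arr4(H, W, cs[l], N);
  for (int n = 0; n < N; ++n) {
    int at = 0;
    for (int l = 0; l < L; ++l) {
      const double* src = g.begin() + plane * (at + (size_t)Ctot * n);
      double* dst = v[l].begin() + plane * (size_t)cs[l] * n;
      std::copy(src, src + plane * cs[l], dst);
      at += cs[l];
    }
  }
  for (int l = 0; l < L; ++l) out[l] = v[l];
  return out;
}
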