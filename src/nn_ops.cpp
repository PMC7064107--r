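#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Minimal CNN primitives for the artifact-prediction U-Net.
// Feature maps are R arrays with dims (H, W, C, B), column-major, so the
// flat index of (h, w, c, b) is h + H*(w + W*(c + C*b)).
// Convolution weights have dims (kh, kw, Cin, Cout); with K = kh*kw*Cin the
// flat layout is exactly a K x Cout matrix, which im2col GEMM uses directly.

static inline IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, B)");
  return d;
}

// im2col for one image into rows [row0, row0 + HW) of a stacked matrix
// (pixel-major rows, one column per kernel offset). Zero padding: pt rows
// on top (x index), pl cols on left.
static void im2col_into(const double* x, int H, int W, int Ci,
                        int kh, int kw, int pt, int pl,
                        arma::mat& cols, size_t row0) {
  const int HW = H * W;
  for (int ci = 0; ci < Ci; ++ci) {
    const double* xc = x + (size_t)ci * HW;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * ci);
        double* col = cols.colptr(r) + row0;
        for (int w = 0; w < W; ++w) {
          const int sw = w + dw - pl;
          double* cp = col + (size_t)w * H;
          if (sw < 0 || sw >= W) {
            std::fill(cp, cp + H, 0.0);
            continue;
          }
          const double* src = xc + (size_t)sw * H;
          for (int h = 0; h < H; ++h) {
            const int sh = h + dh - pt;
            cp[h] = (sh < 0 || sh >= H) ? 0.0 : src[sh];
          }
        }
      }
    }
  }
}

// scatter-add adjoint of im2col for rows [row0, row0 + HW)
static void col2im_from(const arma::mat& cols, size_t row0,
                        int H, int W, int Ci,
                        int kh, int kw, int pt, int pl, double* gx) {
  for (int ci = 0; ci < Ci; ++ci) {
    double* gc = gx + (size_t)ci * H * W;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * ci);
        const double* col = cols.colptr(r) + row0;
        for (int w = 0; w < W; ++w) {
          const int sw = w + dw - pl;
          if (sw < 0 || sw >= W) continue;
          const double* cp = col + (size_t)w * H;
          double* dst = gc + (size_t)sw * H;
          for (int h = 0; h < H; ++h) {
            const int sh = h + dh - pt;
            if (sh >= 0 && sh < H) dst[sh] += cp[h];
          }
        }
      }
    }
  }
}

// Zero-padded "same"-size convolution. pt/pl default to the symmetric (odd
// kernel) or left-heavy (even kernel) padding so output size equals input.
// [[Rcpp::export]]
NumericVector cpp_conv_forward(const NumericVector& x, const NumericVector& w,
                               const NumericVector& b, int pt, int pl) {
  IntegerVector dx = dims4(x), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Ci = dx[2], B = dx[3];
  const int kh = dw[0], kw = dw[1], Co = dw[3];
  if (dw[2] != Ci) stop("channel mismatch between input and weights");
  const int K = kh * kw * Ci, HW = H * W;
  arma::mat wk(const_cast<double*>(w.begin()), K, Co, false, true);
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)HW * Co * B));
  y.attr("dim") = IntegerVector::create(H, W, Co, B);
  // one batched im2col + GEMM: rows of `cols` hold all images stacked
  arma::mat cols((size_t)HW * B, K);
  for (int n = 0; n < B; ++n)
    im2col_into(x.begin() + (size_t)n * HW * Ci, H, W, Ci, kh, kw, pt, pl,
                cols, (size_t)n * HW);
  arma::mat out = cols * wk;
  for (int n = 0; n < B; ++n) {
    double* yp = y.begin() + (size_t)n * HW * Co;
    for (int co = 0; co < Co; ++co) {
      const double* src = out.colptr(co) + (size_t)n * HW;
      double* dst = yp + (size_t)co * HW;
      for (int i = 0; i < HW; ++i) dst[i] = src[i] + b[co];
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_backward(const NumericVector& x, const NumericVector& w,
                       const NumericVector& gy, int pt, int pl) {
  IntegerVector dx = dims4(x), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Ci = dx[2], B = dx[3];
  const int kh = dw[0], kw = dw[1], Co = dw[3];
  const int K = kh * kw * Ci, HW = H * W;
  arma::mat wk(const_cast<double*>(w.begin()), K, Co, false, true);
  NumericVector gxv(Rf_allocVector(REALSXP, (R_xlen_t)HW * Ci * B));
  std::fill(gxv.begin(), gxv.end(), 0.0);
  gxv.attr("dim") = IntegerVector::create(H, W, Ci, B);
  NumericVector gwv(Rf_allocVector(REALSXP, (R_xlen_t)K * Co));
  std::fill(gwv.begin(), gwv.end(), 0.0);
  gwv.attr("dim") = dw;
  NumericVector gbv(Co);
  arma::mat gw(gwv.begin(), K, Co, false, true);
  arma::mat cols((size_t)HW * B, K);
  arma::mat g((size_t)HW * B, Co);
  for (int n = 0; n < B; ++n) {
    im2col_into(x.begin() + (size_t)n * HW * Ci, H, W, Ci, kh, kw, pt, pl,
                cols, (size_t)n * HW);
    for (int co = 0; co < Co; ++co)
      std::copy(gy.begin() + (size_t)HW * (co + (size_t)Co * n),
                gy.begin() + (size_t)HW * (co + 1 + (size_t)Co * n),
                g.colptr(co) + (size_t)n * HW);
  }
  gw = cols.t() * g;
  arma::mat gcols = g * wk.t();
  for (int n = 0; n < B; ++n)
    col2im_from(gcols, (size_t)n * HW, H, W, Ci, kh, kw, pt, pl,
                gxv.begin() + (size_t)n * HW * Ci);
  for (int co = 0; co < Co; ++co) gbv[co] = arma::accu(g.col(co));
  return List::create(_["gx"] = gxv, _["gw"] = gwv, _["gb"] = gbv);
}

// 2x2 max pooling, stride 2; returns pooled map and argmax codes (0..3).
// [[Rcpp::export]]
List cpp_maxpool_forward(const NumericVector& x) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  if (H % 2 || W % 2) stop("spatial size must be even for 2x2 pooling");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * C * B));
  IntegerVector idx(Rf_allocVector(INTSXP, (R_xlen_t)Ho * Wo * C * B));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  const size_t planes = (size_t)C * B;
  for (size_t cb = 0; cb < planes; ++cb) {
    const double* xq = xp + cb * H * W;
    double* yq = yp + cb * Ho * Wo;
    int* iq = ip + cb * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int h = 2 * ho, w = 2 * wo;
        double v00 = xq[h + H * w],     v10 = xq[h + 1 + H * w];
        double v01 = xq[h + H * (w+1)], v11 = xq[h + 1 + H * (w+1)];
        int best = 0; double bv = v00;
        if (v10 > bv) { bv = v10; best = 1; }
        if (v01 > bv) { bv = v01; best = 2; }
        if (v11 > bv) { bv = v11; best = 3; }
        yq[ho + Ho * wo] = bv;
        iq[ho + Ho * wo] = best;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(const NumericVector& gy,
                                   const IntegerVector& idx) {
  IntegerVector d = gy.attr("dim");
  const int Ho = d[0], Wo = d[1], C = d[2], B = d[3];
  const int H = 2 * Ho, W = 2 * Wo;
  NumericVector gx(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * B));
  std::fill(gx.begin(), gx.end(), 0.0);
  gx.attr("dim") = IntegerVector::create(H, W, C, B);
  const double* gp = gy.begin();
  const int* ip = idx.begin();
  double* xp = gx.begin();
  const size_t planes = (size_t)C * B;
  for (size_t cb = 0; cb < planes; ++cb) {
    const double* gq = gp + cb * Ho * Wo;
    const int* iq = ip + cb * Ho * Wo;
    double* xq = xp + cb * H * W;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const int code = iq[ho + Ho * wo];
        const int h = 2 * ho + (code & 1), w = 2 * wo + (code >> 1);
        xq[h + H * w] += gq[ho + Ho * wo];
      }
  }
  return gx;
}

// Bilinear x2 upsampling (half-pixel-centre convention, clamped borders).
// [[Rcpp::export]]
NumericVector cpp_bilinear_up_forward(const NumericVector& x) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * C * B));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  const double* xp = x.begin();
  double* yp = y.begin();
  const size_t planes = (size_t)C * B;
  std::vector<int> i0(Ho), i1(Ho);
  std::vector<double> wf(Ho);
  for (int o = 0; o < Ho; ++o) {
    double src = 0.5 * o - 0.25;
    int lo = (int)std::floor(src);
    double w = src - lo;
    int hi = lo + 1;
    if (lo < 0) lo = 0;
    if (hi > H - 1) hi = H - 1;
    i0[o] = lo; i1[o] = hi; wf[o] = w;
  }
  for (size_t cb = 0; cb < planes; ++cb) {
    const double* xq = xp + cb * H * W;
    double* yq = yp + cb * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      const int j0 = i0[wo], j1 = i1[wo];
      const double wy = wf[wo];
      const double* c0 = xq + (size_t)j0 * H;
      const double* c1 = xq + (size_t)j1 * H;
      double* out = yq + (size_t)wo * Ho;
      for (int ho = 0; ho < Ho; ++ho) {
        const double wx = wf[ho];
        const int a = i0[ho], b2 = i1[ho];
        out[ho] = (1 - wy) * ((1 - wx) * c0[a] + wx * c0[b2])
                + wy * ((1 - wx) * c1[a] + wx * c1[b2]);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_up_backward(const NumericVector& gy) {
  IntegerVector d = gy.attr("dim");
  const int Ho = d[0], Wo = d[1], C = d[2], B = d[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector gx(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * B));
  std::fill(gx.begin(), gx.end(), 0.0);
  gx.attr("dim") = IntegerVector::create(H, W, C, B);
  const double* gp = gy.begin();
  double* xp = gx.begin();
  const size_t planes = (size_t)C * B;
  std::vector<int> i0(Ho), i1(Ho);
  std::vector<double> wf(Ho);
  for (int o = 0; o < Ho; ++o) {
    double src = 0.5 * o - 0.25;
    int lo = (int)std::floor(src);
    double w = src - lo;
    int hi = lo + 1;
    if (lo < 0) lo = 0;
    if (hi > H - 1) hi = H - 1;
    i0[o] = lo; i1[o] = hi; wf[o] = w;
  }
  for (size_t cb = 0; cb < planes; ++cb) {
    const double* gq = gp + cb * Ho * Wo;
    double* xq = xp + cb * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      const int j0 = i0[wo], j1 = i1[wo];
      const double wy = wf[wo];
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = gq[ho + (size_t)wo * Ho];
        const double wx = wf[ho];
        const int a = i0[ho], b2 = i1[ho];
        xq[a + (size_t)j0 * H]  += (1 - wy) * (1 - wx) * g;
        xq[b2 + (size_t)j0 * H] += (1 - wy) * wx * g;
        xq[a + (size_t)j1 * H]  += wy * (1 - wx) * g;
        xq[b2 + (size_t)j1 * H] += wy * wx * g;
      }
    }
  }
  return gx;
}

// 2x2 stride-2 transposed convolution (the checkerboard-prone alternative
// decoder). w dims (2, 2, Cin, Cout).
// [[Rcpp::export]]
NumericVector cpp_deconv2_forward(const NumericVector& x,
                                  const NumericVector& w,
                                  const NumericVector& b) {
  IntegerVector dx = dims4(x), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Ci = dx[2], B = dx[3];
  const int Co = dw[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * Co * B));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, B);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* yp = y.begin();
  for (int n = 0; n < B; ++n) {
    for (int co = 0; co < Co; ++co) {
      double* yq = yp + (size_t)Ho * Wo * (co + (size_t)Co * n);
      std::fill(yq, yq + (size_t)Ho * Wo, b[co]);
      for (int ci = 0; ci < Ci; ++ci) {
        const double* xq = xp + (size_t)H * W * (ci + (size_t)Ci * n);
        const double w00 = wp[0 + 2 * (0 + 2 * (ci + Ci * co))];
        const double w10 = wp[1 + 2 * (0 + 2 * (ci + Ci * co))];
        const double w01 = wp[0 + 2 * (1 + 2 * (ci + Ci * co))];
        const double w11 = wp[1 + 2 * (1 + 2 * (ci + Ci * co))];
        for (int wj = 0; wj < W; ++wj)
          for (int hi = 0; hi < H; ++hi) {
            const double v = xq[hi + (size_t)wj * H];
            double* base = yq + 2 * hi + (size_t)(2 * wj) * Ho;
            base[0] += w00 * v;
            base[1] += w10 * v;
            base[Ho] += w01 * v;
            base[Ho + 1] += w11 * v;
          }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_deconv2_backward(const NumericVector& x, const NumericVector& w,
                          const NumericVector& gy) {
  IntegerVector dx = dims4(x), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Ci = dx[2], B = dx[3];
  const int Co = dw[3];
  const int Ho = 2 * H;
  NumericVector gxv(Rf_allocVector(REALSXP, (R_xlen_t)H * W * Ci * B));
  std::fill(gxv.begin(), gxv.end(), 0.0);
  gxv.attr("dim") = dx;
  NumericVector gwv(Rf_allocVector(REALSXP, (R_xlen_t)4 * Ci * Co));
  std::fill(gwv.begin(), gwv.end(), 0.0);
  gwv.attr("dim") = dw;
  NumericVector gbv(Co);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gp = gy.begin();
  for (int n = 0; n < B; ++n) {
    for (int co = 0; co < Co; ++co) {
      const double* gq = gp + (size_t)(2 * H) * (2 * W) * (co + (size_t)Co * n);
      double acc = 0.0;
      for (size_t k = 0; k < (size_t)(2 * H) * (2 * W); ++k) acc += gq[k];
      gbv[co] += acc;
      for (int ci = 0; ci < Ci; ++ci) {
        const double* xq = xp + (size_t)H * W * (ci + (size_t)Ci * n);
        double* gxq = gxv.begin() + (size_t)H * W * (ci + (size_t)Ci * n);
        const size_t wbase = 4 * ((size_t)ci + (size_t)Ci * co);
        const double w00 = wp[wbase + 0], w10 = wp[wbase + 1];
        const double w01 = wp[wbase + 2], w11 = wp[wbase + 3];
        double g00 = 0, g10 = 0, g01 = 0, g11 = 0;
        for (int wj = 0; wj < W; ++wj)
          for (int hi = 0; hi < H; ++hi) {
            const double* base = gq + 2 * hi + (size_t)(2 * wj) * Ho;
            const double v = xq[hi + (size_t)wj * H];
            g00 += base[0] * v;      g10 += base[1] * v;
            g01 += base[Ho] * v;     g11 += base[Ho + 1] * v;
            gxq[hi + (size_t)wj * H] += w00 * base[0] + w10 * base[1]
                                      + w01 * base[Ho] + w11 * base[Ho + 1];
          }
        gwv[wbase + 0] += g00; gwv[wbase + 1] += g10;
        gwv[wbase + 2] += g01; gwv[wbase + 3] += g11;
      }
    }
  }
  return List::create(_["gx"] = gxv, _["gw"] = gwv, _["gb"] = gbv);
}

// Batch normalization forward: per-channel statistics over (H, W, B).
// Returns y, xhat (cached for backward), inv_std and updated running
// moments.
// [[Rcpp::export]]
List cpp_bn_forward(const NumericVector& x, const NumericVector& gamma,
                    const NumericVector& beta, const NumericVector& rm,
                    const NumericVector& rv, bool training,
                    double momentum, double eps) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const size_t HW = (size_t)H * W;
  NumericVector mu(C), va(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int n = 0; n < B; ++n) {
        const double* p = x.begin() + HW * (c + (size_t)C * n);
        for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      const double m = s / (HW * B);
      mu[c] = m;
      va[c] = s2 / (HW * B) - m * m;
    }
  } else {
    mu = clone(rm); va = clone(rv);
  }
  NumericVector rm_new(C), rv_new(C);
  for (int c = 0; c < C; ++c) {
    rm_new[c] = training ? (1 - momentum) * rm[c] + momentum * mu[c] : rm[c];
    rv_new[c] = training ? (1 - momentum) * rv[c] + momentum * va[c] : rv[c];
  }
  NumericVector inv_std(C);
  for (int c = 0; c < C; ++c) inv_std[c] = 1.0 / std::sqrt(va[c] + eps);
  NumericVector y(Rf_allocVector(REALSXP, x.size()));
  y.attr("dim") = d;
  NumericVector xhat(Rf_allocVector(REALSXP, x.size()));
  xhat.attr("dim") = d;
  for (int n = 0; n < B; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + HW * (c + (size_t)C * n);
      double* xh = xhat.begin() + HW * (c + (size_t)C * n);
      double* yp = y.begin() + HW * (c + (size_t)C * n);
      const double m = mu[c], is = inv_std[c], g = gamma[c], bb = beta[c];
      for (size_t i = 0; i < HW; ++i) {
        const double v = (p[i] - m) * is;
        xh[i] = v;
        yp[i] = g * v + bb;
      }
    }
  return List::create(_["y"] = y, _["xhat"] = xhat,
                      _["inv_std"] = inv_std,
                      _["rm"] = rm_new, _["rv"] = rv_new);
}

// [[Rcpp::export]]
List cpp_bn_backward(const NumericVector& gy, const NumericVector& xhat,
                     const NumericVector& gamma,
                     const NumericVector& inv_std, bool training) {
  IntegerVector d = dims4(gy);
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const size_t HW = (size_t)H * W;
  NumericVector ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    double s1 = 0, s2 = 0;
    for (int n = 0; n < B; ++n) {
      const double* g = gy.begin() + HW * (c + (size_t)C * n);
      const double* xh = xhat.begin() + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) { s1 += g[i]; s2 += g[i] * xh[i]; }
    }
    gbeta[c] = s1;
    ggamma[c] = s2;
  }
  NumericVector gx(Rf_allocVector(REALSXP, gy.size()));
  gx.attr("dim") = d;
  const double n_inv = 1.0 / ((double)HW * B);
  for (int n = 0; n < B; ++n)
    for (int c = 0; c < C; ++c) {
      const double* g = gy.begin() + HW * (c + (size_t)C * n);
      const double* xh = xhat.begin() + HW * (c + (size_t)C * n);
      double* o = gx.begin() + HW * (c + (size_t)C * n);
      const double sc = gamma[c] * inv_std[c];
      if (training) {
        const double a = gbeta[c] * n_inv, b2 = ggamma[c] * n_inv;
        for (size_t i = 0; i < HW; ++i)
          o[i] = sc * (g[i] - a - xh[i] * b2);
      } else {
        for (size_t i = 0; i < HW; ++i) o[i] = sc * g[i];
      }
    }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta);
}

// fused ReLU forward (y = max(x, 0)) and backward mask multiply
// [[Rcpp::export]]
NumericVector cpp_relu_forward(const NumericVector& x) {
  NumericVector y(Rf_allocVector(REALSXP, x.size()));
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_backward(const NumericVector& x,
                                const NumericVector& gy) {
  NumericVector g(Rf_allocVector(REALSXP, x.size()));
  g.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) g[i] = x[i] > 0 ? gy[i] : 0;
  return g;
}
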