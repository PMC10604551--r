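// Low-level dense kernels for the detector's CNN: 2-D convolution,
// transposed convolution and max pooling, all via im2col/col2im + GEMM.
// Tensor layout matches R arrays: dim = c(H, W, C, N), column-major, so a
// (H,W,C) sample is a contiguous block of N such blocks.
// Convolution weights: dim = c(k, k, Cin, Cout); transposed-convolution
// weights: dim = c(k, k, Cout, Cin).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline IntegerVector dims4(const NumericVector &x, const char *what) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("%s must be a 4-d array", what);
  return d;
}

// COL(oh + Ho*ow, i + k*j + k*k*c) = im(oh*s - p + i, ow*s - p + j, c), 0 outside.
static void im2col(const double *im, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo, arma::mat &col) {
  col.zeros(Ho * (arma::uword)Wo, (arma::uword)k * k * C);
  for (int c = 0; c < C; ++c) {
    const double *plane = im + (size_t)c * H * W;
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        const arma::uword cc = i + k * j + k * k * c;
        double *dst = col.colptr(cc);
        for (int ow = 0; ow < Wo; ++ow) {
          int w = ow * stride - pad + j;
          if (w < 0 || w >= W) continue;
          const double *src = plane + (size_t)w * H;
          for (int oh = 0; oh < Ho; ++oh) {
            int h = oh * stride - pad + i;
            if (h < 0 || h >= H) continue;
            dst[oh + (size_t)Ho * ow] = src[h];
          }
        }
      }
    }
  }
}

// Adjoint of im2col: accumulate patches back into the image.
static void col2im(const arma::mat &col, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo, double *im) {
  for (int c = 0; c < C; ++c) {
    double *plane = im + (size_t)c * H * W;
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        const arma::uword cc = i + k * j + k * k * c;
        const double *src = col.colptr(cc);
        for (int ow = 0; ow < Wo; ++ow) {
          int w = ow * stride - pad + j;
          if (w < 0 || w >= W) continue;
          double *dst = plane + (size_t)w * H;
          for (int oh = 0; oh < Ho; ++oh) {
            int h = oh * stride - pad + i;
            if (h < 0 || h >= H) continue;
            dst[h] += src[oh + (size_t)Ho * ow];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cn_conv2d_forward(NumericVector x, NumericVector w,
                                NumericVector b, int stride, int pad) {
  IntegerVector dx = dims4(x, "x"), dw = dims4(w, "w");
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int k = dw[0], Cin = dw[2], Cout = dw[3];
  if (dw[1] != k) stop("kernel must be square");
  if (Cin != C) stop("channel mismatch: input %d vs weight %d", C, Cin);
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");

  arma::mat wm(const_cast<double *>(w.begin()), (arma::uword)k * k * C, Cout, false, true);
  NumericVector out((R_xlen_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, Ho, Wo, col);
    arma::mat y = col * wm;                      // (Ho*Wo) x Cout
    if (b.size() > 0) y.each_row() += arma::rowvec(const_cast<double *>(b.begin()), Cout, false, true);
    std::copy(y.begin(), y.end(), out.begin() + (size_t)n * Ho * Wo * Cout);
  }
  return out;
}

// [[Rcpp::export]]
List cn_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                        int stride, int pad) {
  IntegerVector dx_ = dims4(x, "x"), dw_ = dims4(w, "w"), dd = dims4(dy, "dy");
  int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  int k = dw_[0], Cout = dw_[3];
  int Ho = dd[0], Wo = dd[1];
  if (dd[2] != Cout || dd[3] != N) stop("dy shape mismatch");

  arma::mat wm(const_cast<double *>(w.begin()), (arma::uword)k * k * C, Cout, false, true);
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat dwm((arma::uword)k * k * C, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  arma::mat col;
  for (int n = 0; n < N; ++n) {
    const double *xs = x.begin() + (size_t)n * H * W * C;
    arma::mat dym(const_cast<double *>(dy.begin()) + (size_t)n * Ho * Wo * Cout,
                  (arma::uword)Ho * Wo, Cout, false, true);
    im2col(xs, H, W, C, k, stride, pad, Ho, Wo, col);
    dwm += col.t() * dym;
    db += arma::sum(dym, 0);
    arma::mat dcol = dym * wm.t();
    col2im(dcol, H, W, C, k, stride, pad, Ho, Wo, dx.begin() + (size_t)n * H * W * C);
  }
  NumericVector dwv(dwm.begin(), dwm.end());
  dwv.attr("dim") = IntegerVector::create(k, k, C, Cout);
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
NumericVector cn_convt2d_forward(NumericVector x, NumericVector w,
                                 NumericVector b, int stride, int pad) {
  IntegerVector dx = dims4(x, "x"), dw = dims4(w, "w");
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int k = dw[0], Cout = dw[2], Cin = dw[3];
  if (Cin != C) stop("channel mismatch: input %d vs weight %d", C, Cin);
  int Ho = (H - 1) * stride - 2 * pad + k;
  int Wo = (W - 1) * stride - 2 * pad + k;

  arma::mat wm(const_cast<double *>(w.begin()), (arma::uword)k * k * Cout, Cin, false, true);
  NumericVector out((R_xlen_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  std::fill(out.begin(), out.end(), 0.0);
  for (int n = 0; n < N; ++n) {
    arma::mat xm(const_cast<double *>(x.begin()) + (size_t)n * H * W * C,
                 (arma::uword)H * W, C, false, true);
    arma::mat m = xm * wm.t();                   // (H*W) x (k*k*Cout)
    double *ys = out.begin() + (size_t)n * Ho * Wo * Cout;
    col2im(m, Ho, Wo, Cout, k, stride, pad, H, W, ys);
    if (b.size() > 0)
      for (int c = 0; c < Cout; ++c) {
        double *plane = ys + (size_t)c * Ho * Wo;
        for (size_t t = 0; t < (size_t)Ho * Wo; ++t) plane[t] += b[c];
      }
  }
  return out;
}

// [[Rcpp::export]]
List cn_convt2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pad) {
  IntegerVector dx_ = dims4(x, "x"), dw_ = dims4(w, "w"), dd = dims4(dy, "dy");
  int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  int k = dw_[0], Cout = dw_[2];
  int Ho = dd[0], Wo = dd[1];

  arma::mat wm(const_cast<double *>(w.begin()), (arma::uword)k * k * Cout, C, false, true);
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat dwm((arma::uword)k * k * Cout, C, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat dm;
  for (int n = 0; n < N; ++n) {
    arma::mat xm(const_cast<double *>(x.begin()) + (size_t)n * H * W * C,
                 (arma::uword)H * W, C, false, true);
    const double *dys = dy.begin() + (size_t)n * Ho * Wo * Cout;
    im2col(dys, Ho, Wo, Cout, k, stride, pad, H, W, dm);
    arma::mat dxm = dm * wm;                     // (H*W) x Cin
    std::copy(dxm.begin(), dxm.end(), dx.begin() + (size_t)n * H * W * C);
    dwm += dm.t() * xm;
    for (int c = 0; c < Cout; ++c) {
      const double *plane = dys + (size_t)c * Ho * Wo;
      for (size_t t = 0; t < (size_t)Ho * Wo; ++t) db[c] += plane[t];
    }
  }
  NumericVector dwv(dwm.begin(), dwm.end());
  dwv.attr("dim") = IntegerVector::create(k, k, Cout, C);
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
List cn_maxpool_forward(NumericVector x, int k, int stride, int pad) {
  IntegerVector dx = dims4(x, "x");
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);   // 0-based index into the (H,W) plane
  size_t t = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *plane = x.begin() + ((size_t)n * C + c) * H * W;
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          double best = R_NegInf; int bi = -1;
          for (int j = 0; j < k; ++j) {
            int w = ow * stride - pad + j;
            if (w < 0 || w >= W) continue;
            for (int i = 0; i < k; ++i) {
              int h = oh * stride - pad + i;
              if (h < 0 || h >= H) continue;
              double v = plane[h + (size_t)w * H];
              if (v > best) { best = v; bi = h + w * H; }
            }
          }
          size_t o = ((size_t)n * C + c) * Ho * Wo + oh + (size_t)Ho * ow;
          out[o] = best; idx[o] = bi;
          ++t;
        }
    }
  (void)t;
  return List::create(_["y"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cn_maxpool_backward(NumericVector dy, IntegerVector idx,
                                  int H, int W) {
  IntegerVector dd = dims4(dy, "dy");
  int Ho = dd[0], Wo = dd[1], C = dd[2], N = dd[3];
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double *plane = dx.begin() + ((size_t)n * C + c) * H * W;
      const size_t base = ((size_t)n * C + c) * Ho * Wo;
      for (size_t t = 0; t < (size_t)Ho * Wo; ++t)
        if (idx[base + t] >= 0) plane[idx[base + t]] += dy[base + t];
    }
  return dx;
}

// Batch-normalisation helpers: statistics over (H, W, N) per channel,
// single-pass apply, and the standard backward recomputing xhat on the fly.

// [[Rcpp::export]]
List cn_bn_stats(NumericVector x) {
  IntegerVector d = dims4(x, "x");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t P = (size_t)H * W;
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double *plane = x.begin() + ((size_t)n * C + c) * P;
      for (size_t t = 0; t < P; ++t) { s += plane[t]; s2 += plane[t] * plane[t]; }
    }
    double m = s / (P * N);
    mean[c] = m;
    var[c] = s2 / (P * N) - m * m;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
NumericVector cn_bn_apply(NumericVector x, NumericVector mean, NumericVector ivar,
                          NumericVector gamma, NumericVector beta) {
  IntegerVector d = dims4(x, "x");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t P = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = d;
  for (int c = 0; c < C; ++c) {
    double a = gamma[c] * ivar[c];
    double b = beta[c] - a * mean[c];
    for (int n = 0; n < N; ++n) {
      const double *src = x.begin() + ((size_t)n * C + c) * P;
      double *dst = y.begin() + ((size_t)n * C + c) * P;
      for (size_t t = 0; t < P; ++t) dst[t] = a * src[t] + b;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cn_bn_backward(NumericVector x, NumericVector dy, NumericVector mean,
                    NumericVector ivar, NumericVector gamma) {
  IntegerVector d = dims4(x, "x");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t P = (size_t)H * W;
  double m = (double)P * N;
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double sdy = 0, sdyx = 0;
    for (int n = 0; n < N; ++n) {
      const double *xs = x.begin() + ((size_t)n * C + c) * P;
      const double *ds = dy.begin() + ((size_t)n * C + c) * P;
      for (size_t t = 0; t < P; ++t) {
        double xh = (xs[t] - mean[c]) * ivar[c];
        sdy += ds[t];
        sdyx += ds[t] * xh;
      }
    }
    dgamma[c] = sdyx;
    dbeta[c] = sdy;
    double a = gamma[c] * ivar[c];
    for (int n = 0; n < N; ++n) {
      const double *xs = x.begin() + ((size_t)n * C + c) * P;
      const double *ds = dy.begin() + ((size_t)n * C + c) * P;
      double *dd = dx.begin() + ((size_t)n * C + c) * P;
      for (size_t t = 0; t < P; ++t) {
        double xh = (xs[t] - mean[c]) * ivar[c];
        dd[t] = a * (ds[t] - sdy / m - xh * sdyx / m);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Elementwise rectifier; backward masks on the cached output (y > 0).

// [[Rcpp::export]]
NumericVector cn_relu_forward(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector cn_relu_backward(NumericVector y, NumericVector dy) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[i] = y[i] > 0 ? dy[i] : 0.0;
  return dx;
}

// CBAM plumbing: global per-channel statistics, channel-wise spatial
// statistics, broadcast scaling, and the matching reductions for backward.

// [[Rcpp::export]]
List cn_channel_stats(NumericVector x) {
  IntegerVector d = dims4(x, "x");
  size_t P = (size_t)d[0] * d[1];
  int CN = d[2] * d[3];
  NumericVector avg(CN), mx(CN);
  IntegerVector amax(CN);
  for (int c = 0; c < CN; ++c) {
    const double *plane = x.begin() + (size_t)c * P;
    double s = 0, m = plane[0]; int mi = 0;
    for (size_t t = 0; t < P; ++t) {
      s += plane[t];
      if (plane[t] > m) { m = plane[t]; mi = (int)t; }
    }
    avg[c] = s / P; mx[c] = m; amax[c] = mi;
  }
  return List::create(_["avg"] = avg, _["max"] = mx, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector cn_scale_channel(NumericVector x, NumericVector gate) {
  IntegerVector d = dims4(x, "x");
  size_t P = (size_t)d[0] * d[1];
  int CN = d[2] * d[3];
  NumericVector y(x.size());
  y.attr("dim") = d;
  for (int c = 0; c < CN; ++c) {
    const double *src = x.begin() + (size_t)c * P;
    double *dst = y.begin() + (size_t)c * P;
    double g = gate[c];
    for (size_t t = 0; t < P; ++t) dst[t] = src[t] * g;
  }
  return y;
}

// Per-(channel, sample) dot product of two tensors over the spatial plane.
// [[Rcpp::export]]
NumericVector cn_plane_dot(NumericVector a, NumericVector b) {
  IntegerVector d = dims4(a, "a");
  size_t P = (size_t)d[0] * d[1];
  int CN = d[2] * d[3];
  NumericVector out(CN);
  for (int c = 0; c < CN; ++c) {
    const double *pa = a.begin() + (size_t)c * P;
    const double *pb = b.begin() + (size_t)c * P;
    double s = 0;
    for (size_t t = 0; t < P; ++t) s += pa[t] * pb[t];
    out[c] = s;
  }
  return out;
}

// [[Rcpp::export]]
List cn_spatial_stats(NumericVector x) {
  IntegerVector d = dims4(x, "x");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t P = (size_t)H * W;
  NumericVector stats(2 * P * (size_t)N);
  stats.attr("dim") = IntegerVector::create(H, W, 2, N);
  IntegerVector amax(P * (size_t)N);
  for (int n = 0; n < N; ++n) {
    const double *base = x.begin() + (size_t)n * C * P;
    double *mean_out = stats.begin() + (size_t)n * 2 * P;
    double *max_out = mean_out + P;
    int *am = amax.begin() + (size_t)n * P;
    for (size_t t = 0; t < P; ++t) {
      double s = base[t], m = base[t]; int mi = 0;
      for (int c = 1; c < C; ++c) {
        double v = base[t + (size_t)c * P];
        s += v;
        if (v > m) { m = v; mi = c; }
      }
      mean_out[t] = s / C; max_out[t] = m; am[t] = mi;
    }
  }
  return List::create(_["stats"] = stats, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector cn_scale_spatial(NumericVector x, NumericVector gate) {
  IntegerVector d = dims4(x, "x");
  int C = d[2], N = d[3];
  size_t P = (size_t)d[0] * d[1];
  NumericVector y(x.size());
  y.attr("dim") = d;
  for (int n = 0; n < N; ++n) {
    const double *g = gate.begin() + (size_t)n * P;
    for (int c = 0; c < C; ++c) {
      const double *src = x.begin() + ((size_t)n * C + c) * P;
      double *dst = y.begin() + ((size_t)n * C + c) * P;
      for (size_t t = 0; t < P; ++t) dst[t] = src[t] * g[t];
    }
  }
  return y;
}

// Sum over channels of a*b per pixel -> (H, W, 1, N).
// [[Rcpp::export]]
NumericVector cn_spatial_dot(NumericVector a, NumericVector b) {
  IntegerVector d = dims4(a, "a");
  int C = d[2], N = d[3];
  size_t P = (size_t)d[0] * d[1];
  NumericVector out(P * (size_t)N);
  out.attr("dim") = IntegerVector::create(d[0], d[1], 1, N);
  for (int n = 0; n < N; ++n) {
    double *o = out.begin() + (size_t)n * P;
    for (int c = 0; c < C; ++c) {
      const double *pa = a.begin() + ((size_t)n * C + c) * P;
      const double *pb = b.begin() + ((size_t)n * C + c) * P;
      for (size_t t = 0; t < P; ++t) o[t] += pa[t] * pb[t];
    }
  }
  return out;
}

// Backward of the channel stats: davg spreads uniformly, dmax scatters to
// the argmax position of each (channel, sample) plane. Adds into dx.
// [[Rcpp::export]]
NumericVector cn_channel_stats_backward(NumericVector dx, NumericVector davg,
                                        NumericVector dmax, IntegerVector amax) {
  IntegerVector d = dims4(dx, "dx");
  size_t P = (size_t)d[0] * d[1];
  int CN = d[2] * d[3];
  for (int c = 0; c < CN; ++c) {
    double *plane = dx.begin() + (size_t)c * P;
    double da = davg[c] / P;
    for (size_t t = 0; t < P; ++t) plane[t] += da;
    plane[amax[c]] += dmax[c];
  }
  return dx;
}

// Backward of the spatial stats: mean channel gets dmean/C everywhere, the
// argmax channel gets dmax. Adds into dx.
// [[Rcpp::export]]
NumericVector cn_spatial_stats_backward(NumericVector dx, NumericVector dstats,
                                        IntegerVector amax) {
  IntegerVector d = dims4(dx, "dx");
  int C = d[2], N = d[3];
  size_t P = (size_t)d[0] * d[1];
  for (int n = 0; n < N; ++n) {
    const double *dmean = dstats.begin() + (size_t)n * 2 * P;
    const double *dmax = dmean + P;
    const int *am = amax.begin() + (size_t)n * P;
    for (int c = 0; c < C; ++c) {
      double *plane = dx.begin() + ((size_t)n * C + c) * P;
      for (size_t t = 0; t < P; ++t) {
        plane[t] += dmean[t] / C;
        if (am[t] == c) plane[t] += dmax[t];
      }
    }
  }
  return dx;
}
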