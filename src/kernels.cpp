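// Numerical kernels for the stochastic encoder-decoder and the geometry
// utilities. Feature maps are R arrays of dim (H, W, C, B), column-major,
// so a (channel, batch) slab is contiguous with stride H*W. Convolutions
// use same-padding im2col + BLAS gemm; backward passes rebuild the column
// matrix rather than caching it (memory over speed at desk scale).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Reshape the (kh, kw, Cin, F) weight array into the (kh*kw*Cin, F) matrix
// whose row order matches im2col_t below.
static arma::mat weight_mat(const NumericVector& w, int kh, int kw, int Cin,
                            int F) {
  arma::mat Wm(kh * kw * Cin, F);
  const double* wp = w.begin();
  for (int f = 0; f < F; ++f) {
    int r = 0;
    for (int ci = 0; ci < Cin; ++ci)
      for (int dj = 0; dj < kw; ++dj)
        for (int di = 0; di < kh; ++di)
          Wm(r++, f) = wp[di + (size_t)kh * (dj + (size_t)kw * (ci + (size_t)Cin * f))];
  }
  return Wm;
}

// colT is (H*W) x (kh*kw*Cin); spatial index s = i + H*j.
static void im2col_t(const double* x, int H, int W, int Cin, int kh, int kw,
                     arma::mat& colT) {
  const int ph = kh / 2, pw = kw / 2;
  colT.zeros();
  int r = 0;
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + (size_t)H * W * ci;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        double* dst = colT.colptr(r++);
        const int i0 = std::max(0, ph - di);
        const int i1 = std::min(H, H + ph - di);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pw;
          if (sj < 0 || sj >= W) continue;
          const double* src = xc + (size_t)H * sj + (di - ph);
          double* d = dst + (size_t)H * j;
          for (int i = i0; i < i1; ++i) d[i] = src[i];
        }
      }
    }
  }
}

// Adjoint of im2col_t: scatter-add the column gradient back onto the image.
static void col2im_t(const arma::mat& dcolT, int H, int W, int Cin, int kh,
                     int kw, double* dx) {
  const int ph = kh / 2, pw = kw / 2;
  int r = 0;
  for (int ci = 0; ci < Cin; ++ci) {
    double* xc = dx + (size_t)H * W * ci;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const double* src0 = dcolT.colptr(r++);
        const int i0 = std::max(0, ph - di);
        const int i1 = std::min(H, H + ph - di);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pw;
          if (sj < 0 || sj >= W) continue;
          double* d = xc + (size_t)H * sj + (di - ph);
          const double* src = src0 + (size_t)H * j;
          for (int i = i0; i < i1; ++i) d[i] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  const size_t HW = (size_t)H * W;
  arma::mat Wm = weight_mat(w, kh, kw, Cin, F);
  NumericVector y(HW * F * B);
  y.attr("dim") = IntegerVector::create(H, W, F, B);
  arma::mat colT(HW, (size_t)kh * kw * Cin);
  for (int b = 0; b < B; ++b) {
    im2col_t(x.begin() + HW * Cin * b, H, W, Cin, kh, kw, colT);
    arma::mat ym(y.begin() + HW * F * b, HW, F, false, true);
    ym = colT * Wm;
    for (int f = 0; f < F; ++f) ym.col(f) += bias[f];
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  const size_t HW = (size_t)H * W;
  arma::mat Wm = weight_mat(w, kh, kw, Cin, F);
  arma::mat dWm(Wm.n_rows, Wm.n_cols, arma::fill::zeros);
  NumericVector dx(x.size()), dw(w.size()), db(F);
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  arma::mat colT(HW, (size_t)kh * kw * Cin);
  for (int b = 0; b < B; ++b) {
    im2col_t(x.begin() + HW * Cin * b, H, W, Cin, kh, kw, colT);
    const arma::mat dym(const_cast<double*>(dy.begin()) + HW * F * b, HW, F,
                        false, true);
    dWm += colT.t() * dym;
    arma::mat dcolT = dym * Wm.t();
    col2im_t(dcolT, H, W, Cin, kh, kw, dx.begin() + HW * Cin * b);
    for (int f = 0; f < F; ++f) db[f] += arma::accu(dym.col(f));
  }
  double* dwp = dw.begin();
  for (int f = 0; f < F; ++f) {
    int r = 0;
    for (int ci = 0; ci < Cin; ++ci)
      for (int dj = 0; dj < kw; ++dj)
        for (int di = 0; di < kh; ++di)
          dwp[di + (size_t)kh * (dj + (size_t)kw * (ci + (size_t)Cin * f))] =
              dWm(r++, f);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2; idx caches the winning input element (1-based
// linear index into x) for the backward scatter.
// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * B);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  size_t o = 0;
  for (int cb = 0; cb < C * B; ++cb) {
    const size_t base = (size_t)H * W * cb;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        size_t k00 = base + 2 * i + (size_t)H * (2 * j);
        size_t best = k00;
        double v = xp[k00];
        const size_t cand[3] = {k00 + 1, k00 + H, k00 + H + 1};
        for (int q = 0; q < 3; ++q)
          if (xp[cand[q]] > v) { v = xp[cand[q]]; best = cand[q]; }
        yp[o] = v;
        ip[o++] = (int)(best + 1);
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(IntegerVector idx, NumericVector dy,
                           IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  for (R_xlen_t k = 0; k < dy.size(); ++k) dxp[ip[k] - 1] += dyp[k];
  return dx;
}

// Transposed convolution with a 2x2 kernel and stride 2 (learned upsampling;
// the stride equals the kernel so output blocks do not overlap).
// [[Rcpp::export]]
NumericVector convt2_fwd(NumericVector x, NumericVector w, NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  const int F = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  const size_t HW = (size_t)H * W, HWo = (size_t)Ho * Wo;
  NumericVector y(HWo * F * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, B);
  const double* wp = w.begin();
  for (int b = 0; b < B; ++b) {
    const arma::mat xm(const_cast<double*>(x.begin()) + HW * Cin * b, HW, Cin,
                       false, true);
    for (int dj = 0; dj < 2; ++dj) {
      for (int di = 0; di < 2; ++di) {
        arma::mat Wsub(Cin, F);
        for (int f = 0; f < F; ++f)
          for (int ci = 0; ci < Cin; ++ci)
            Wsub(ci, f) = wp[di + 2 * (dj + 2 * (ci + (size_t)Cin * f))];
        arma::mat ysub = xm * Wsub;  // HW x F
        for (int f = 0; f < F; ++f) {
          double* yc = y.begin() + HWo * (f + (size_t)F * b);
          const double* sc = ysub.colptr(f);
          const double bf = bias[f];
          for (int j = 0; j < W; ++j) {
            double* d = yc + (size_t)Ho * (2 * j + dj) + di;
            const double* s = sc + (size_t)H * j;
            for (int i = 0; i < H; ++i) d[2 * i] = s[i] + bf;
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List convt2_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  const int F = wd[3];
  const int Ho = 2 * H;
  const size_t HW = (size_t)H * W, HWo = (size_t)Ho * 2 * W;
  NumericVector dx(x.size()), dw(w.size()), db(F);
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  const double* wp = w.begin();
  double* dwp = dw.begin();
  for (int b = 0; b < B; ++b) {
    const arma::mat xm(const_cast<double*>(x.begin()) + HW * Cin * b, HW, Cin,
                       false, true);
    arma::mat dxm(dx.begin() + HW * Cin * b, HW, Cin, false, true);
    for (int dj = 0; dj < 2; ++dj) {
      for (int di = 0; di < 2; ++di) {
        arma::mat dysub(HW, F);
        for (int f = 0; f < F; ++f) {
          const double* yc = dy.begin() + HWo * (f + (size_t)F * b);
          double* dcol = dysub.colptr(f);
          for (int j = 0; j < W; ++j) {
            const double* s = yc + (size_t)Ho * (2 * j + dj) + di;
            double* d = dcol + (size_t)H * j;
            for (int i = 0; i < H; ++i) d[i] = s[2 * i];
          }
        }
        arma::mat Wsub(Cin, F);
        for (int f = 0; f < F; ++f)
          for (int ci = 0; ci < Cin; ++ci)
            Wsub(ci, f) = wp[di + 2 * (dj + 2 * (ci + (size_t)Cin * f))];
        arma::mat dWsub = xm.t() * dysub;
        for (int f = 0; f < F; ++f) {
          for (int ci = 0; ci < Cin; ++ci)
            dwp[di + 2 * (dj + 2 * (ci + (size_t)Cin * f))] += dWsub(ci, f);
          db[f] += arma::accu(dysub.col(f));
        }
        dxm += dysub * Wsub.t();
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Per-channel mean and (biased) variance over H, W and batch.
// [[Rcpp::export]]
List bn_stats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[2], B = xd[3];
  const size_t HW = (size_t)xd[0] * xd[1];
  NumericVector mean(C), var(C);
  const double m = (double)HW * B;
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int b = 0; b < B; ++b) {
      const double* p = x.begin() + HW * (c + (size_t)C * b);
      for (size_t k = 0; k < HW; ++k) { s += p[k]; s2 += p[k] * p[k]; }
    }
    mean[c] = s / m;
    var[c] = s2 / m - mean[c] * mean[c];
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
NumericVector bn_apply(NumericVector x, NumericVector mean, NumericVector var,
                       NumericVector gamma, NumericVector beta, double eps) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[2], B = xd[3];
  const size_t HW = (size_t)xd[0] * xd[1];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    const double istd = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c] * istd, off = beta[c] - gamma[c] * istd * mean[c];
    for (int b = 0; b < B; ++b) {
      const double* p = x.begin() + HW * (c + (size_t)C * b);
      double* q = y.begin() + HW * (c + (size_t)C * b);
      for (size_t k = 0; k < HW; ++k) q[k] = g * p[k] + off;
    }
  }
  return y;
}

// Standard batch-norm backward using the batch statistics.
// [[Rcpp::export]]
List bn_bwd(NumericVector x, NumericVector mean, NumericVector var,
            NumericVector gamma, double eps, NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[2], B = xd[3];
  const size_t HW = (size_t)xd[0] * xd[1];
  const double m = (double)HW * B;
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  dx.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    const double istd = 1.0 / std::sqrt(var[c] + eps);
    double sg = 0, sb = 0;
    for (int b = 0; b < B; ++b) {
      const double* xp = x.begin() + HW * (c + (size_t)C * b);
      const double* dp = dy.begin() + HW * (c + (size_t)C * b);
      for (size_t k = 0; k < HW; ++k) {
        sg += dp[k] * (xp[k] - mean[c]) * istd;
        sb += dp[k];
      }
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    const double a = gamma[c] * istd / m;
    for (int b = 0; b < B; ++b) {
      const double* xp = x.begin() + HW * (c + (size_t)C * b);
      const double* dp = dy.begin() + HW * (c + (size_t)C * b);
      double* q = dx.begin() + HW * (c + (size_t)C * b);
      for (size_t k = 0; k < HW; ++k)
        q[k] = a * (m * dp[k] - sb - (xp[k] - mean[c]) * istd * sg);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Inverse-mapped affine warp: each output pixel (i, j), 0-based, samples the
// input at src = Ainv %*% (dst - cdst) + csrc. Out-of-grid samples read as
// `fill`; bilinear or nearest-neighbour interpolation.
// [[Rcpp::export]]
NumericMatrix warp_affine(NumericMatrix img, NumericMatrix Ainv,
                          NumericVector cdst, NumericVector csrc, int out_h,
                          int out_w, bool bilinear, double fill,
                          bool clamp) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(out_h, out_w);
  const double a11 = Ainv(0, 0), a12 = Ainv(0, 1), a21 = Ainv(1, 0),
               a22 = Ainv(1, 1);
  for (int j = 0; j < out_w; ++j) {
    const double dj = j - cdst[1];
    for (int i = 0; i < out_h; ++i) {
      const double di = i - cdst[0];
      double si = a11 * di + a12 * dj + csrc[0];
      double sj = a21 * di + a22 * dj + csrc[1];
      if (clamp) {
        si = std::min(std::max(si, 0.0), (double)(H - 1));
        sj = std::min(std::max(sj, 0.0), (double)(W - 1));
      }
      if (bilinear) {
        const int i0 = (int)std::floor(si), j0 = (int)std::floor(sj);
        const double fi = si - i0, fj = sj - j0;
        double acc = 0;
        for (int dj2 = 0; dj2 <= 1; ++dj2) {
          for (int di2 = 0; di2 <= 1; ++di2) {
            const int ii = i0 + di2, jj = j0 + dj2;
            const double wgt = (di2 ? fi : 1 - fi) * (dj2 ? fj : 1 - fj);
            const double v = (ii >= 0 && ii < H && jj >= 0 && jj < W)
                                 ? img(ii, jj)
                                 : fill;
            acc += wgt * v;
          }
        }
        out(i, j) = acc;
      } else {
        const int ii = (int)std::lround(si), jj = (int)std::lround(sj);
        out(i, j) = (ii >= 0 && ii < H && jj >= 0 && jj < W) ? img(ii, jj)
                                                             : fill;
      }
    }
  }
  return out;
}

// For each row of `a` (points in mm), the Euclidean distance to the nearest
// row of `b`. Exact O(n*m) scan; boundary sets at this image scale are small.
// [[Rcpp::export]]
NumericVector min_dists(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double ai = a(i, 0), aj = a(i, 1);
    double best = R_PosInf;
    for (int k = 0; k < m; ++k) {
      const double d0 = ai - b(k, 0), d1 = aj - b(k, 1);
      const double d = d0 * d0 + d1 * d1;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
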