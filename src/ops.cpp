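// Low-level compute kernels for the segmentation networks.
//
// All feature maps are dense double arrays with dim = c(H, W, C, N)
// (column-major, H fastest). Convolutions are stride-1 with symmetric
// zero padding; pooling and up-sampling work on a fixed 2x2 window,
// which is all the U-Net family needs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector &x, int &H, int &W, int &C, int &N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// Gather the k*k*C receptive fields of every output pixel of one sample
// into a (H*W) x (k*k*C) matrix. Column index = ki + k*kj + k*k*ci.
static void im2col(const double *x, int H, int W, int C, int k, int pad,
                   arma::mat &col) {
  const int HW = H * W;
  for (int ci = 0; ci < C; ++ci) {
    const double *xc = x + (size_t)ci * HW;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double *dst = col.colptr(ki + k * kj + k * k * ci);
        for (int w = 0; w < W; ++w) {
          int xw = w + kj - pad;
          if (xw < 0 || xw >= W) {
            std::fill(dst + (size_t)w * H, dst + (size_t)(w + 1) * H, 0.0);
            continue;
          }
          const double *src = xc + (size_t)xw * H;
          double *d0 = dst + (size_t)w * H;
          int h0 = std::max(0, pad - ki), h1 = std::min(H, H + pad - ki);
          for (int h = 0; h < h0; ++h) d0[h] = 0.0;
          for (int h = h0; h < h1; ++h) d0[h] = src[h + ki - pad];
          for (int h = h1; h < H; ++h) d0[h] = 0.0;
        }
      }
    }
  }
}

// Scatter-add the columns back to image layout (transpose of im2col).
static void col2im(const arma::mat &col, int H, int W, int C, int k, int pad,
                   double *gx) {
  const int HW = H * W;
  for (int ci = 0; ci < C; ++ci) {
    double *xc = gx + (size_t)ci * HW;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double *src = col.colptr(ki + k * kj + k * k * ci);
        for (int w = 0; w < W; ++w) {
          int xw = w + kj - pad;
          if (xw < 0 || xw >= W) continue;
          double *x0 = xc + (size_t)xw * H;
          const double *s0 = src + (size_t)w * H;
          int h0 = std::max(0, pad - ki), h1 = std::min(H, H + pad - ki);
          for (int h = h0; h < h1; ++h) x0[h + ki - pad] += s0[h];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b, int pad) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (wd[1] != k) stop("non-square kernel");
  if (Cin != C) stop("conv2d: input has %d channels, kernel expects %d", C, Cin);
  const int HW = H * W, kkC = k * k * C;
  NumericVector y(no_init((size_t)HW * Cout * N));
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(const_cast<double *>(w.begin()), kkC, Cout, false, true);
  arma::mat col(HW, kkC);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * C, H, W, C, k, pad, col);
    arma::mat ym(y.begin() + (size_t)n * HW * Cout, HW, Cout, false, true);
    ym = col * Wm;
    if (b.size() == Cout)
      for (int co = 0; co < Cout; ++co) ym.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy, int pad) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int k = wd[0], Cout = wd[3];
  const int HW = H * W, kkC = k * k * C;
  arma::mat Wm(const_cast<double *>(w.begin()), kkC, Cout, false, true);
  NumericVector gx((size_t)HW * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector gw((size_t)kkC * Cout);
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::mat gWm(gw.begin(), kkC, Cout, false, true);
  arma::mat col(HW, kkC);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * C, H, W, C, k, pad, col);
    arma::mat gym(const_cast<double *>(gy.begin()) + (size_t)n * HW * Cout,
                  HW, Cout, false, true);
    gWm += col.t() * gym;
    for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(gym.col(co));
    arma::mat gcol = gym * Wm.t();
    col2im(gcol, H, W, C, k, pad, gx.begin() + (size_t)n * HW * C);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("max pooling needs even spatial dims, got %d x %d", H, W);
  int Ho = H / 2, Wo = W / 2;
  NumericVector y(no_init((size_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(no_init((size_t)Ho * Wo * C * N));
  const double *xp = x.begin();
  double *yp = y.begin();
  int *ip = idx.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t base = ((size_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          size_t p00 = base + (size_t)(2 * w) * H + 2 * h;
          size_t cand[4] = {p00, p00 + 1, p00 + H, p00 + H + 1};
          size_t best = cand[0];
          for (int t = 1; t < 4; ++t) if (xp[cand[t]] > xp[best]) best = cand[t];
          yp[o] = xp[best];
          ip[o] = (int)best; // safe: tensors here stay < 2^31 elements
          ++o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  return gx;
}

// [[Rcpp::export(name = ".upsample2_fwd")]]
NumericVector upsample2_fwd(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(no_init((size_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *xp = x.begin();
  double *yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t bx = ((size_t)n * C + c) * H * W;
      size_t by = ((size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < Wo; ++w) {
        const double *src = xp + bx + (size_t)(w / 2) * H;
        double *dst = yp + by + (size_t)w * Ho;
        for (int h = 0; h < H; ++h) { dst[2 * h] = src[h]; dst[2 * h + 1] = src[h]; }
      }
    }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bwd")]]
NumericVector upsample2_bwd(NumericVector gy) {
  int Ho, Wo, C, N; get_dims4(gy, Ho, Wo, C, N);
  int H = Ho / 2, W = Wo / 2;
  NumericVector gx(no_init((size_t)H * W * C * N));
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double *gp = gy.begin();
  double *xp = gx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t bx = ((size_t)n * C + c) * H * W;
      size_t by = ((size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < W; ++w) {
        double *dst = xp + bx + (size_t)w * H;
        const double *s0 = gp + by + (size_t)(2 * w) * Ho;
        const double *s1 = gp + by + (size_t)(2 * w + 1) * Ho;
        for (int h = 0; h < H; ++h)
          dst[h] = s0[2 * h] + s0[2 * h + 1] + s1[2 * h] + s1[2 * h + 1];
      }
    }
  return gx;
}

// Batch normalization over (H, W, N) per channel, training mode.
// [[Rcpp::export(name = ".bn_fwd")]]
List bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta, double eps) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const size_t HW = (size_t)H * W;
  NumericVector y(no_init(x.size()));
  y.attr("dim") = x.attr("dim");
  NumericVector mean(C), invstd(C), var_unb(C);
  double M = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double *p = x.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    double mu = s / M, v = s2 / M - mu * mu;
    if (v < 0) v = 0;
    mean[c] = mu;
    invstd[c] = 1.0 / std::sqrt(v + eps);
    var_unb[c] = M > 1 ? v * M / (M - 1) : v;
    double a = gamma[c] * invstd[c], b0 = beta[c] - a * mu;
    for (int n = 0; n < N; ++n) {
      const double *p = x.begin() + ((size_t)n * C + c) * HW;
      double *q = y.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) q[i] = a * p[i] + b0;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["invstd"] = invstd,
                      _["var_unbiased"] = var_unb);
}

// [[Rcpp::export(name = ".bn_bwd")]]
List bn_bwd(NumericVector x, NumericVector gy, NumericVector gamma,
            NumericVector mean, NumericVector invstd) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const size_t HW = (size_t)H * W;
  double M = (double)HW * N;
  NumericVector gx(no_init(x.size()));
  gx.attr("dim") = x.attr("dim");
  NumericVector ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0, sgx = 0; // sum(gy), sum(gy * xhat)
    for (int n = 0; n < N; ++n) {
      const double *p = x.begin() + ((size_t)n * C + c) * HW;
      const double *g = gy.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) {
        double xh = (p[i] - mean[c]) * invstd[c];
        sg += g[i]; sgx += g[i] * xh;
      }
    }
    gbeta[c] = sg; ggamma[c] = sgx;
    double a = gamma[c] * invstd[c] / M;
    for (int n = 0; n < N; ++n) {
      const double *p = x.begin() + ((size_t)n * C + c) * HW;
      const double *g = gy.begin() + ((size_t)n * C + c) * HW;
      double *q = gx.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) {
        double xh = (p[i] - mean[c]) * invstd[c];
        q[i] = a * (M * g[i] - sg - xh * sgx);
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}
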