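// Low-level tensor primitives for the CPU training core.
// Layout convention everywhere: activations are (H, W, C, N) column-major
// R arrays; convolution weights are (kh, kw, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void dims4(const NumericVector &a, int d[4]) {
  IntegerVector dm = a.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// im2col for one sample: M is K x P with K = kh*kw*C, P = Ho*Wo,
// column index p = ho + Ho*wo.
static void im2col(const double *x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat &M) {
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        const int krow = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int win = wo * stride - pad + j;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hin = ho * stride - pad + i;
            double v = 0.0;
            if (hin >= 0 && hin < H && win >= 0 && win < W)
              v = x[hin + (size_t)H * (win + (size_t)W * c)];
            M(krow, ho + (size_t)Ho * wo) = v;
          }
        }
      }
}

static void col2im_acc(const arma::mat &M, double *gx, int H, int W, int C,
                       int kh, int kw, int stride, int pad, int Ho, int Wo) {
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        const int krow = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int win = wo * stride - pad + j;
          if (win < 0 || win >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hin = ho * stride - pad + i;
            if (hin < 0 || hin >= H) continue;
            gx[hin + (size_t)H * (win + (size_t)W * c)] +=
                M(krow, ho + (size_t)Ho * wo);
          }
        }
      }
}

// [[Rcpp::export(name = ".cpp_conv_fwd")]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                           int stride, int pad) {
  int xd[4], wd[4];
  dims4(x, xd); dims4(w, wd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch in conv forward");
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv output would be empty");
  const int K = kh * kw * C, P = Ho * Wo;

  arma::mat Wm(K, Cout);
  for (int o = 0; o < Cout; ++o)
    for (int k = 0; k < K; ++k)
      Wm(k, o) = w[k + (size_t)K * o];

  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat M(K, P);
  for (int n = 0; n < N; ++n) {
    im2col(&x[0] + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad, Ho, Wo, M);
    arma::mat Y = M.t() * Wm;  // P x Cout
    double *yp = &y[0] + (size_t)P * Cout * n;
    for (int o = 0; o < Cout; ++o) {
      const double bo = b[o];
      for (int p = 0; p < P; ++p) yp[p + (size_t)P * o] = Y(p, o) + bo;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv_bwd")]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector gy,
                  int stride, int pad) {
  int xd[4], wd[4], gd[4];
  dims4(x, xd); dims4(w, wd); dims4(gy, gd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1];
  const int K = kh * kw * C, P = Ho * Wo;

  arma::mat Wm(K, Cout);
  for (int o = 0; o < Cout; ++o)
    for (int k = 0; k < K; ++k)
      Wm(k, o) = w[k + (size_t)K * o];

  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat gW(K, Cout, arma::fill::zeros);
  NumericVector gb(Cout);

  arma::mat M(K, P), G(P, Cout);
  for (int n = 0; n < N; ++n) {
    const double *gp = &gy[0] + (size_t)P * Cout * n;
    for (int o = 0; o < Cout; ++o)
      for (int p = 0; p < P; ++p) G(p, o) = gp[p + (size_t)P * o];
    im2col(&x[0] + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad, Ho, Wo, M);
    gW += M * G;
    for (int o = 0; o < Cout; ++o) gb[o] += arma::accu(G.col(o));
    arma::mat gM = Wm * G.t();  // K x P
    col2im_acc(gM, &gx[0] + (size_t)H * W * C * n, H, W, C, kh, kw, stride,
               pad, Ho, Wo);
  }

  NumericVector gw((size_t)K * Cout);
  gw.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
  for (int o = 0; o < Cout; ++o)
    for (int k = 0; k < K; ++k) gw[k + (size_t)K * o] = gW(k, o);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// k x k pooling, stride 1, same padding (k odd). type: 0 = avg, 1 = max.
// Average pooling divides by k*k (zero padding); max pooling ignores
// out-of-bounds positions.
// [[Rcpp::export(name = ".cpp_pool_fwd")]]
List cpp_pool_fwd(NumericVector x, int k, int type) {
  int xd[4];
  dims4(x, xd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int half = (k - 1) / 2;
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  IntegerVector idx(type == 1 ? x.size() : 0);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)H * W * (c + (size_t)C * n);
      const double *xp = &x[0] + off;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          if (type == 0) {
            double s = 0.0;
            for (int j = -half; j <= half; ++j) {
              const int ww = w + j;
              if (ww < 0 || ww >= W) continue;
              for (int i = -half; i <= half; ++i) {
                const int hh = h + i;
                if (hh < 0 || hh >= H) continue;
                s += xp[hh + (size_t)H * ww];
              }
            }
            y[off + h + (size_t)H * w] = s / (k * k);
          } else {
            double best = -std::numeric_limits<double>::infinity();
            int bi = -1;
            for (int j = -half; j <= half; ++j) {
              const int ww = w + j;
              if (ww < 0 || ww >= W) continue;
              for (int i = -half; i <= half; ++i) {
                const int hh = h + i;
                if (hh < 0 || hh >= H) continue;
                const double v = xp[hh + (size_t)H * ww];
                if (v > best) { best = v; bi = hh + H * ww; }
              }
            }
            y[off + h + (size_t)H * w] = best;
            idx[off + h + (size_t)H * w] = bi;
          }
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_pool_bwd")]]
NumericVector cpp_pool_bwd(NumericVector gy, IntegerVector idx, int k, int type) {
  int gd[4];
  dims4(gy, gd);
  const int H = gd[0], W = gd[1], C = gd[2], N = gd[3];
  const int half = (k - 1) / 2;
  NumericVector gx(gy.size());
  gx.attr("dim") = gy.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)H * W * (c + (size_t)C * n);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double g = gy[off + h + (size_t)H * w];
          if (type == 0) {
            const double gs = g / (k * k);
            for (int j = -half; j <= half; ++j) {
              const int ww = w + j;
              if (ww < 0 || ww >= W) continue;
              for (int i = -half; i <= half; ++i) {
                const int hh = h + i;
                if (hh < 0 || hh >= H) continue;
                gx[off + hh + (size_t)H * ww] += gs;
              }
            }
          } else {
            gx[off + idx[off + h + (size_t)H * w]] += g;
          }
        }
    }
  return gx;
}

// Nearest-neighbour resize to (Ho, Wo).
// [[Rcpp::export(name = ".cpp_resize_fwd")]]
NumericVector cpp_resize_fwd(NumericVector x, int Ho, int Wo) {
  int xd[4];
  dims4(x, xd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> hmap(Ho), wmap(Wo);
  for (int ho = 0; ho < Ho; ++ho)
    hmap[ho] = std::min(H - 1, (int)std::floor((ho + 0.5) * H / Ho));
  for (int wo = 0; wo < Wo; ++wo)
    wmap[wo] = std::min(W - 1, (int)std::floor((wo + 0.5) * W / Wo));
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xp = &x[0] + (size_t)H * W * (c + (size_t)C * n);
      double *yp = &y[0] + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          yp[ho + (size_t)Ho * wo] = xp[hmap[ho] + (size_t)H * wmap[wo]];
    }
  return y;
}

// [[Rcpp::export(name = ".cpp_resize_bwd")]]
NumericVector cpp_resize_bwd(NumericVector gy, int H, int W) {
  int gd[4];
  dims4(gy, gd);
  const int Ho = gd[0], Wo = gd[1], C = gd[2], N = gd[3];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::vector<int> hmap(Ho), wmap(Wo);
  for (int ho = 0; ho < Ho; ++ho)
    hmap[ho] = std::min(H - 1, (int)std::floor((ho + 0.5) * H / Ho));
  for (int wo = 0; wo < Wo; ++wo)
    wmap[wo] = std::min(W - 1, (int)std::floor((wo + 0.5) * W / Wo));
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *gp = &gy[0] + (size_t)Ho * Wo * (c + (size_t)C * n);
      double *xp = &gx[0] + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          xp[hmap[ho] + (size_t)H * wmap[wo]] += gp[ho + (size_t)Ho * wo];
    }
  return gx;
}
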