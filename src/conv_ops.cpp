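// Dense and dilated 2D convolution kernels (im2col + GEMM) used by the
// autodiff engine. Arrays follow the (batch, channel, height, width)
// contract of the R side, i.e. an R array with dim = c(N, C, H, W) in
// column-major order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out_size(int in, int k, int s, int p, int d) {
  return (in + 2 * p - d * (k - 1) - 1) / s + 1;
}

// Gather the patch matrix for sample n: rows index (ci, i, j), columns
// index output positions (ho, wo). Out-of-bounds taps are zero.
static void im2col_sample(const double* x, int n, int N, int C, int H, int W,
                          int kh, int kw, int s, int p, int d,
                          int Ho, int Wo, arma::mat& col) {
  for (int j = 0; j < kw; ++j) {
    for (int i = 0; i < kh; ++i) {
      for (int ci = 0; ci < C; ++ci) {
        int r = ci + C * (i + kh * j);
        for (int wo = 0; wo < Wo; ++wo) {
          int w = wo * s - p + j * d;
          for (int ho = 0; ho < Ho; ++ho) {
            int h = ho * s - p + i * d;
            int q = ho + Ho * wo;
            if (h >= 0 && h < H && w >= 0 && w < W) {
              col(r, q) = x[n + (R_xlen_t)N * (ci + (R_xlen_t)C * (h + (R_xlen_t)H * w))];
            } else {
              col(r, q) = 0.0;
            }
          }
        }
      }
    }
  }
}

// Scatter-add of a patch-matrix gradient back onto the input gradient.
static void col2im_sample(const arma::mat& col, double* gx, int n, int N,
                          int C, int H, int W, int kh, int kw, int s, int p,
                          int d, int Ho, int Wo) {
  for (int j = 0; j < kw; ++j) {
    for (int i = 0; i < kh; ++i) {
      for (int ci = 0; ci < C; ++ci) {
        int r = ci + C * (i + kh * j);
        for (int wo = 0; wo < Wo; ++wo) {
          int w = wo * s - p + j * d;
          if (w < 0 || w >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int h = ho * s - p + i * d;
            if (h < 0 || h >= H) continue;
            int q = ho + Ho * wo;
            gx[n + (R_xlen_t)N * (ci + (R_xlen_t)C * (h + (R_xlen_t)H * w))] += col(r, q);
          }
        }
      }
    }
  }
}

// Weight array (Co, Ci, kh, kw) -> matrix (Co x Ci*kh*kw) whose column
// ordering matches the im2col row ordering.
static arma::mat weight_matrix(const NumericVector& w, int Co, int Ci, int kh, int kw) {
  arma::mat Wm(Co, Ci * kh * kw);
  const double* wp = w.begin();
  for (int j = 0; j < kw; ++j)
    for (int i = 0; i < kh; ++i)
      for (int ci = 0; ci < Ci; ++ci) {
        int r = ci + Ci * (i + kh * j);
        for (int co = 0; co < Co; ++co)
          Wm(co, r) = wp[co + (R_xlen_t)Co * (ci + (R_xlen_t)Ci * (i + (R_xlen_t)kh * j))];
      }
  return Wm;
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int Co = wd[0], Ci = wd[1], kh = wd[2], kw = wd[3];
  if (Ci != C) stop("conv2d: input has %d channels but weight expects %d", C, Ci);
  int Ho = conv_out_size(H, kh, stride, pad, dil);
  int Wo = conv_out_size(W, kw, stride, pad, dil);
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");

  arma::mat Wm = weight_matrix(w, Co, Ci, kh, kw);
  NumericVector y((R_xlen_t)N * Co * Ho * Wo);
  arma::mat col(Ci * kh * kw, Ho * Wo);
  double* yp = y.begin();
  const double* xp = x.begin();
  arma::vec b;
  bool has_b = bias.isNotNull();
  if (has_b) b = as<arma::vec>(bias.get());

  for (int n = 0; n < N; ++n) {
    im2col_sample(xp, n, N, C, H, W, kh, kw, stride, pad, dil, Ho, Wo, col);
    arma::mat yn = Wm * col;                    // Co x (Ho*Wo)
    if (has_b) yn.each_col() += b;
    for (int q = 0; q < Ho * Wo; ++q)
      for (int co = 0; co < Co; ++co)
        yp[n + (R_xlen_t)N * (co + (R_xlen_t)Co * q)] = yn(co, q);
  }
  y.attr("dim") = IntegerVector::create(N, Co, Ho, Wo);
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd_x")]]
NumericVector cpp_conv2d_bwd_x(NumericVector gy, NumericVector w,
                               int stride, int pad, int dil,
                               int Hin, int Win) {
  IntegerVector gd = gy.attr("dim"), wd = w.attr("dim");
  int N = gd[0], Co = gd[1], Ho = gd[2], Wo = gd[3];
  int Co_w = wd[0], Ci = wd[1], kh = wd[2], kw = wd[3];
  if (Co_w != Co) stop("conv2d backward: gradient has %d channels but weight has %d", Co, Co_w);

  arma::mat Wm = weight_matrix(w, Co, Ci, kh, kw);
  NumericVector gx((R_xlen_t)N * Ci * Hin * Win); // zero-initialised
  double* gxp = gx.begin();
  const double* gp = gy.begin();
  arma::mat gyn(Co, Ho * Wo);

  for (int n = 0; n < N; ++n) {
    for (int q = 0; q < Ho * Wo; ++q)
      for (int co = 0; co < Co; ++co)
        gyn(co, q) = gp[n + (R_xlen_t)N * (co + (R_xlen_t)Co * q)];
    arma::mat colg = Wm.t() * gyn;              // (Ci*kh*kw) x (Ho*Wo)
    col2im_sample(colg, gxp, n, N, Ci, Hin, Win, kh, kw, stride, pad, dil, Ho, Wo);
  }
  gx.attr("dim") = IntegerVector::create(N, Ci, Hin, Win);
  return gx;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd_w")]]
NumericVector cpp_conv2d_bwd_w(NumericVector x, NumericVector gy,
                               int stride, int pad, int dil,
                               int kh, int kw) {
  IntegerVector xd = x.attr("dim"), gd = gy.attr("dim");
  int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int Co = gd[1], Ho = gd[2], Wo = gd[3];

  arma::mat gw(Co, C * kh * kw, arma::fill::zeros);
  arma::mat col(C * kh * kw, Ho * Wo);
  arma::mat gyn(Co, Ho * Wo);
  const double* xp = x.begin();
  const double* gp = gy.begin();

  for (int n = 0; n < N; ++n) {
    im2col_sample(xp, n, N, C, H, W, kh, kw, stride, pad, dil, Ho, Wo, col);
    for (int q = 0; q < Ho * Wo; ++q)
      for (int co = 0; co < Co; ++co)
        gyn(co, q) = gp[n + (R_xlen_t)N * (co + (R_xlen_t)Co * q)];
    gw += gyn * col.t();
  }

  NumericVector out((R_xlen_t)Co * C * kh * kw);
  double* op = out.begin();
  for (int j = 0; j < kw; ++j)
    for (int i = 0; i < kh; ++i)
      for (int ci = 0; ci < C; ++ci) {
        int r = ci + C * (i + kh * j);
        for (int co = 0; co < Co; ++co)
          op[co + (R_xlen_t)Co * (ci + (R_xlen_t)C * (i + (R_xlen_t)kh * j))] = gw(co, r);
      }
  out.attr("dim") = IntegerVector::create(Co, C, kh, kw);
  return out;
}
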