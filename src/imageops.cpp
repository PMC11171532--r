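// Double-precision image primitives exposed to R: bilinear warping with
// analytic gradients, Keys bicubic / nearest-neighbour resampling, and a
// separable Gaussian blur with reflecting boundaries.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export]]
NumericMatrix cpp_warp_bilinear(NumericMatrix moving, NumericMatrix u_row,
                                NumericMatrix u_col) {
  const int H = moving.nrow(), W = moving.ncol();
  NumericMatrix out(H, W);
  for (int j = 0; j < W; j++)
    for (int i = 0; i < H; i++) {
      double sr = clampd(i + u_row(i, j), 0, H - 1);
      double sc = clampd(j + u_col(i, j), 0, W - 1);
      int i0 = (int)sr; if (i0 > H - 2) i0 = H - 2;
      int j0 = (int)sc; if (j0 > W - 2) j0 = W - 2;
      const double fr = sr - i0, fc = sc - j0;
      out(i, j) = (1 - fr) * (1 - fc) * moving(i0, j0) +
                  fr * (1 - fc) * moving(i0 + 1, j0) +
                  (1 - fr) * fc * moving(i0, j0 + 1) +
                  fr * fc * moving(i0 + 1, j0 + 1);
    }
  return out;
}

// Vector-Jacobian product of the warp: given upstream d(out), returns
// gradients with respect to the moving image and both field components.
// [[Rcpp::export]]
List cpp_warp_vjp(NumericMatrix moving, NumericMatrix u_row,
                  NumericMatrix u_col, NumericMatrix upstream) {
  const int H = moving.nrow(), W = moving.ncol();
  NumericMatrix d_m(H, W), d_ur(H, W), d_uc(H, W);
  for (int j = 0; j < W; j++)
    for (int i = 0; i < H; i++) {
      const double g = upstream(i, j);
      double sr = i + u_row(i, j), sc = j + u_col(i, j);
      const bool cr = (sr <= 0 || sr >= H - 1), cc = (sc <= 0 || sc >= W - 1);
      sr = clampd(sr, 0, H - 1); sc = clampd(sc, 0, W - 1);
      int i0 = (int)sr; if (i0 > H - 2) i0 = H - 2;
      int j0 = (int)sc; if (j0 > W - 2) j0 = W - 2;
      const double fr = sr - i0, fc = sc - j0;
      const double m00 = moving(i0, j0), m10 = moving(i0 + 1, j0);
      const double m01 = moving(i0, j0 + 1), m11 = moving(i0 + 1, j0 + 1);
      d_m(i0, j0) += g * (1 - fr) * (1 - fc);
      d_m(i0 + 1, j0) += g * fr * (1 - fc);
      d_m(i0, j0 + 1) += g * (1 - fr) * fc;
      d_m(i0 + 1, j0 + 1) += g * fr * fc;
      d_ur(i, j) = cr ? 0.0 : g * ((1 - fc) * (m10 - m00) + fc * (m11 - m01));
      d_uc(i, j) = cc ? 0.0 : g * ((1 - fr) * (m01 - m00) + fr * (m11 - m10));
    }
  return List::create(Named("d_moving") = d_m, Named("d_u_row") = d_ur,
                      Named("d_u_col") = d_uc);
}

// Keys cubic kernel, a = -0.5 (the classic 4x4-neighbourhood bicubic).
static inline double keys(double x) {
  x = std::fabs(x);
  if (x < 1) return 1.5 * x * x * x - 2.5 * x * x + 1.0;
  if (x < 2) return -0.5 * x * x * x + 2.5 * x * x - 4.0 * x + 2.0;
  return 0.0;
}

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_resize_bicubic(NumericMatrix img, int out_h, int out_w) {
  const int H = img.nrow(), W = img.ncol();
  const double sy = (double)H / out_h, sx = (double)W / out_w;
  NumericMatrix out(out_h, out_w);
  std::vector<double> wy(4), wx(4);
  for (int j = 0; j < out_w; j++) {
    const double src_x = (j + 0.5) * sx - 0.5;
    const int x0 = (int)std::floor(src_x) - 1;
    for (int k = 0; k < 4; k++) wx[k] = keys(src_x - (x0 + k));
    for (int i = 0; i < out_h; i++) {
      const double src_y = (i + 0.5) * sy - 0.5;
      const int y0 = (int)std::floor(src_y) - 1;
      for (int k = 0; k < 4; k++) wy[k] = keys(src_y - (y0 + k));
      double acc = 0.0;
      for (int kx = 0; kx < 4; kx++) {
        const int jj = reflect_idx(x0 + kx, W);
        double col = 0.0;
        for (int ky = 0; ky < 4; ky++)
          col += wy[ky] * img(reflect_idx(y0 + ky, H), jj);
        acc += wx[kx] * col;
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_resize_nearest(NumericMatrix img, int out_h, int out_w) {
  const int H = img.nrow(), W = img.ncol();
  const double sy = (double)H / out_h, sx = (double)W / out_w;
  NumericMatrix out(out_h, out_w);
  for (int j = 0; j < out_w; j++) {
    int jj = (int)std::floor((j + 0.5) * sx);
    if (jj > W - 1) jj = W - 1;
    for (int i = 0; i < out_h; i++) {
      int ii = (int)std::floor((i + 0.5) * sy);
      if (ii > H - 1) ii = H - 1;
      out(i, j) = img(ii, jj);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; t++) {
    k[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += k[t + r];
  }
  for (auto& v : k) v /= s;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; j++)
    for (int i = 0; i < H; i++) {
      double acc = 0.0;
      for (int t = -r; t <= r; t++) acc += k[t + r] * img(reflect_idx(i + t, H), j);
      tmp(i, j) = acc;
    }
  for (int j = 0; j < W; j++)
    for (int i = 0; i < H; i++) {
      double acc = 0.0;
      for (int t = -r; t <= r; t++) acc += k[t + r] * tmp(i, reflect_idx(j + t, W));
      out(i, j) = acc;
    }
  return out;
}
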