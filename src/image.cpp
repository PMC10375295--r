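#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Symmetric reflection: ... c b a | a b c ... (scipy "reflect")
static inline int refl(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_conv3_reflect(NumericMatrix img, NumericMatrix kernel) {
  int nr = img.nrow(), nc = img.ncol();
  if (kernel.nrow() != 3 || kernel.ncol() != 3) stop("kernel must be 3x3");
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int dc = -1; dc <= 1; ++dc)
        for (int dr = -1; dr <= 1; ++dr)
          acc += kernel(dr + 1, dc + 1) * img(refl(r + dr, nr), refl(c + dc, nc));
      out(r, c) = acc;
    }
  return out;
}

// Brute-force bilateral filter on one channel; diameter d window, Gaussian
// range (sigma_color, on a 0..255 scale) and spatial (sigma_space) kernels.
// [[Rcpp::export]]
NumericMatrix cpp_bilateral(NumericMatrix img, int d, double sigma_color,
                            double sigma_space) {
  int nr = img.nrow(), nc = img.ncol();
  int rad = d / 2;
  double ic = -0.5 / (sigma_color * sigma_color);
  double is = -0.5 / (sigma_space * sigma_space);
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double centre = img(r, c), wsum = 0.0, vsum = 0.0;
      for (int dc = -rad; dc <= rad; ++dc)
        for (int dr = -rad; dr <= rad; ++dr) {
          double v = img(refl(r + dr, nr), refl(c + dc, nc));
          double dv = v - centre;
          double w = std::exp(is * (dr * dr + dc * dc) + ic * dv * dv);
          wsum += w;
          vsum += w * v;
        }
      out(r, c) = vsum / wsum;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= s;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) acc += k[i + rad] * img(refl(r + i, nr), c);
      tmp(r, c) = acc;
    }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) acc += k[i + rad] * tmp(r, refl(c + i, nc));
      out(r, c) = acc;
    }
  return out;
}

// Similarity warp (rotation about the image centre + translation), bilinear
// sampling with clamp-to-edge. angle in radians; positive = CCW in (row, col).
// [[Rcpp::export]]
NumericMatrix cpp_warp_similarity(NumericMatrix img, double angle, double scale,
                                  double tx, double ty) {
  int nr = img.nrow(), nc = img.ncol();
  double cr = (nr - 1) / 2.0, cc = (nc - 1) / 2.0;
  double ca = std::cos(angle) / scale, sa = std::sin(angle) / scale;
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      // inverse map: source position that lands on (r, c)
      double yr = r - cr - ty, xc = c - cc - tx;
      double sr = ca * yr - sa * xc + cr;
      double sc = sa * yr + ca * xc + cc;
      int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
      double fr = sr - r0, fc = sc - c0;
      int r0c = std::min(std::max(r0, 0), nr - 1);
      int r1c = std::min(std::max(r0 + 1, 0), nr - 1);
      int c0c = std::min(std::max(c0, 0), nc - 1);
      int c1c = std::min(std::max(c0 + 1, 0), nc - 1);
      double v00 = img(r0c, c0c), v10 = img(r1c, c0c);
      double v01 = img(r0c, c1c), v11 = img(r1c, c1c);
      out(r, c) = (1 - fr) * ((1 - fc) * v00 + fc * v01) +
                  fr * ((1 - fc) * v10 + fc * v11);
    }
  return out;
}
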