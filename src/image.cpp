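// Image primitives used by the orientation pipeline: separable Gaussian
// smoothing with reflected boundaries (circular FFT smoothing would bleed
// content across image edges and bias orientations there) and the rolling
// ball background: a grayscale opening by a ball-shaped structuring element.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;

static inline int reflect_idx(int i, int n) {
  // symmetric reflection: -1 -> 0, -2 -> 1, n -> n-1, ...
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
arma::mat sep_gauss_cpp(const arma::mat& img, double sigma) {
  if (sigma <= 0) return img;
  const int r = std::max(1, (int)std::ceil(4.0 * sigma));
  arma::vec w(2 * r + 1);
  for (int k = -r; k <= r; ++k)
    w(k + r) = std::exp(-0.5 * k * k / (sigma * sigma));
  w /= arma::accu(w);
  const int nx = img.n_rows, ny = img.n_cols;
  mat tmp(nx, ny), out(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double s = 0.0;
      for (int k = -r; k <= r; ++k) s += w(k + r) * img(reflect_idx(i + k, nx), j);
      tmp(i, j) = s;
    }
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j) {
      double s = 0.0;
      for (int k = -r; k <= r; ++k) s += w(k + r) * tmp(i, reflect_idx(j + k, ny));
      out(i, j) = s;
    }
  return out;
}

// Grayscale opening by a ball: erosion (min of img - ball) then dilation
// (max of eroded + ball).  `height` is the ball's intensity-domain height;
// offsets outside the image are skipped (clamped support).
// [[Rcpp::export]]
arma::mat ball_opening_cpp(const arma::mat& img, int radius, double height) {
  if (radius < 1) stop("ball radius must be >= 1");
  const int nx = img.n_rows, ny = img.n_cols;
  std::vector<int> di, dj;
  std::vector<double> bz;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b) {
      const double d2 = (double)(a * a + b * b);
      if (d2 <= (double)radius * radius) {
        di.push_back(a); dj.push_back(b);
        bz.push_back(height * std::sqrt(1.0 - d2 / ((double)radius * radius)));
      }
    }
  const int m = (int)di.size();
  mat ero(nx, ny), out(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double v = arma::datum::inf;
      for (int k = 0; k < m; ++k) {
        const int ii = i + di[k], jj = j + dj[k];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
        const double c = img(ii, jj) - bz[k];
        if (c < v) v = c;
      }
      ero(i, j) = v;
    }
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double v = -arma::datum::inf;
      for (int k = 0; k < m; ++k) {
        const int ii = i + di[k], jj = j + dj[k];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
        const double c = ero(ii, jj) + bz[k];
        if (c > v) v = c;
      }
      out(i, j) = v;
    }
  return out;
}
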