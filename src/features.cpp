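#include <Rcpp.h>
#include <algorithm>
#include "conv.h"
using namespace Rcpp;

#define reflect101f reflect101_idx
#define sep_blur sep_convolve_impl

static double lap_var(const NumericMatrix &m) {
  int nr = m.nrow(), nc = m.ncol();
  double s = 0.0, s2 = 0.0;
  long n = (long)nr * nc;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double v = m(reflect101f(i - 1, nr), j) + m(reflect101f(i + 1, nr), j)
               + m(i, reflect101f(j - 1, nc)) + m(i, reflect101f(j + 1, nc))
               - 4.0 * m(i, j);
      s += v; s2 += v * v;
    }
  double mu = s / n;
  return s2 / n - mu * mu;
}

// mean squared central-difference gradient magnitude over the interior
static double grad_energy(const NumericMatrix &m) {
  int nr = m.nrow(), nc = m.ncol();
  double sx = 0.0, sy = 0.0;
  for (int j = 0; j < nc; ++j)
    for (int i = 1; i < nr - 1; ++i) {
      double d = (m(i + 1, j) - m(i - 1, j)) / 2.0;
      sx += d * d;
    }
  for (int j = 1; j < nc - 1; ++j)
    for (int i = 0; i < nr; ++i) {
      double d = (m(i, j + 1) - m(i, j - 1)) / 2.0;
      sy += d * d;
    }
  return sx / ((double)(nr - 2) * nc) + sy / ((double)nr * (nc - 2));
}

static double median_of(const NumericMatrix &m) {
  std::vector<double> v(m.begin(), m.end());
  size_t n = v.size(), h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double upper = v[h];
  if (n % 2 == 1) return upper;
  std::nth_element(v.begin(), v.begin() + h - 1, v.begin() + h);
  return (v[h - 1] + upper) / 2.0;
}

static int blob_count(const NumericMatrix &m, double threshold) {
  int nr = m.nrow(), nc = m.ncol(), count = 0;
  for (int j = 1; j < nc - 1; ++j)
    for (int i = 1; i < nr - 1; ++i) {
      double v = m(i, j);
      if (v >= threshold) continue;
      if (v < m(i - 1, j) && v < m(i + 1, j) &&
          v < m(i, j - 1) && v < m(i, j + 1) &&
          v < m(i - 1, j - 1) && v < m(i - 1, j + 1) &&
          v < m(i + 1, j - 1) && v < m(i + 1, j + 1))
        ++count;
    }
  return count;
}

// The 12-component handcrafted tile descriptor; k1/k2/k4 are the normalised
// 1-D Gaussian kernels for smoothing scales 1, 2 and 4; thr1/thr2 the
// dark-blob detection depths at the two scales.
// [[Rcpp::export]]
NumericVector tile_features_cpp(NumericMatrix lum, NumericVector k1,
                                NumericVector k2, NumericVector k4,
                                double thr1, double thr2) {
  long n = (long)lum.nrow() * lum.ncol();
  double s = 0.0, s2 = 0.0;
  for (long i = 0; i < n; ++i) { s += lum[i]; s2 += lum[i] * lum[i]; }
  double mu = s / n;
  double sdv = std::sqrt((s2 - n * mu * mu) / (n - 1));

  NumericMatrix sm1 = sep_blur(lum, k1);
  NumericMatrix sm2 = sep_blur(lum, k2);
  NumericMatrix sm4 = sep_blur(lum, k4);

  double c4s = 0.0, c4s2 = 0.0;
  for (long i = 0; i < n; ++i) { c4s += sm4[i]; c4s2 += sm4[i] * sm4[i]; }
  double c4mu = c4s / n;
  double coarse = std::sqrt((c4s2 - n * c4mu * c4mu) / (n - 1));

  // 32-bin intensity histogram entropy (bits)
  std::vector<long> h(32, 0);
  for (long i = 0; i < n; ++i) {
    int b = (int)std::floor(lum[i] / 8.0);
    if (b < 0) b = 0;
    if (b > 31) b = 31;
    ++h[b];
  }
  double ent = 0.0;
  for (int b = 0; b < 32; ++b)
    if (h[b] > 0) {
      double p = (double)h[b] / n;
      ent -= p * std::log2(p);
    }

  NumericVector out = NumericVector::create(
    _["mean"] = mu, _["sd"] = sdv,
    _["lv_s0"] = lap_var(lum), _["lv_s1"] = lap_var(sm1),
    _["lv_s2"] = lap_var(sm2), _["lv_s4"] = lap_var(sm4),
    _["grad_s1"] = grad_energy(sm1), _["grad_s2"] = grad_energy(sm2),
    _["blob_s1"] = (double)blob_count(sm1, median_of(sm1) - thr1),
    _["blob_s2"] = (double)blob_count(sm2, median_of(sm2) - thr2),
    _["coarse_energy"] = coarse, _["entropy"] = ent);
  return out;
}

// Bilinear upsampling by an integer factor; sample t maps to coarse
// coordinate 1 + (t - 1) / f (1-based), clamped to the coarse grid.
// [[Rcpp::export]]
NumericMatrix upsample_bilinear_cpp(NumericMatrix coarse, int factor, int nr,
                                    int nc) {
  NumericMatrix out(nr, nc);
  int cr = coarse.nrow(), cc = coarse.ncol();
  for (int j = 0; j < nc; ++j) {
    double y = (double)j / factor;
    int j0 = (int)std::floor(y); if (j0 > cc - 2) j0 = cc - 2;
    double wy = y - j0;
    for (int i = 0; i < nr; ++i) {
      double x = (double)i / factor;
      int i0 = (int)std::floor(x); if (i0 > cr - 2) i0 = cr - 2;
      double wx = x - i0;
      out(i, j) = (1 - wx) * (1 - wy) * coarse(i0, j0)
                + wx * (1 - wy) * coarse(i0 + 1, j0)
                + (1 - wx) * wy * coarse(i0, j0 + 1)
                + wx * wy * coarse(i0 + 1, j0 + 1);
    }
  }
  return out;
}
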