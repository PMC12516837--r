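#ifndef SHARPGATE_CONV_H
#define SHARPGATE_CONV_H

#include <Rcpp.h>

inline int reflect101_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * (n - 1);
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : period - i;
}

// Separable reflect-101 convolution with a symmetric odd-length 1-D kernel.
// Interior pixels use straight pointer loops; only the border band reflects.
inline Rcpp::NumericMatrix sep_convolve_impl(const Rcpp::NumericMatrix &img,
                                             const Rcpp::NumericVector &kern) {
  int nr = img.nrow(), nc = img.ncol();
  int r = (kern.size() - 1) / 2;
  Rcpp::NumericMatrix tmp(nr, nc), out(nr, nc);
  const double *k = &kern[0];

  // vertical pass (contiguous within a column)
  for (int j = 0; j < nc; ++j) {
    const double *col = &img(0, j);
    double *dst = &tmp(0, j);
    int lo = std::min(r, nr), hi = std::max(nr - r, lo);
    for (int i = 0; i < lo; ++i) {
      double s = 0.0;
      for (int t = -r; t <= r; ++t) s += k[t + r] * col[reflect101_idx(i + t, nr)];
      dst[i] = s;
    }
    for (int i = lo; i < hi; ++i) {
      double s = 0.0;
      const double *p = col + i - r;
      for (int t = 0; t <= 2 * r; ++t) s += k[t] * p[t];
      dst[i] = s;
    }
    for (int i = hi; i < nr; ++i) {
      double s = 0.0;
      for (int t = -r; t <= r; ++t) s += k[t + r] * col[reflect101_idx(i + t, nr)];
      dst[i] = s;
    }
  }

  // horizontal pass: accumulate whole shifted columns (cache-friendly)
  for (int j = 0; j < nc; ++j) {
    double *dst = &out(0, j);
    std::fill(dst, dst + nr, 0.0);
    for (int t = -r; t <= r; ++t) {
      double w = k[t + r];
      const double *src = &tmp(0, reflect101_idx(j + t, nc));
      for (int i = 0; i < nr; ++i) dst[i] += w * src[i];
    }
  }
  return out;
}

#endif
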