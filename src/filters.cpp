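#include <Rcpp.h>
#include "conv.h"
using namespace Rcpp;

#define reflect101 reflect101_idx

// Separable convolution with a symmetric odd-length 1-D kernel, applied down
// columns then across rows, reflect-101 borders. Used for Gaussian smoothing.
// [[Rcpp::export]]
NumericMatrix sep_convolve_cpp(NumericMatrix img, NumericVector k) {
  return sep_convolve_impl(img, k);
}

// Response of the 3x3 four-neighbour Laplacian [[0,1,0],[1,-4,1],[0,1,0]],
// reflect-101 borders.
// [[Rcpp::export]]
NumericMatrix laplacian4_cpp(NumericMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      out(i, j) = img(reflect101(i - 1, nr), j) + img(reflect101(i + 1, nr), j)
                + img(i, reflect101(j - 1, nc)) + img(i, reflect101(j + 1, nc))
                - 4.0 * img(i, j);
    }
  }
  return out;
}

// Count strict 8-neighbour local minima with value below `threshold`.
// Border pixels are excluded (a planted blob centre is never on the border).
// [[Rcpp::export]]
int count_local_minima_cpp(NumericMatrix img, double threshold) {
  int nr = img.nrow(), nc = img.ncol(), count = 0;
  for (int j = 1; j < nc - 1; ++j) {
    for (int i = 1; i < nr - 1; ++i) {
      double v = img(i, j);
      if (v >= threshold) continue;
      if (v < img(i - 1, j) && v < img(i + 1, j) &&
          v < img(i, j - 1) && v < img(i, j + 1) &&
          v < img(i - 1, j - 1) && v < img(i - 1, j + 1) &&
          v < img(i + 1, j - 1) && v < img(i + 1, j + 1))
        ++count;
    }
  }
  return count;
}
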