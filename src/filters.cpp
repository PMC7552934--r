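#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Median filter with replicate (edge-clamp) padding. `window` is the odd
// edge length of the square neighbourhood.
// [[Rcpp::export(name = ".median_filter_cpp")]]
NumericMatrix median_filter_cpp(NumericMatrix img, int window) {
  if (window < 1 || window % 2 == 0)
    stop("`window` must be an odd integer >= 1");
  const int nr = img.nrow(), nc = img.ncol(), h = window / 2;
  const int m = window * window, mid = m / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(m);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int n = 0;
      for (int dj = -h; dj <= h; ++dj) {
        int jj = std::min(std::max(j + dj, 0), nc - 1);
        for (int di = -h; di <= h; ++di) {
          int ii = std::min(std::max(i + di, 0), nr - 1);
          buf[n++] = img(ii, jj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      out(i, j) = buf[mid];
    }
  }
  return out;
}

// Niblack local threshold T = m + k * sigma over a circular window of the
// given radius, clipped at image borders; sigma is the population standard
// deviation. Output is 1 where intensity > T (stroma), else 0 (lumen
// candidate). Ties (v == T) are classified 0.
//
// Window sums use per-row prefix sums so the cost per pixel is O(radius),
// not O(radius^2). For integer-valued images all partial sums are exact in
// double precision, so the result is bit-identical to a naive loop using
// the same m/sigma formulas.
// [[Rcpp::export(name = ".niblack_cpp")]]
IntegerMatrix niblack_cpp(NumericMatrix img, int radius, double k) {
  if (radius < 1) stop("`radius` must be >= 1");
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix out(nr, nc);

  // half-width of the disc at each row offset: dx such that di^2+dx^2 <= r^2
  std::vector<int> half(2 * radius + 1);
  for (int di = -radius; di <= radius; ++di)
    half[di + radius] =
        (int)std::floor(std::sqrt((double)radius * radius - (double)di * di));

  // prefix sums along columns for each row: S(i, j) = sum img(i, 0..j-1)
  std::vector<double> S((size_t)nr * (nc + 1)), SS((size_t)nr * (nc + 1));
  for (int i = 0; i < nr; ++i) {
    S[(size_t)i * (nc + 1)] = 0.0;
    SS[(size_t)i * (nc + 1)] = 0.0;
    for (int j = 0; j < nc; ++j) {
      double v = img(i, j);
      S[(size_t)i * (nc + 1) + j + 1] = S[(size_t)i * (nc + 1) + j] + v;
      SS[(size_t)i * (nc + 1) + j + 1] = SS[(size_t)i * (nc + 1) + j] + v * v;
    }
  }

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0, ss = 0.0;
      long n = 0;
      int dlo = std::max(-radius, -i), dhi = std::min(radius, nr - 1 - i);
      for (int di = dlo; di <= dhi; ++di) {
        int hw = half[di + radius];
        int jlo = std::max(j - hw, 0), jhi = std::min(j + hw, nc - 1);
        const size_t row = (size_t)(i + di) * (nc + 1);
        s += S[row + jhi + 1] - S[row + jlo];
        ss += SS[row + jhi + 1] - SS[row + jlo];
        n += jhi - jlo + 1;
      }
      double mean = s / n;
      double var = ss / n - mean * mean;
      if (var < 0) var = 0;
      double T = mean + k * std::sqrt(var);
      out(i, j) = img(i, j) > T ? 1 : 0;
    }
  }
  return out;
}
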