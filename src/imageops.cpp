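#include <Rcpp.h>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Symmetric (half-sample) reflection: -1 -> 0, n -> n-1.
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable convolution with reflective borders; `kernel` must be odd-length.
// [[Rcpp::export]]
NumericMatrix conv_sep_reflect(NumericMatrix img, NumericVector kernel) {
  int nr = img.nrow(), nc = img.ncol();
  int k = kernel.size(), h = k / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (vertical pass)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int t = -h; t <= h; ++t) s += kernel[t + h] * img(reflect(i + t, nr), j);
      tmp(i, j) = s;
    }
  // along columns (horizontal pass)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int t = -h; t <= h; ++t) s += kernel[t + h] * tmp(i, reflect(j + t, nc));
      out(i, j) = s;
    }
  return out;
}

// Grayscale erosion (take_min) / dilation over an arbitrary flat structuring
// element given as (dr, dc) offsets; reflective border handling.
// [[Rcpp::export]]
NumericMatrix morph_minmax(NumericMatrix img, IntegerVector dr, IntegerVector dc,
                           bool take_min) {
  int nr = img.nrow(), nc = img.ncol(), m = dr.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double v = take_min ? R_PosInf : R_NegInf;
      for (int t = 0; t < m; ++t) {
        double x = img(reflect(i + dr[t], nr), reflect(j + dc[t], nc));
        if (take_min) { if (x < v) v = x; } else { if (x > v) v = x; }
      }
      out(i, j) = v;
    }
  return out;
}

// Connected-component labeling; labels assigned 1..N in raster (row-major)
// order of each component's first pixel.  connectivity is 4 or 8.
// [[Rcpp::export]]
IntegerMatrix label_components(IntegerMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int *dr = connectivity == 8 ? dr8 : dr4;
  const int *dc = connectivity == 8 ? dc8 : dc4;
  int nb = connectivity == 8 ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < nr; ++i)        // raster order: rows, then columns
    for (int j = 0; j < nc; ++j) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i * nc + j);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p / nc, pj = p % nc;
        for (int t = 0; t < nb; ++t) {
          int qi = pi + dr[t], qj = pj + dc[t];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi * nc + qj);
          }
        }
      }
    }
  return lab;
}

// Expand labels into the background by Euclidean distance <= n_px.
// Ties (equal squared distance to two labels) go to the lower label.
// Existing labels are never overwritten.
// [[Rcpp::export]]
IntegerMatrix expand_labels_cpp(IntegerMatrix labels, double n_px) {
  int nr = labels.nrow(), nc = labels.ncol();
  IntegerMatrix out = clone(labels);
  if (n_px <= 0) return out;
  int n = (int) std::floor(n_px);
  double n2 = n_px * n_px;
  // offsets with 0 < dr^2+dc^2 <= n_px^2, sorted by squared distance
  std::vector<std::array<int, 3>> offs;  // (d2, dr, dc)
  for (int a = -n; a <= n; ++a)
    for (int b = -n; b <= n; ++b) {
      int d2 = a * a + b * b;
      if (d2 > 0 && (double) d2 <= n2) offs.push_back({d2, a, b});
    }
  std::sort(offs.begin(), offs.end());
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      if (labels(i, j) != 0) continue;
      int best = 0, bestd2 = -1;
      for (size_t t = 0; t < offs.size(); ++t) {
        if (bestd2 >= 0 && offs[t][0] > bestd2) break;  // past the nearest shell
        int qi = i + offs[t][1], qj = j + offs[t][2];
        if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
        int l = labels(qi, qj);
        if (l > 0) {
          if (bestd2 < 0) { bestd2 = offs[t][0]; best = l; }
          else if (l < best) best = l;
        }
      }
      if (best > 0) out(i, j) = best;
    }
  return out;
}
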