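// Small pixel-level routines with spec-pinned border/connectivity semantics:
// 3x3 median with replicated borders, 8-connected component labelling, and
// the hysteresis fill used by the Canny detector.

#include <Rcpp.h>
#include <vector>
#include <algorithm>

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_median3(Rcpp::NumericMatrix x) {
  int nr = x.nrow(), nc = x.ncol();
  Rcpp::NumericMatrix out(nr, nc);
  double buf[9];
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int t = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = std::min(std::max(j + dj, 0), nc - 1);
        for (int di = -1; di <= 1; ++di) {
          int ii = std::min(std::max(i + di, 0), nr - 1);
          buf[t++] = x(ii, jj);
        }
      }
      std::nth_element(buf, buf + 4, buf + 9);
      out(i, j) = buf[4];
    }
  }
  return out;
}

// 8-connected labelling of the non-zero pixels; labels start at 1.
// [[Rcpp::export]]
Rcpp::IntegerMatrix cpp_label8(Rcpp::IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  Rcpp::IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(j * nr + i);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int ii = pi + di, jj = pj + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (mask(ii, jj) != 0 && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              stack.push_back(jj * nr + ii);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Keep weak pixels 8-connected to a strong pixel (dual-threshold hysteresis).
// [[Rcpp::export]]
Rcpp::IntegerMatrix cpp_hysteresis(Rcpp::IntegerMatrix weak,
                                   Rcpp::IntegerMatrix strong) {
  int nr = weak.nrow(), nc = weak.ncol();
  Rcpp::IntegerMatrix out(nr, nc);
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (strong(i, j) != 0) {
        out(i, j) = 1;
        stack.push_back(j * nr + i);
      }
  while (!stack.empty()) {
    int p = stack.back();
    stack.pop_back();
    int pi = p % nr, pj = p / nr;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        int ii = pi + di, jj = pj + dj;
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        if (weak(ii, jj) != 0 && out(ii, jj) == 0) {
          out(ii, jj) = 1;
          stack.push_back(jj * nr + ii);
        }
      }
    }
  }
  return out;
}
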