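#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sum of x over a Euclidean disc of radius radius_px centred on every pixel.
// Column prefix sums + per-column-offset vertical half-widths give
// O(nrow * ncol * (2R+1)) instead of O(n * R^2). NAs must be masked to 0 by
// the caller (pair each value matrix with a 0/1 count matrix to form means).
// [[Rcpp::export]]
NumericMatrix disc_window_sum(const NumericMatrix& x, double radius_px) {
  const int nr = x.nrow(), nc = x.ncol();
  const int R = (int)std::floor(radius_px);
  if (radius_px < 0) stop("radius_px must be >= 0");
  NumericMatrix out(nr, nc);
  std::vector<double> P((size_t)(nr + 1) * nc);
  for (int j = 0; j < nc; ++j) {
    double s = 0.0;
    double* Pj = &P[(size_t)j * (nr + 1)];
    Pj[0] = 0.0;
    for (int i = 0; i < nr; ++i) {
      s += x(i, j);
      Pj[i + 1] = s;
    }
  }
  const double r2 = radius_px * radius_px;
  for (int j = 0; j < nc; ++j) {
    for (int dj = -R; dj <= R; ++dj) {
      const int jj = j + dj;
      if (jj < 0 || jj >= nc) continue;
      const int h = (int)std::floor(std::sqrt(r2 - (double)dj * dj));
      const double* Pj = &P[(size_t)jj * (nr + 1)];
      for (int i = 0; i < nr; ++i) {
        int lo = i - h; if (lo < 0) lo = 0;
        int hi = i + h + 1; if (hi > nr) hi = nr;
        out(i, j) += Pj[hi] - Pj[lo];
      }
    }
  }
  return out;
}

// Connected-component labeling of a logical matrix, 8- or 4-connectivity.
// Labels are assigned 1..n in column-major first-encounter order.
// [[Rcpp::export]]
IntegerMatrix cc_label(const LogicalMatrix& mask, bool eight = true) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  static const int di8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dj8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int di4[4] = {-1, 1, 0, 0};
  static const int dj4[4] = {0, 0, -1, 1};
  const int ndir = eight ? 8 : 4;
  const int* DI = eight ? di8 : di4;
  const int* DJ = eight ? dj8 : dj4;
  std::vector<int> stack;
  int cur = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++cur;
      lab(i, j) = cur;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pi = p % nr, pj = p / nr;
        for (int d = 0; d < ndir; ++d) {
          const int qi = pi + DI[d], qj = pj + DJ[d];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && !lab(qi, qj)) {
            lab(qi, qj) = cur;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  lab.attr("n") = cur;
  return lab;
}

// Nearest-class-mean assignment for refinement pixels.
// refine: 1 where the pixel must be (re)assigned; sum_t/cnt_t and sum_s/cnt_s
// are disc-window sums/counts of the provisional tree and soil classes.
// Returns 1 (tree) / 0 (soil); ties go to soil; empty soil window -> tree,
// empty tree window -> soil.
// [[Rcpp::export]]
IntegerMatrix nearest_mean_assign(const NumericMatrix& dsm,
                                  const LogicalMatrix& refine,
                                  const NumericMatrix& sum_t,
                                  const NumericMatrix& cnt_t,
                                  const NumericMatrix& sum_s,
                                  const NumericMatrix& cnt_s) {
  const int nr = dsm.nrow(), nc = dsm.ncol();
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!refine(i, j)) { out(i, j) = NA_INTEGER; continue; }
      const double ct = cnt_t(i, j), cs = cnt_s(i, j);
      if (ct <= 0 && cs <= 0) { out(i, j) = 0; continue; }
      if (ct <= 0) { out(i, j) = 0; continue; }
      if (cs <= 0) { out(i, j) = 1; continue; }
      const double z = dsm(i, j);
      const double mt = sum_t(i, j) / ct, ms = sum_s(i, j) / cs;
      out(i, j) = (std::fabs(z - mt) < std::fabs(z - ms)) ? 1 : 0;
    }
  }
  return out;
}
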