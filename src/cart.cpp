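#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exhaustive CART split scan over all features and all midpoints between
// consecutive distinct sorted values, restricted to the rows in `idx`
// (1-based). criterion: 0 = SSE (regression, impurity = sum of squared
// deviations from the node mean), 1 = Gini (two-class, y in {0,1},
// impurity = 1 - sum p_k^2; children weighted by size). A candidate is
// admissible when both children hold at least `min_leaf` rows. Features
// are scanned in column order and thresholds ascending; a candidate must
// beat the incumbent by more than a tie tolerance proportional to the
// parent impurity, so mathematically tied gains (whose floating-point
// evaluations may differ in the last bits) resolve to the lower feature
// index, then the lower threshold.
// [[Rcpp::export]]
List cpp_best_split(const NumericMatrix& X, const IntegerVector& idx,
                    const NumericVector& y, int criterion, int min_leaf) {
  const int n = idx.size();
  const int p = X.ncol();

  std::vector<double> yv(n);
  for (int i = 0; i < n; ++i) yv[i] = y[idx[i] - 1];

  double parent_imp;
  double sum_y = 0.0, sum_y2 = 0.0, n1 = 0.0;
  for (int i = 0; i < n; ++i) {
    sum_y += yv[i];
    sum_y2 += yv[i] * yv[i];
    if (yv[i] == 1.0) n1 += 1.0;
  }
  if (criterion == 0) {
    parent_imp = sum_y2 - sum_y * sum_y / n;
  } else {
    double p1 = n1 / n, p0 = 1.0 - p1;
    parent_imp = 1.0 - (p0 * p0 + p1 * p1);
  }

  bool found = false;
  int best_feat = -1;
  double best_thr = 0.0, best_gain = R_NegInf;
  const double tie_tol = 1e-9 * (std::abs(parent_imp) + 1.0);

  std::vector<int> ord(n);
  std::vector<double> xv(n), ys(n);

  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) xv[i] = X(idx[i] - 1, j);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return xv[a] < xv[b]; });
    // left-to-right cumulative sums in sorted order
    double cl_sum = 0.0, cl_sum2 = 0.0, cl_n1 = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      const double yi = yv[ord[i]];
      cl_sum += yi;
      cl_sum2 += yi * yi;
      if (yi == 1.0) cl_n1 += 1.0;
      const double xlo = xv[ord[i]], xhi = xv[ord[i + 1]];
      if (!(xlo < xhi)) continue; // not a distinct-value boundary
      const int nl = i + 1, nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      double child;
      if (criterion == 0) {
        const double sse_l = cl_sum2 - cl_sum * cl_sum / nl;
        const double sr = sum_y - cl_sum, sr2 = sum_y2 - cl_sum2;
        const double sse_r = sr2 - sr * sr / nr;
        child = sse_l + sse_r;
      } else {
        const double pl1 = cl_n1 / nl, pl0 = 1.0 - pl1;
        const double pr1 = (n1 - cl_n1) / nr, pr0 = 1.0 - pr1;
        const double gl = 1.0 - (pl0 * pl0 + pl1 * pl1);
        const double gr = 1.0 - (pr0 * pr0 + pr1 * pr1);
        child = ((double)nl * gl + (double)nr * gr) / n;
      }
      const double gain = parent_imp - child;
      if (gain > best_gain + (found ? tie_tol : 0.0)) {
        best_gain = gain;
        best_feat = j + 1;
        best_thr = (xlo + xhi) / 2.0;
        found = true;
      }
    }
  }

  return List::create(_["found"] = found, _["feature"] = best_feat,
                      _["threshold"] = best_thr, _["gain"] = best_gain,
                      _["impurity"] = parent_imp);
}
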