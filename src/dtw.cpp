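#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Classical dynamic-time-warping distance between two univariate sequences
// with absolute-difference local cost and unit steps {match, insert, delete}.
// band < 0 disables the Sakoe-Chiba constraint; otherwise cells with
// |i - j| > band (after slope correction for unequal lengths) are skipped.
// Two rolling rows keep memory at O(min length).
// [[Rcpp::export]]
double dtw_cost_cpp(NumericVector a, NumericVector b, int band) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0)
    stop("dtw: sequences must be non-empty");
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<double> prev(m + 1, INF), cur(m + 1, INF);
  prev[0] = 0.0;
  // slope-corrected band so the diagonal of a rectangular grid stays feasible
  const double slope = (n > 1 && m > 1) ? (double)(m - 1) / (double)(n - 1) : 0.0;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    int jlo = 1, jhi = m;
    if (band >= 0) {
      double center = (n > 1) ? 1.0 + slope * (i - 1) : 1.0;
      jlo = std::max(1, (int)std::ceil(center - band));
      jhi = std::min(m, (int)std::floor(center + band));
      if (jlo > jhi) { jlo = 1; jhi = m; } // degenerate band: fall back
    }
    for (int j = jlo; j <= jhi; ++j) {
      double cost = std::fabs(a[i - 1] - b[j - 1]);
      double best = prev[j - 1];            // match
      if (prev[j] < best) best = prev[j];   // delete
      if (cur[j - 1] < best) best = cur[j - 1]; // insert
      cur[j] = cost + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
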