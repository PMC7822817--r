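#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Victor-Purpura spike-train edit distance: minimal cost to transform one
// train into the other with insertion/deletion cost 1 per spike and shift
// cost q * |dt|. Standard O(n*m) dynamic program over the two sorted trains.

// [[Rcpp::export]]
double cpp_vp_distance(NumericVector t1, NumericVector t2, double q) {
  const int n = t1.size(), m = t2.size();
  if (q < 0) stop("q must be non-negative");
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;  // insert all of t2
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;                              // delete all of t1
    for (int j = 1; j <= m; ++j) {
      const double shift = prev[j - 1] + q * std::fabs(t1[i - 1] - t2[j - 1]);
      cur[j] = std::min(shift, std::min(prev[j], cur[j - 1]) + 1.0);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
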