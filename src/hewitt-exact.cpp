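#include <Rcpp.h>
#include <algorithm>

// Exact null distribution of the maximum circular 6-month rank sum.
// The statistic is invariant under rotation of the 12 months, so the
// 12! permutations fall into rotation classes of size 12; pinning the
// value 12 to position 1 picks one representative per class, leaving
// 11! = 39,916,800 arrangements to enumerate.
//
// Returns counts of T = 40..57 over the 11! representatives.
// [[Rcpp::export]]
Rcpp::NumericVector hewitt_exact_counts() {
  int vals[11] = {1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11};
  double counts[18] = {0};
  int p[12];
  p[0] = 12;
  do {
    for (int i = 0; i < 11; ++i) p[i + 1] = vals[i];
    int w = p[0] + p[1] + p[2] + p[3] + p[4] + p[5];
    int T = w;
    for (int k = 0; k < 11; ++k) {
      w += p[(k + 6) % 12] - p[k];
      if (w > T) T = w;
    }
    counts[T - 40] += 1.0;
  } while (std::next_permutation(vals, vals + 11));
  return Rcpp::NumericVector(counts, counts + 18);
}
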