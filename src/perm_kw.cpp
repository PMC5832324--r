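#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo engine for the permutation Kruskal-Wallis test. Given the
// mid-ranks of the pooled sample, counts permutations whose statistic
// T* = sum_i (group rank sum)^2 / n_i reaches the observed T. T is a
// strictly increasing transform of the tie-corrected H for fixed ranks,
// so the count equals #{H* >= H_obs}. Uses R's RNG so set.seed() in R
// governs reproducibility.
// [[Rcpp::export]]
int perm_kw_count(NumericVector ranks, IntegerVector sizes, int B,
                  double t_obs) {
  int N = ranks.size();
  int k = sizes.size();
  std::vector<double> work(ranks.begin(), ranks.end());
  int count = 0;
  RNGScope scope;
  for (int b = 0; b < B; ++b) {
    // Fisher-Yates shuffle
    for (int i = N - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(work[i], work[j]);
    }
    double t = 0.0;
    int pos = 0;
    for (int g = 0; g < k; ++g) {
      double s = 0.0;
      for (int m = 0; m < sizes[g]; ++m) s += work[pos++];
      t += s * s / sizes[g];
    }
    if (t >= t_obs - 1e-9) ++count;
  }
  return count;
}
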