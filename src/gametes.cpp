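#include <Rcpp.h>
using namespace Rcpp;

// One recombinant gamete per offspring. Each offspring copies, per locus,
// one of the two parental haplotypes; the choice follows a Markov switch
// process along each chromosome with switch probability equal to the
// recombination fraction to the previous locus (0.5 = independent).
// [[Rcpp::export]]
IntegerMatrix draw_gametes_cpp(IntegerMatrix hap1, IntegerMatrix hap2,
                               IntegerVector parent_idx,
                               LogicalVector new_chrom,
                               NumericVector recomb) {
  const int n = parent_idx.size();
  const int L = hap1.ncol();
  IntegerMatrix out(n, L);
  std::vector<char> state(n);
  for (int l = 0; l < L; ++l) {
    if (new_chrom[l]) {
      for (int i = 0; i < n; ++i) state[i] = unif_rand() < 0.5;
    } else {
      double r = recomb[l];
      if (r >= 0.5) {
        for (int i = 0; i < n; ++i) state[i] = unif_rand() < 0.5;
      } else if (r > 0) {
        for (int i = 0; i < n; ++i)
          if (unif_rand() < r) state[i] = !state[i];
      }
    }
    for (int i = 0; i < n; ++i) {
      int p = parent_idx[i] - 1;
      out(i, l) = state[i] ? hap1(p, l) : hap2(p, l);
    }
  }
  return out;
}
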