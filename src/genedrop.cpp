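#include <Rcpp.h>
using namespace Rcpp;

// Monte Carlo gene drop through a pedigree, accumulating per-label marginal
// count histograms over the tested haplotype pool.
//
// All indices are 0-based on the C++ side. Individuals with fixedA[i] > 0
// carry a fixed label pair (founders, and individuals with both parents
// unknown, which carry the pooled unknown label twice). Every other
// individual receives, per known parent, one of that parent's two current
// labels with probability 1/2; an unknown parent contributes the unknown
// label deterministically. Uses R's RNG, so results are reproducible with
// set.seed() on the R side.
//
// ord      : pedigree indices in topological (parents-first) order
// sire,dam : parent index or -1 when unknown
// fixedA/B : fixed label pair, or -1 for simulated individuals
// subset   : indices of the tested individuals
// K1       : number of labels including the unknown label (K + 1)
// [[Rcpp::export]]
List cpp_simulate_null(IntegerVector ord, IntegerVector sire, IntegerVector dam,
                       IntegerVector fixedA, IntegerVector fixedB,
                       int unknown_label, IntegerVector subset,
                       int K1, int n_iter, bool keep_samples) {
  const int n_ind = sire.size();
  const int n_sub = subset.size();
  const int n_hap = 2 * n_sub;
  IntegerMatrix marginal(K1, n_hap + 1);
  IntegerMatrix samples(keep_samples ? n_iter : 0, keep_samples ? K1 : 0);
  std::vector<int> A(n_ind), B(n_ind), cnt(K1);
  RNGScope scope;

  for (int it = 0; it < n_iter; ++it) {
    for (int oi = 0; oi < n_ind; ++oi) {
      const int i = ord[oi];
      if (fixedA[i] > 0) {
        A[i] = fixedA[i];
        B[i] = fixedB[i];
        continue;
      }
      const int s = sire[i], d = dam[i];
      A[i] = (s < 0) ? unknown_label : (unif_rand() < 0.5 ? A[s] : B[s]);
      B[i] = (d < 0) ? unknown_label : (unif_rand() < 0.5 ? A[d] : B[d]);
    }
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int u = 0; u < n_sub; ++u) {
      ++cnt[A[subset[u]] - 1];
      ++cnt[B[subset[u]] - 1];
    }
    for (int k = 0; k < K1; ++k) {
      ++marginal(k, cnt[k]);
      if (keep_samples) samples(it, k) = cnt[k];
    }
  }
  return List::create(_["marginal"] = marginal, _["samples"] = samples);
}

// Recombination-aware genome drop: each meiosis transmits a crossover mosaic
// of the parent's two label sequences. rec[l] is the recombination fraction
// between locus l-1 and locus l (rec[0] is ignored; a value of 0.5 makes loci
// independent, as across chromosome boundaries). Accumulates one marginal
// histogram per locus; per-locus marginals match the unlinked drop.
// [[Rcpp::export]]
IntegerVector cpp_simulate_null_linked(IntegerVector ord, IntegerVector sire,
                                       IntegerVector dam,
                                       IntegerVector fixedA, IntegerVector fixedB,
                                       int unknown_label, IntegerVector subset,
                                       int K1, int n_iter, NumericVector rec) {
  const int n_ind = sire.size();
  const int n_sub = subset.size();
  const int n_hap = 2 * n_sub;
  const int L = rec.size();
  // marginal[k + K1 * (c + (n_hap+1) * l)]
  IntegerVector marginal(Dimension(K1, n_hap + 1, L));
  std::vector<std::vector<int> > A(n_ind, std::vector<int>(L)),
      B(n_ind, std::vector<int>(L));
  std::vector<int> cnt(K1);
  RNGScope scope;

  for (int it = 0; it < n_iter; ++it) {
    for (int oi = 0; oi < n_ind; ++oi) {
      const int i = ord[oi];
      if (fixedA[i] > 0) {
        std::fill(A[i].begin(), A[i].end(), fixedA[i]);
        std::fill(B[i].begin(), B[i].end(), fixedB[i]);
        continue;
      }
      for (int g = 0; g < 2; ++g) {
        const int p = g == 0 ? sire[i] : dam[i];
        std::vector<int> &tgt = g == 0 ? A[i] : B[i];
        if (p < 0) {
          std::fill(tgt.begin(), tgt.end(), unknown_label);
          continue;
        }
        bool from_a = unif_rand() < 0.5;
        for (int l = 0; l < L; ++l) {
          if (l > 0 && unif_rand() < rec[l]) from_a = !from_a;
          tgt[l] = from_a ? A[p][l] : B[p][l];
        }
      }
    }
    for (int l = 0; l < L; ++l) {
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int u = 0; u < n_sub; ++u) {
        ++cnt[A[subset[u]][l] - 1];
        ++cnt[B[subset[u]][l] - 1];
      }
      for (int k = 0; k < K1; ++k)
        ++marginal[k + K1 * (cnt[k] + (n_hap + 1) * l)];
    }
  }
  return marginal;
}
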