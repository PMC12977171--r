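---
title: "Detecting founder-haplotype frequency bias by gene-drop simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting founder-haplotype frequency bias by gene-drop simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Breeding programmes for perennial fruit crops (apple being the motivating
case) rely on a handful of founder cultivars whose haplotypes spread through
a documented, multi-generation pedigree. When phased SNP genotypes of the
descendants can be traced back to labelled founder haplotypes, the observed
frequency of each founder haplotype at each locus can be compared with what
random Mendelian inheritance through that same pedigree would produce.
Local deviations are signatures of selection — intentional (a breeder
favouring a sweetness allele) or inadvertent (hitchhiking, regional
adaptation) — and, unlike GWAS-based scans, the comparison needs no
phenotypes at all.

`haplodrop` implements the full workflow: pedigree validation and
generation layering, Monte Carlo gene-drop simulation of the null,
empirical per-SNP tests, generation-wise analyses and frequency
trajectories, BayesB estimation of founder-haplotype effects for markers
near trait loci, and concordance of biased regions with GWAS peaks and gene
annotations. A synthetic-data module generates all inputs so every stage is
testable end to end.

## The null model

Each individual carries two haplotype labels per locus. Founder `i` (of
`F` founders, in file order) carries the fixed pair `(2i - 1, 2i)`; with 7
founders, labels run 1–14 and label 15 is the pooled label for haplotypes
of unknown origin (an undocumented parent transmits label 15
deterministically; an individual with two undocumented parents carries
`(15, 15)`). A single gene drop propagates labels through the pedigree in
topological order: every known parent transmits one of its two current
labels with probability 1/2, independently at each meiosis.

Repeating the drop `N` times and counting labels over the `n = 2s`
haplotypes of the `s` tested individuals yields the empirical null: for
each label `k`, a histogram of its count `x_k` across iterations. The count
vector is multinomial-like — `sum_k x_k = n` always — but its cell
probabilities are induced by the pedigree, not exchangeable, which is why
they are estimated by simulation rather than written down. For small
pedigrees (`m` meioses, `2^m` outcomes) `exact_null_small()` enumerates the
null exactly and serves as the test oracle; `expected_contribution()` gives
the exact mean by the recursion `e(i) = (e(sire) + e(dam)) / 2`, which the
simulated mean must reproduce.

Because the per-meiosis rule is identical at every locus, the unlinked null
does not depend on the locus: one simulation per tested subset serves all
SNPs, making genome-wide testing O(1) simulations instead of O(#SNPs). A
recombination-aware variant (`drop_genome_linked()`,
`simulate_null_linked()`) transmits crossover mosaics using the Haldane map
function `r = (1 - e^{-2d})/2`; its per-locus marginals coincide with the
unlinked null (a tested invariant), so it matters only for joint statistics
across loci, e.g. max-statistic family-wise nulls. Haldane was chosen over
Kosambi as the simplest standard map function; nothing downstream depends
on the choice.

## The p-value

The p-value of an observed count is its *difficulty of occurrence* under
the simulated null: the total null mass of counts no more probable than the
observed one, estimated with the pseudo-count correction `(r + 1)/(N + 1)`
so that p is never 0 and never smaller than `1/(N + 1)`. This
likelihood-ordered two-sided convention is the package default
(`alternative = "occurrence"`). The more familiar doubled convention
(`2 min(p_up, p_low)`, ties counted in both tails) and one-sided modes are
available; on the discrete, sometimes strongly skewed count supports that
pedigrees produce, doubling is noticeably conservative (its realized level
at nominal 0.05 falls around 0.03 under the default synthetic conditions,
versus about 0.045 for the occurrence convention), which is why it is not
the default. The reported direction is the sign of the deviation from the
null mean.

A locus–label pair is declared significant when `-log10(p)` exceeds the
threshold, default 4. No further multiplicity correction is applied — the
fixed threshold *is* the genome-wide rule — and the pseudo-count floor
implies a minimum iteration count: with `N = 1e5`, the smallest achievable
p is about `1e-5`, so the `1e-4` threshold is resolvable; with `N = 1e3` it
is not, and `iteration_stability()` makes such resolution limits visible by
tracking the significant-SNP set across an ascending iteration grid. The
package default is `N = 1e6`; in our synthetic checks detection is stable
from `1e5` onwards, mirroring the diminishing returns beyond a few hundred
thousand iterations.

Counting at a locus skips missing labels. When missingness changes the
haplotype pool size away from the null's `n`, the locus is flagged
(`p = NA`) by default; `resimulate = TRUE` instead re-runs the null on that
locus's complete-data individuals. Individuals missing one label of a pair
at a locus are dropped entirely at that locus, keeping the pool an even
number of haplotypes from whole individuals.

## Generations

Founders are generation 1; every other individual is one more than the
maximum generation of its known parents (a node with a single known parent
is placed by that lineage). `assign_generations()` also accepts a
`merge_spec` such as `c("6" = 5)` to pool a sparse late layer into its
predecessor. `test_by_generation()` repeats the bias test with the tested
subset restricted to one generation at a time — separate null per subset —
which can expose shifts that happened early and were diluted later.
Generation 1 is deterministic (founders carry fixed labels), so its
p-values are identically 1; it is tested only for completeness. The
whole-population test includes founders by default, matching the idea of
testing the entire genotyped population; `subset = "nonfounders"` is
available.

## Haplotype effects (BayesB)

For markers of interest, the genotypic value is modelled as
`u_i = sum_j gamma_j sum_l (x_ijl + x'_ijl) beta_jl`, where `x`/`x'` are
maternal/paternal one-hot indicators of the founder haplotype at marker `j`
(dosages sum to 2 per marker per individual, a tested design invariant),
`gamma_j` is a per-marker inclusion indicator, and the effects at marker
`j` share a marker-specific variance `sigma2_beta_j`. Priors:
`gamma_j ~ Bernoulli(pi_incl)` with `pi_incl = 0.05`;
`beta_jl | sigma2_beta_j ~ N(0, sigma2_beta_j)`;
`sigma2_beta_j ~` scaled-inv-chi-square with `nu = 4.2` and a scale set
from the phenotypic variance (an expected-R² = 0.5 heuristic spread over
the expected number of included contrasts); Gaussian residual with a
weakly informative scaled-inv-chi-square prior. The sampler is Gibbs with
the indicator drawn from its conditional with the marker's effects
integrated out (conditional on `sigma2_beta_j`), then effects from their
multivariate-normal conditional and variances from their conjugate
posteriors — the classical BayesB construction. Chain defaults are 10 000
iterations, 2 000 burn-in, thinning 10; none of these values is dictated
by the underlying method, so they follow common practice in the BayesB
literature, and all are arguments.

Two reporting conventions coexist: `post_mean` is the effect posterior mean
*conditional on inclusion* (used with `gamma` in `genotypic_values()`), and
`effective` is the unconditional `E[gamma * beta]` (the shrunken effect,
used for consistency classification). Because dosages at a marker sum to
two, a constant shift of all effects at one marker is absorbed by the
intercept; the prior centres effects at zero, so estimates are identified
as contrasts and should be read relative to each other within a marker.
Phenotypes are per-cultivar means across years; year effects are out of
scope. The joint regression drops individuals missing at any fitted marker
(per-marker masks are kept in the design for transparency).

`classify_consistency()` combines three signs: the direction of a
haplotype's frequency change, the sign of its estimated effect, and the
generational trend of the trait (OLS slope of generation means on
generation index, t-test at 0.05 — the simplest defensible reading of a
"generational trend"). Frequency-up × positive-effect × trait-up is
`consistent`; a non-significant trend is `no-trend`; the remaining sign
pattern is `inconsistent`.

## Synthetic data: what it emulates, and what it does not

`generate_pedigree()` builds a layered breeding pedigree: founders in
generation 1, later matings pairing a previous-layer parent with a parent
from any earlier layer, both drawn with gamma-distributed per-individual
popularity weights (`popularity_skew = 1.5` by default) so a few elite
parents are reused disproportionately — the "Fuji effect" that makes
contribution-driven frequency inflation look like selection unless the
null accounts for pedigree structure, which is exactly what the gene drop
does. Defaults (7 founders, 5 generations, 12 matings × 4 offspring per
round, 199 individuals, 500 loci on 5 chromosomes, no missing data) are a
reduced-scale analogue of a real apple panel (185 cultivars, ~12k SNPs, 7
founders); reduced loci counts keep the full pipeline and its tests within
desk-scale runtimes, and are stated per test where they differ.

Selection is modelled as transmission distortion at chosen loci:
in `gametic` mode a heterozygous carrier parent transmits the favoured
label with probability `k` instead of 1/2 (`k = 0.5` neutral, `k = 1`
deterministic) — acting exactly where the null's 1/2 rule acts, which
makes power analytically tractable; `viability` mode instead resamples
non-carrier offspring with acceptance probability `2(1 - k)`. Power
scenarios favour the most common segregating label (by
`expected_contribution`), since selection on an almost-absent haplotype is
both unrealistic and undetectable. Phenotypes are dosage-weighted sums of
chosen true effects plus Gaussian noise scaled to a target heritability.

The generator reproduces pedigree structure, label bookkeeping,
missingness, distortion, and effect-based phenotypes. It does *not*
simulate sequence-level variation, genotyping error, phasing error in the
upstream founder-label assignment, year-by-environment phenotype
structure, or linkage disequilibrium between loci (loci are dropped
independently unless the linked drop is used). Passing tests therefore
validate the statistical machinery under clean label assignments; they do
not quantify robustness to upstream assignment error.

## Numerical and design notes

* All randomness flows through R's RNG (`set.seed`), including the C++
  drop kernel via `unif_rand`; identical seed, pedigree, subset and
  iteration count give bit-identical nulls. Simulations run
  single-threaded, so one stream suffices for exact reproducibility.
* The unknown label (15) is tested like any other label; with a fully
  documented pedigree it never segregates, its null is a point mass, and
  its p-value is identically 1 — harmless, and informative when
  undocumented parents do occur.
* Degenerate cases handled explicitly: empty tested subsets, point-mass
  nulls (p = 1), constant phenotypes (effects shrink to ~0), markers with
  a single observed label (excluded from designs with a warning),
  generations with fewer than two members (skipped with a warning), and
  merge specifications naming absent layers (error).
* `exact_null_small()` refuses pedigrees beyond `max_meioses` (default
  20, i.e. about a million enumerated outcomes) and directs the caller to
  the simulator.
* Coordinates are 1-based inclusive everywhere (GFF3 convention); gene
  containment includes both interval boundaries. GWAS-peak matching
  defaults to exact SNP identity (`window = 0`), since peak-overlap is
  most defensibly read as marker identity; a bp window is available.
* Iteration-grid stability is summarized by Jaccard similarity to the
  largest count plus the smallest count whose significant set equals the
  largest's.

## Scale of the shipped checks

The package's own acceptance checks run, on one CPU in a few minutes:
exact-vs-simulated total-variation checks at `1e5` iterations on
enumerable pedigrees; analytic-mean agreement at `1e5` iterations on a
~100-individual pedigree; neutral calibration on 500 loci × 15 labels;
power at `k = 0.9` over 50 replicates (detection well above 90% with
off-target hits at the type-I expectation); grid stability over
`{1e4, 1e5, 1e6}`; BayesB recovery over 10 replicates (causal marker
ranked first, effect correlation above 0.8); and brute-force oracles for
the interval machinery. These sizes are the package's chosen test
conditions, not limits of the method; the same functions run unchanged at
`1e7` iterations or tens of thousands of SNPs.
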