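# Shared fixtures, built in code. The default synthetic bundle (pedigree,
# scheme, 1e5-iteration null) is expensive enough to share across tests;
# it is memoised in this environment.

.fx <- new.env(parent = emptyenv())

# trio: two founders and one child
trio_pedigree <- function() {
  pedigree(c("F1", "F2", "C"), c(NA, NA, "F1"), c(NA, NA, "F2"))
}

# chain: F1 x F2 -> C1, C1 x F3 -> C2 (4 meioses)
chain_pedigree <- function() {
  pedigree(c("F1", "F2", "F3", "C1", "C2"),
           c(NA, NA, NA, "F1", "C1"),
           c(NA, NA, NA, "F2", "F3"))
}

# three generations, 6 meioses: C1, C2 children of F1 x F2; G child of C1 x C2
sib_pedigree <- function() {
  pedigree(c("F1", "F2", "C1", "C2", "G"),
           c(NA, NA, "F1", "F1", "C1"),
           c(NA, NA, "F2", "F2", "C2"))
}

# default synthetic study conditions: 7 founders, 5 generations, 199
# individuals (see synth_config defaults)
default_bundle <- function() {
  if (is.null(.fx$bundle)) {
    cfg <- synth_config()
    ped <- generate_pedigree(cfg)
    scheme <- founder_label_scheme(ped)
    .fx$bundle <- list(cfg = cfg, ped = ped, scheme = scheme)
  }
  .fx$bundle
}

# shared 1e5-iteration whole-population null on the default pedigree
default_null <- function() {
  if (is.null(.fx$null)) {
    b <- default_bundle()
    .fx$null <- simulate_null(b$ped, b$scheme, "all", 1e5, seed = 3)
  }
  .fx$null
}

# the favoured label for selection scenarios: the most common segregating
# founder haplotype by analytic expected contribution (selection can only
# act on haplotypes actually present in the population)
favored_label <- function() {
  if (is.null(.fx$fav)) {
    b <- default_bundle()
    ec <- vapply(seq_len(b$scheme$K), function(k)
      expected_contribution(b$ped, b$scheme, k, "all"), numeric(1))
    .fx$fav <- which.max(ec)
  }
  .fx$fav
}

# tiny 1-locus haplotype matrix built directly
tiny_matrix <- function(ids, a, b, K = 14L) {
  hap_matrix(data.frame(chrom = "chr1", pos = 100L, snp_id = "s1"),
             ids, matrix(a, ncol = 1L), matrix(b, ncol = 1L), K = K)
}
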