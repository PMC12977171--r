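Package: haplodrop
Title: Gene-Drop Simulation to Detect Founder-Haplotype Frequency Bias in
    Breeding Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pedigree-based Monte Carlo gene-drop simulation for structured
    breeding populations with labelled founder haplotypes. Builds empirical
    null distributions of founder-haplotype counts under Mendelian (1/2 per
    meiosis) transmission, tests observed SNP-wise haplotype frequencies for
    bias with pseudo-count Monte Carlo p-values, analyses each breeding
    generation separately, estimates founder-haplotype effects at markers with
    a BayesB Markov chain Monte Carlo sampler, checks concordance of biased
    regions with GWAS peaks and gene annotations, and generates synthetic
    pedigrees, haplotype matrices, and phenotypes (with optional transmission
    distortion emulating breeder selection) for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    data.table,
    jsonlite,
    yaml,
    Rcpp,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
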