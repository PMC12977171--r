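# Independent brute-force oracles used to cross-check the interval and
# peak-matching code paths.

brute_force_overlap <- function(snps, genes) {
  hits <- list()
  for (i in seq_len(nrow(snps))) {
    for (j in seq_len(nrow(genes))) {
      if (snps$chrom[i] == genes$chrom[j] &&
          snps$pos[i] >= genes$start[j] && snps$pos[i] <= genes$end[j])
        hits[[length(hits) + 1L]] <- paste(snps$snp_id[i], genes$gene_id[j])
    }
  }
  sort(unlist(hits))
}

brute_force_peaks <- function(bias, peaks, window) {
  want <- character(0)
  for (i in seq_len(nrow(bias))) {
    for (j in seq_len(nrow(peaks))) {
      id_hit <- !is.null(peaks$snp_id) &&
        bias$snp_id[i] == peaks$snp_id[j]
      xy_hit <- !is.null(peaks$pos) &&
        bias$chrom[i] == peaks$chrom[j] &&
        abs(bias$pos[i] - peaks$pos[j]) <= window
      if (id_hit || xy_hit)
        want <- c(want, paste(bias$snp_id[i], peaks$trait[j],
                              peaks$snp_id[j]))
    }
  }
  sort(unique(want))
}

random_fixture <- function(seed, n_snps = 100, n_genes = 20) {
  set.seed(seed)
  snps <- data.frame(snp_id = sprintf("s%03d", seq_len(n_snps)),
                     chrom = sample(c("chr1", "chr2"), n_snps, TRUE),
                     pos = sample.int(10000, n_snps, replace = TRUE))
  st <- sample.int(9500, n_genes, replace = TRUE)
  genes <- data.frame(gene_id = sprintf("g%02d", seq_len(n_genes)),
                      chrom = sample(c("chr1", "chr2"), n_genes, TRUE),
                      start = st, end = st + sample.int(800, n_genes, TRUE),
                      strand = "+")
  list(snps = snps, genes = genes)
}
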