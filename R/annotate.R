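# Intersect significant bias SNPs with GWAS peaks and gene intervals, and
# assemble candidate gene lists for external enrichment tools.

#' Match biased SNPs against GWAS peaks
#'
#' Exact SNP-ID matches are always included (distance 0); when the peak
#' table carries coordinates, peaks within `window` bp of a biased SNP on
#' the same chromosome are also matched, with their distance. A biased SNP
#' may match peaks for several traits.
#'
#' @param bias data.frame from [test_bias()] (typically filtered to
#'   `significant` rows).
#' @param peaks data.frame from [read_gwas_peaks()].
#' @param window matching window in bp (default 0 = exact identity only).
#' @return data.frame with columns `snp_id`, `chrom`, `pos`, `label`,
#'   `direction`, `trait`, `peak_snp_id`, `distance`.
#' @export
match_gwas_peaks <- function(bias, peaks, window = 0) {
  if (window < 0) stop("window must be >= 0")
  snps <- unique(bias[, intersect(c("snp_id", "chrom", "pos", "label",
                                    "direction"), names(bias))])
  empty <- data.frame(snp_id = character(0), chrom = character(0),
                      pos = integer(0), label = integer(0),
                      direction = character(0), trait = character(0),
                      peak_snp_id = character(0), distance = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(snps) || !nrow(peaks)) return(empty)
  out <- list()
  has_id <- "snp_id" %in% names(peaks)
  has_xy <- all(c("chrom", "pos") %in% names(peaks))
  for (r in seq_len(nrow(peaks))) {
    hit <- rep(FALSE, nrow(snps))
    dist <- rep(NA_integer_, nrow(snps))
    if (has_id && !is.na(peaks$snp_id[r])) {
      hit <- snps$snp_id == peaks$snp_id[r]
      dist[hit] <- 0L
    }
    if (has_xy && !is.na(peaks$pos[r])) {
      d <- ifelse(snps$chrom == peaks$chrom[r],
                  abs(snps$pos - peaks$pos[r]), NA_integer_)
      near <- !is.na(d) & d <= window
      dist[near & !hit] <- d[near & !hit]
      hit <- hit | near
    }
    if (any(hit))
      out[[length(out) + 1L]] <- data.frame(
        snps[hit, c("snp_id", "chrom", "pos",
                    intersect(c("label", "direction"), names(snps)))],
        trait = peaks$trait[r],
        peak_snp_id = if (has_id) peaks$snp_id[r] else NA_character_,
        distance = dist[hit], stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$snp_id, res$trait), , drop = FALSE]
}

#' SNPs contained in gene intervals
#'
#' One row per (SNP, containing gene), with 1-based inclusive interval
#' semantics (a SNP at a gene's start or end is contained). SNPs in no gene
#' are omitted; overlapping genes each receive the SNP. Uses interval
#' overlap via GenomicRanges.
#'
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos`.
#' @param genes data.frame from [read_gff3_genes()].
#' @return data.frame with columns `snp_id`, `chrom`, `pos`, `gene_id`,
#'   `gene_start`, `gene_end`, plus attributes `n_snps` and `n_genes`
#'   (distinct matched counts).
#' @export
overlap_snps_genes <- function(snps, genes) {
  snps <- unique(as.data.frame(snps)[, c("snp_id", "chrom", "pos")])
  genes <- as.data.frame(genes)
  unmatched <- setdiff(unique(snps$chrom), unique(genes$chrom))
  if (length(unmatched) && nrow(genes))
    warning("chromosome(s) absent from annotation: ",
            paste(unmatched, collapse = ", "))
  empty <- data.frame(snp_id = character(0), chrom = character(0),
                      pos = integer(0), gene_id = character(0),
                      gene_start = integer(0), gene_end = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(snps) || !nrow(genes)) {
    attr(empty, "n_snps") <- 0L; attr(empty, "n_genes") <- 0L
    return(empty)
  }
  q <- GenomicRanges::GRanges(snps$chrom,
                              IRanges::IRanges(snps$pos, snps$pos))
  s <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$start, genes$end))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(q, s))
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  res <- data.frame(snp_id = snps$snp_id[qi], chrom = snps$chrom[qi],
                    pos = snps$pos[qi], gene_id = genes$gene_id[si],
                    gene_start = genes$start[si], gene_end = genes$end[si],
                    stringsAsFactors = FALSE)
  res <- res[order(res$snp_id, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_snps") <- length(unique(res$snp_id))
  attr(res, "n_genes") <- length(unique(res$gene_id))
  res
}

#' Write a one-gene-per-line list for external enrichment tools
#'
#' @param snp_genes data.frame from [overlap_snps_genes()].
#' @param path output path.
#' @export
write_gene_list <- function(snp_genes, path) {
  writeLines(sort(unique(snp_genes$gene_id)), path)
  invisible(path)
}

#' One-sided hypergeometric term enrichment
#'
#' Convenience built-in for self-contained testing of candidate gene lists:
#' for each term, the upper-tail hypergeometric probability of observing at
#' least the seen number of candidate genes annotated to it, given the
#' universe. No multiplicity correction is applied by default.
#'
#' @param genes character vector of candidate gene IDs.
#' @param term2gene data.frame with columns `term`, `gene_id`.
#' @param universe character vector of all annotatable gene IDs (default:
#'   all genes in `term2gene`).
#' @return data.frame with columns `term`, `k` (candidates in term), `m`
#'   (term size), `n_candidates`, `universe_size`, `p_value`, sorted by
#'   p-value.
#' @export
enrich_hypergeometric <- function(genes, term2gene, universe = NULL) {
  if (is.null(universe)) universe <- unique(term2gene$gene_id)
  genes <- intersect(unique(genes), universe)
  N <- length(universe); nc <- length(genes)
  terms <- split(term2gene$gene_id, term2gene$term)
  rows <- lapply(names(terms), function(tm) {
    tg <- intersect(unique(terms[[tm]]), universe)
    k <- length(intersect(genes, tg))
    data.frame(term = tm, k = k, m = length(tg), n_candidates = nc,
               universe_size = N,
               p_value = stats::phyper(k - 1L, length(tg), N - length(tg),
                                       nc, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res[order(res$p_value, res$term), , drop = FALSE]
}
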