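# Readers and writers for the tabular and annotation formats the pipeline
# touches: founder-haplotype matrix, genetic map, GWAS peaks, phenotypes,
# GFF3 gene intervals, bias-result tables, and serialized null distributions.

#' Construct a founder-haplotype matrix
#'
#' Holds, per individual and SNP locus, the ordered pair of founder-haplotype
#' labels assigned to the phased genotypes. Labels are integers in `1..K+1`
#' (the unknown-origin pool is `K+1`); `NA` marks missing assignments.
#'
#' @param loci data.frame with columns `chrom`, `pos`, `snp_id`, sorted by
#'   (chrom, pos) with unique SNP IDs.
#' @param ids character vector of individual IDs.
#' @param A,B integer matrices (individuals x loci) of maternal/paternal-side
#'   labels.
#' @param K number of founder labels (unknown label is `K + 1`).
#' @return Object of class `hap_matrix`.
#' @export
hap_matrix <- function(loci, ids, A, B, K) {
  loci <- as.data.frame(loci)
  stopifnot(all(c("chrom", "pos", "snp_id") %in% names(loci)))
  if (anyDuplicated(loci$snp_id))
    stop("duplicate SNP ID(s): ",
         paste(unique(loci$snp_id[duplicated(loci$snp_id)]), collapse = ", "))
  o <- order(loci$chrom, loci$pos)
  if (!identical(o, seq_len(nrow(loci))))
    stop("loci must be sorted by (chrom, pos)")
  if (!identical(dim(A), dim(B)) ||
      nrow(A) != length(ids) || ncol(A) != nrow(loci))
    stop("A and B must be individuals x loci matrices matching ids and loci")
  for (nm in c("A", "B")) {
    M <- get(nm)
    bad <- which(!is.na(M) & (M < 1L | M > K + 1L), arr.ind = TRUE)
    if (nrow(bad))
      stop("label out of range 1..", K + 1L, " at individual '",
           ids[bad[1L, 1L]], "', locus '", loci$snp_id[bad[1L, 2L]], "'")
  }
  dimnames(A) <- dimnames(B) <- list(ids, loci$snp_id)
  structure(list(loci = loci, ids = ids, A = A, B = B, K = as.integer(K)),
            class = "hap_matrix")
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat("Founder-haplotype matrix:", length(x$ids), "individuals x",
      nrow(x$loci), "loci, K =", x$K,
      sprintf("(%.1f%% missing)\n",
              100 * mean(is.na(x$A) | is.na(x$B))))
  invisible(x)
}

#' Read a founder-haplotype matrix
#'
#' TSV with header: columns `chrom`, `pos`, `snp_id`, then two columns per
#' individual named `ID.A` and `ID.B`. Missing labels are `NA`.
#'
#' @param path file path.
#' @param K number of founder labels. By default inferred from the maximum
#'   observed label `M`: `K = 2 x founders` is even, so an odd `M` is the
#'   pooled unknown label `K + 1` and an even `M` is `K` itself (the unknown
#'   label need not be observed).
#' @return A `hap_matrix`.
#' @export
read_haplotype_matrix <- function(path, K = NULL) {
  tab <- data.table::fread(path, header = TRUE, sep = "\t",
                           na.strings = c("NA", ""))
  need <- c("chrom", "pos", "snp_id")
  if (!all(need %in% names(tab)))
    stop("haplotype matrix must start with columns chrom, pos, snp_id")
  hapcols <- setdiff(names(tab), need)
  ids_a <- sub("\\.A$", "", grep("\\.A$", hapcols, value = TRUE))
  ids_b <- sub("\\.B$", "", grep("\\.B$", hapcols, value = TRUE))
  if (!identical(ids_a, ids_b))
    stop("each individual needs paired columns ID.A and ID.B")
  loci <- as.data.frame(tab[, need, with = FALSE])
  o <- order(loci$chrom, loci$pos)
  if (!identical(o, seq_len(nrow(loci))))
    stop("loci are not sorted by (chrom, pos)")
  A <- t(as.matrix(tab[, paste0(ids_a, ".A"), with = FALSE]))
  B <- t(as.matrix(tab[, paste0(ids_a, ".B"), with = FALSE]))
  storage.mode(A) <- storage.mode(B) <- "integer"
  if (is.null(K)) {
    M <- max(A, B, na.rm = TRUE)
    K <- if (M %% 2L == 1L) M - 1L else M
  }
  hap_matrix(loci, ids_a, A, B, K)
}

#' Write a founder-haplotype matrix
#'
#' @param mat a `hap_matrix`.
#' @param path output path.
#' @export
write_haplotype_matrix <- function(mat, path) {
  tab <- data.table::as.data.table(mat$loci)
  for (i in seq_along(mat$ids)) {
    tab[[paste0(mat$ids[i], ".A")]] <- mat$A[i, ]
    tab[[paste0(mat$ids[i], ".B")]] <- mat$B[i, ]
  }
  data.table::fwrite(tab, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a genetic map
#'
#' CSV with columns `chrom`, `snp_id`, `cM`; positions must be non-decreasing
#' within a chromosome.
#'
#' @param path file path.
#' @return data.frame with those columns.
#' @export
read_genetic_map <- function(path) {
  map <- as.data.frame(data.table::fread(path, header = TRUE))
  if (!all(c("chrom", "snp_id", "cM") %in% names(map)))
    stop("genetic map needs columns chrom, snp_id, cM")
  bad <- unlist(tapply(map$cM, map$chrom, function(x) any(diff(x) < 0)))
  if (any(bad))
    stop("map positions decrease within chromosome(s): ",
         paste(names(bad)[bad], collapse = ", "))
  map
}

#' Read a GWAS peak table
#'
#' TSV with columns `trait`, `snp_id` and/or `chrom` + `pos`, and optionally
#' `label` and `effect` (per-haplotype effect sign or value at the peak).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_gwas_peaks <- function(path) {
  tab <- as.data.frame(data.table::fread(path, header = TRUE,
                                         na.strings = c("NA", "")))
  if (!"trait" %in% names(tab)) stop("GWAS peak table needs a trait column")
  if (!("snp_id" %in% names(tab) || all(c("chrom", "pos") %in% names(tab))))
    stop("GWAS peak table needs snp_id or chrom+pos columns")
  tab
}

#' Read a phenotype table
#'
#' TSV of cultivar x trait values (multi-year means precomputed upstream);
#' first column is the individual ID.
#'
#' @param path file path.
#' @return data.frame with rownames set to individual IDs.
#' @export
read_phenotypes <- function(path) {
  tab <- as.data.frame(data.table::fread(path, header = TRUE,
                                         na.strings = c("NA", "")))
  if (anyDuplicated(tab[[1L]])) stop("duplicate individual IDs in phenotypes")
  rownames(tab) <- as.character(tab[[1L]])
  tab[-1L]
}

#' Write a phenotype table
#' @param pheno data.frame with individual IDs as rownames.
#' @param path output path.
#' @export
write_phenotypes <- function(pheno, path) {
  tab <- data.table::data.table(id = rownames(pheno))
  for (nm in names(pheno)) tab[[nm]] <- pheno[[nm]]
  data.table::fwrite(tab, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read gene intervals from a GFF3 file
#'
#' Retains only features of type `gene`; coordinates are 1-based inclusive
#' per the GFF3 standard. Malformed rows (wrong column count, coordinate 0)
#' are reported with their line number before parsing.
#'
#' @param path GFF3 file path.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gff3_genes <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (ln in body) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L)
      stop("malformed GFF3 line ", ln, ": expected 9 columns, found ",
           length(f))
    if (f[4L] == "0" || f[5L] == "0")
      stop("malformed GFF3 line ", ln, ": coordinate 0 (GFF3 is 1-based)")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & gr$type == "gene"]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
    as.character(seq_along(gr))
  data.frame(gene_id = ids,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write a bias-result table
#'
#' TSV with columns `chrom`, `pos`, `snp_id`, `label`, `observed_count`,
#' `expected_count`, `n`, `p_value`, `neg_log10_p`, `direction`,
#' `significant`, `flagged`, rows ordered by (locus, label). Output is
#' byte-identical across runs for identical input.
#'
#' @param results data.frame from [test_bias()].
#' @param path output path.
#' @export
write_bias_table <- function(results, path) {
  data.table::fwrite(data.table::as.data.table(results), path, sep = "\t",
                     na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a bias-result table written by [write_bias_table()]
#' @param path file path.
#' @return data.frame.
#' @export
read_bias_table <- function(path) {
  as.data.frame(data.table::fread(path, header = TRUE,
                                  na.strings = c("NA", "")))
}

#' Serialize a null distribution to JSON
#' @param null a `null_distribution`.
#' @param path output path.
#' @export
write_null_distribution <- function(null, path) {
  obj <- list(
    marginal = unname(apply(null$marginal, 1L, function(r) unname(r),
                            simplify = FALSE)),
    iterations = null$iterations, seed = null$seed, subset = null$subset,
    n = null$n, K = null$K, unknown_label = null$unknown_label,
    exact = isTRUE(null$exact))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a null distribution from JSON
#' @param path file path.
#' @return A `null_distribution`.
#' @export
read_null_distribution <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  marg <- if (is.matrix(obj$marginal)) obj$marginal else
    do.call(rbind, lapply(obj$marginal, as.numeric))
  dimnames(marg) <- list(label = seq_len(nrow(marg)),
                         count = 0:(ncol(marg) - 1L))
  counts <- 0:(ncol(marg) - 1L)
  mass <- if (isTRUE(obj$exact)) marg else marg / obj$iterations
  structure(list(marginal = marg,
                 mean = as.numeric(mass %*% counts),
                 iterations = obj$iterations, seed = obj$seed,
                 subset = obj$subset, n = obj$n, K = obj$K,
                 unknown_label = obj$unknown_label,
                 exact = isTRUE(obj$exact), samples = NULL),
            class = "null_distribution")
}
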