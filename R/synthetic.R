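# Synthetic breeding pedigrees, founder-labelled haplotype matrices with
# optional transmission distortion (breeder selection), genetic maps,
# phenotypes from haplotype effects, and GFF3 fixtures.

#' Synthetic-data configuration
#'
#' Defaults emulate a compact fruit-breeding programme: 7 founder cultivars,
#' 5 generation layers, 12 matings of 4 offspring per breeding round
#' (7 + 4 x 48 = 199 individuals), 500 SNP loci on 5 chromosomes, no
#' missing data, and a mild "popular parent" skew in mate choice.
#'
#' @param n_founders number of founder cultivars.
#' @param n_generations total generation layers including the founders.
#' @param matings_per_gen matings per breeding round.
#' @param offspring_per_mating offspring per mating.
#' @param n_loci number of SNP loci.
#' @param n_chrom number of chromosomes (loci spread evenly).
#' @param missing_rate fraction of (individual, locus) label pairs set
#'   missing, in `[0, 1)`.
#' @param popularity_skew gamma-shape skew of parent-use weights; 0 =
#'   uniform mating, larger = stronger reuse of a few elite parents.
#' @param unknown_parent_rate fraction of matings whose second parent is an
#'   undocumented outsider (exercises the pooled unknown label).
#' @param seed integer seed.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_founders = 7L, n_generations = 5L,
                         matings_per_gen = 12L, offspring_per_mating = 4L,
                         n_loci = 500L, n_chrom = 5L, missing_rate = 0,
                         popularity_skew = 1.5, unknown_parent_rate = 0,
                         seed = 1L) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              matings_per_gen = as.integer(matings_per_gen),
              offspring_per_mating = as.integer(offspring_per_mating),
              n_loci = as.integer(n_loci), n_chrom = as.integer(n_chrom),
              missing_rate = missing_rate,
              popularity_skew = popularity_skew,
              unknown_parent_rate = unknown_parent_rate,
              seed = as.integer(seed))
  with(cfg, {
    if (any(c(n_founders, n_generations, matings_per_gen,
              offspring_per_mating, n_loci, n_chrom) < 1L))
      stop("all counts must be >= 1")
    if (missing_rate < 0 || missing_rate >= 1)
      stop("missing_rate must be in [0, 1)")
  })
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic breeding pedigree
#'
#' Founders form generation 1. Each later breeding round mates pairs whose
#' first parent comes from the previous layer (so layering reaches the
#' requested depth) and whose second parent is drawn from any earlier layer,
#' both weighted by per-individual "popularity" weights so a few elite
#' parents are reused disproportionately, as in real programmes. With
#' `unknown_parent_rate > 0` some matings use an undocumented second parent
#' (recorded as unknown).
#'
#' @param config a [synth_config()].
#' @param seed overrides `config$seed` when given.
#' @return A `gd_pedigree`.
#' @export
generate_pedigree <- function(config, seed = NULL) {
  cfg <- config
  set.seed(if (is.null(seed)) cfg$seed else seed)
  founders <- sprintf("F%02d", seq_len(cfg$n_founders))
  id <- founders
  sire <- rep(NA_character_, cfg$n_founders)
  dam <- rep(NA_character_, cfg$n_founders)
  gen_of <- stats::setNames(rep(1L, cfg$n_founders), founders)
  # popularity weight drawn once per individual
  wt <- stats::setNames(pop_weight(cfg$n_founders, cfg$popularity_skew),
                        founders)
  for (g in seq(2L, length.out = cfg$n_generations - 1L)) {
    prev <- names(gen_of)[gen_of == g - 1L]
    earlier <- names(gen_of)[gen_of < g]
    if (length(prev) < 1L || length(earlier) < 2L)
      stop("config infeasible: no available parents for generation ", g)
    kid <- 0L
    for (m in seq_len(cfg$matings_per_gen)) {
      p1 <- sample(prev, 1L, prob = wt[prev])
      unknown2 <- stats::runif(1) < cfg$unknown_parent_rate
      p2 <- if (unknown2) NA_character_ else {
        pool <- setdiff(earlier, p1)
        sample(pool, 1L, prob = wt[pool])
      }
      for (o in seq_len(cfg$offspring_per_mating)) {
        kid <- kid + 1L
        cid <- sprintf("G%d_%03d", g, kid)
        id <- c(id, cid)
        sire <- c(sire, p1)
        dam <- c(dam, p2)
        gen_of[cid] <- g
        wt[cid] <- pop_weight(1L, cfg$popularity_skew)
      }
    }
  }
  pedigree(id, sire, dam, founders = founders)
}

pop_weight <- function(n, skew) {
  if (skew <= 0) rep(1, n) else stats::rgamma(n, shape = 1 / skew,
                                              rate = 1 / skew)
}

#' Selection scenario for synthetic haplotype data
#'
#' Describes locus-specific transmission distortion emulating breeder
#' selection. In `gametic` mode a parent heterozygous for the favoured label
#' transmits it with probability `k` instead of 1/2 (`k = 0.5` neutral,
#' `k = 1` deterministic). In `viability` mode offspring genotypes at the
#' locus are resampled: non-carriers are accepted with probability
#' `2 (1 - k)`, carriers always.
#'
#' @param locus locus index (1-based).
#' @param label favoured founder label.
#' @param k distortion strength in `[0.5, 1]`.
#' @param mode `"gametic"` (default) or `"viability"`.
#' @return List of class `selection_scenario`.
#' @export
selection_scenario <- function(locus, label, k, mode = c("gametic",
                                                         "viability")) {
  mode <- match.arg(mode)
  if (k < 0.5 || k > 1) stop("k must be in [0.5, 1]")
  structure(list(locus = as.integer(locus), label = as.integer(label),
                 k = k, mode = mode), class = "selection_scenario")
}

#' Generate a founder-labelled haplotype matrix from a pedigree
#'
#' Drops founder labels through the pedigree independently at each locus
#' under Mendelian 1/2 transmission, except at loci carrying a
#' [selection_scenario()], where transmission is distorted as configured.
#' Missingness is applied uniformly at random last.
#'
#' @inheritParams expected_contribution
#' @param n_loci number of loci.
#' @param scenarios list of [selection_scenario()] objects (or a single one).
#' @param missing_rate per-(individual, locus) missingness probability
#'   applied to both labels of the pair.
#' @param n_chrom chromosomes to spread loci over.
#' @param seed integer seed.
#' @return A `hap_matrix`.
#' @export
generate_haplotype_data <- function(ped, scheme, n_loci = 500L,
                                    scenarios = list(), missing_rate = 0,
                                    n_chrom = 5L, seed = 1L) {
  if (inherits(scenarios, "selection_scenario")) scenarios <- list(scenarios)
  for (sc in scenarios)
    if (sc$locus > n_loci) stop("scenario locus ", sc$locus, " > n_loci")
  set.seed(seed)
  n <- length(ped$id)
  fix <- fixed_label_pairs(ped, scheme)
  u <- scheme$unknown_label
  A <- matrix(NA_integer_, n, n_loci)
  B <- matrix(NA_integer_, n, n_loci)
  sc_at <- rep(list(NULL), n_loci)
  for (sc in scenarios) sc_at[[sc$locus]] <- sc

  gam_mask <- vapply(sc_at, function(s) !is.null(s) && s$mode == "gametic",
                     logical(1))
  fav_vec <- vapply(sc_at, function(s) if (is.null(s)) NA_integer_ else
    s$label, integer(1))
  for (i in ped$ord) {
    if (!is.na(fix$A[i])) {
      A[i, ] <- fix$A[i]; B[i, ] <- fix$B[i]
      next
    }
    # gametic distortion handled per scenario locus; all scenario loci share
    # the parent's draw unless distorted
    Ai <- gamete_multi(ped$sire[i], A, B, u, n_loci, gam_mask, fav_vec, sc_at)
    Bi <- gamete_multi(ped$dam[i], A, B, u, n_loci, gam_mask, fav_vec, sc_at)
    # viability selection: resample the offspring's pair at the locus
    for (l in which(vapply(sc_at, function(s) !is.null(s) &&
                             s$mode == "viability", logical(1)))) {
      sc <- sc_at[[l]]
      # a carrier offspring is only possible if some parent carries the label
      can_carry <- function(p) {
        if (is.na(p)) sc$label == u else sc$label %in% c(A[p, l], B[p, l])
      }
      if (!can_carry(ped$sire[i]) && !can_carry(ped$dam[i])) next
      repeat {
        carrier <- Ai[l] == sc$label || Bi[l] == sc$label
        if (carrier || stats::runif(1) < 2 * (1 - sc$k)) break
        Ai[l] <- redraw_gamete_at(ped$sire[i], l, A, B, u)
        Bi[l] <- redraw_gamete_at(ped$dam[i], l, A, B, u)
      }
    }
    A[i, ] <- Ai; B[i, ] <- Bi
  }
  if (missing_rate > 0) {
    # one mask per (individual, locus): both labels of a pair go missing
    drop <- matrix(stats::runif(n * n_loci) < missing_rate, n, n_loci)
    A[drop] <- NA_integer_
    B[drop] <- NA_integer_
  }
  loci <- synth_loci(n_loci, n_chrom)
  hap_matrix(loci, ped$id, A, B, scheme$K)
}

# gamete over all loci with gametic distortion at masked loci
gamete_multi <- function(p, A, B, u, n_loci, gam_mask, fav_vec, sc_at) {
  if (is.na(p)) return(rep(u, n_loci))
  pick_a <- stats::runif(n_loci) < 0.5
  g <- ifelse(pick_a, A[p, ], B[p, ])
  for (l in which(gam_mask)) {
    fav <- fav_vec[l]; k <- sc_at[[l]]$k
    a <- A[p, l]; b <- B[p, l]
    if ((a == fav) != (b == fav))  # heterozygous carrier
      g[l] <- if (stats::runif(1) < k) fav else if (a == fav) b else a
  }
  g
}

redraw_gamete_at <- function(p, l, A, B, u) {
  if (is.na(p)) return(u)
  if (stats::runif(1) < 0.5) A[p, l] else B[p, l]
}

# evenly spaced synthetic loci in contiguous chromosome blocks
synth_loci <- function(n_loci, n_chrom) {
  chrom_idx <- sort(rep_len(seq_len(n_chrom), n_loci))
  pos <- unlist(lapply(split(seq_len(n_loci), chrom_idx),
                       function(i) seq_along(i) * 10000L), use.names = FALSE)
  data.frame(chrom = sprintf("chr%02d", chrom_idx), pos = pos,
             snp_id = sprintf("SNP_%04d", seq_len(n_loci)),
             stringsAsFactors = FALSE)
}

#' Generate a genetic map for synthetic loci
#'
#' Equal 1 cM spacing within each chromosome by default.
#'
#' @param loci `loci` data.frame of a `hap_matrix`.
#' @param cm_per_locus map spacing in centimorgans.
#' @return data.frame with columns `chrom`, `snp_id`, `cM`.
#' @export
generate_genetic_map <- function(loci, cm_per_locus = 1) {
  cM <- stats::ave(seq_len(nrow(loci)), loci$chrom,
                   FUN = function(i) (seq_along(i) - 1) * cm_per_locus)
  data.frame(chrom = loci$chrom, snp_id = loci$snp_id, cM = cM,
             stringsAsFactors = FALSE)
}

#' Generate phenotypes from founder-haplotype effects
#'
#' Genotypic values are the linear sum of per-(marker, label) effects over
#' haplotype dosages; Gaussian noise is added so the population variance
#' ratio matches the target heritability.
#'
#' @param mat a `hap_matrix`.
#' @param effects data.frame with columns `snp_id`, `label`, `effect`.
#' @param h2 narrow-sense heritability in `(0, 1]`.
#' @param seed integer seed.
#' @param trait trait name for the output column.
#' @return data.frame (rownames = individual IDs) with columns `trait` value
#'   and `genotypic_value`.
#' @export
generate_phenotypes <- function(mat, effects, h2 = 0.8, seed = 1L,
                                trait = "trait") {
  if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")
  u <- numeric(length(mat$ids))
  for (r in seq_len(nrow(effects))) {
    l <- match(effects$snp_id[r], mat$loci$snp_id)
    if (is.na(l)) stop("effect references unknown SNP: ", effects$snp_id[r])
    lab <- effects$label[r]
    if (lab < 1L || lab > mat$K + 1L)
      stop("effect references label outside 1..", mat$K + 1L)
    d <- (!is.na(mat$A[, l]) & mat$A[, l] == lab) +
         (!is.na(mat$B[, l]) & mat$B[, l] == lab)
    u <- u + d * effects$effect[r]
  }
  vu <- stats::var(u)
  if (vu == 0 && h2 < 1)
    stop("zero genetic variance: heritability target undefined")
  set.seed(seed)
  e <- if (h2 == 1) 0 else stats::rnorm(length(u), 0,
                                        sqrt(vu * (1 - h2) / h2))
  out <- data.frame(y = u + e, genotypic_value = u)
  names(out)[1L] <- trait
  rownames(out) <- mat$ids
  out
}

#' Write a synthetic GFF3 gene-annotation fixture
#'
#' Lays non-overlapping synthetic gene intervals over the loci's coordinate
#' range so a configurable fraction of SNPs fall inside genes.
#'
#' @param loci `loci` data.frame of a `hap_matrix`.
#' @param path output GFF3 path.
#' @param n_genes number of genes per chromosome.
#' @param gene_width gene width in bp.
#' @param seed integer seed.
#' @return Invisibly, the gene interval data.frame.
#' @export
generate_gff3_fixture <- function(loci, path, n_genes = 10L,
                                  gene_width = 25000L, seed = 1L) {
  set.seed(seed)
  rows <- list()
  gid <- 0L
  for (ch in unique(loci$chrom)) {
    rng <- range(loci$pos[loci$chrom == ch])
    starts <- sort(sample(seq(rng[1L], max(rng[1L], rng[2L] - gene_width)),
                          min(n_genes, 50L)))
    # enforce non-overlap
    keep <- c(TRUE, diff(starts) > gene_width)
    starts <- starts[keep]
    for (s in starts) {
      gid <- gid + 1L
      rows[[gid]] <- data.frame(gene_id = sprintf("gene%03d", gid),
                                chrom = ch, start = s,
                                end = s + gene_width - 1L, strand = "+",
                                stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, rows)
  gff <- c("##gff-version 3",
           sprintf("%s\thaplodrop\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   genes$chrom, genes$start, genes$end, genes$strand,
                   genes$gene_id))
  writeLines(gff, path)
  invisible(genes)
}
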