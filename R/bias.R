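# Empirical p-values against the gene-drop null; genome-wide, per-generation,
# stability diagnostics, and per-generation frequency trajectories.

# suffix tail sums of a marginal: tail_ge[c+1] = mass of counts >= c,
# tail_le[c+1] = mass of counts <= c (in iteration counts, or probability
# for exact nulls)
tail_sums <- function(marginal_row) {
  list(ge = rev(cumsum(rev(marginal_row))), le = cumsum(marginal_row))
}

# difficulty-of-occurrence mass per possible count: for each count c, the
# total null mass of counts no more probable than c (pmf ties all included)
occurrence_mass <- function(marginal_row) {
  o <- order(marginal_row)
  sorted <- marginal_row[o]
  cum <- cumsum(as.numeric(sorted))
  r <- rle(as.numeric(sorted))
  ends <- cumsum(r$lengths)
  out <- numeric(length(sorted))
  out[o] <- rep(cum[ends], r$lengths)
  out
}

#' Empirical p-value of an observed founder-label count
#'
#' The p-value is the difficulty of occurrence of the observed count under
#' the gene-drop null. The default `"occurrence"` convention takes the null
#' mass of all counts no more probable than the observed one (a two-sided,
#' likelihood-ordered tail); `"two.sided"` instead doubles the smaller of
#' the upper and lower tail probabilities (ties counted in both tails,
#' capped at 1), and `"greater"`/`"less"` are one-sided. For a simulated
#' null of `N` iterations every convention uses the pseudo-count estimator
#' `(r + 1) / (N + 1)` so p is never zero; for an exact null the tail
#' masses are exact. The direction is the sign of the deviation from the
#' null mean.
#'
#' @param observed integer observed count.
#' @param null a `null_distribution`.
#' @param label integer label whose marginal to use.
#' @param alternative `"occurrence"` (default), `"two.sided"`, `"greater"`
#'   or `"less"`.
#' @return List with `p`, `p_up`, `p_low`, `direction` (`"+"`, `"-"` or
#'   `"0"`).
#' @export
empirical_pvalue <- function(observed, null, label,
                             alternative = c("occurrence", "two.sided",
                                             "greater", "less")) {
  alternative <- match.arg(alternative)
  if (observed < 0 || observed > null$n)
    stop("observed count outside 0..", null$n)
  row <- null$marginal[label, ]
  if (sum(row) == 0) stop("empty null marginal for label ", label)
  ts <- tail_sums(row)
  occ <- occurrence_mass(row)[observed + 1L]
  if (isTRUE(null$exact)) {
    p_up <- ts$ge[observed + 1L]
    p_low <- ts$le[observed + 1L]
    p_occ <- occ
  } else {
    N <- null$iterations
    p_up <- (ts$ge[observed + 1L] + 1) / (N + 1)
    p_low <- (ts$le[observed + 1L] + 1) / (N + 1)
    p_occ <- (occ + 1) / (N + 1)
  }
  p <- switch(alternative,
              occurrence = min(1, p_occ),
              two.sided = min(1, 2 * min(p_up, p_low)),
              greater = min(1, p_up),
              less = min(1, p_low))
  dev <- observed - null$mean[label]
  list(p = p, p_up = min(1, p_up), p_low = min(1, p_low),
       direction = if (dev > 0) "+" else if (dev < 0) "-" else "0")
}

# p-values of every possible count for each label under one null, per the
# chosen sidedness convention (see empirical_pvalue)
pvalue_table <- function(null, labels, alternative) {
  K1 <- nrow(null$marginal)
  tab <- matrix(NA_real_, K1, null$n + 1L)
  N <- null$iterations
  pc <- function(raw) {  # pseudo-count correction for simulated nulls
    if (isTRUE(null$exact)) raw else (raw + 1) / (N + 1)
  }
  for (k in labels) {
    row <- null$marginal[k, ]
    ts <- tail_sums(row)
    tab[k, ] <- pmin(1, switch(alternative,
                               occurrence = pc(occurrence_mass(row)),
                               two.sided = 2 * pmin(pc(ts$ge), pc(ts$le)),
                               greater = pc(ts$ge),
                               less = pc(ts$le),
                               stop("unknown alternative: ", alternative)))
  }
  tab
}

# observed per-label haplotype counts at one locus over subset rows,
# ignoring missing labels; returns counts (length K+1) and n
observed_counts <- function(mat, locus_col, rows, K1) {
  labs <- c(mat$A[rows, locus_col], mat$B[rows, locus_col])
  labs <- labs[!is.na(labs)]
  list(x = tabulate(labs, nbins = K1), n = length(labs))
}

#' Test founder-haplotype frequencies for bias
#'
#' For every locus and label, compares the observed haplotype count in the
#' tested subset against the gene-drop null and reports the Monte Carlo
#' p-value. A locus is `significant` when `-log10(p)` exceeds `threshold`
#' (default 4). Counts are taken over non-missing labels; when missingness
#' makes a locus's haplotype pool size differ from the null's `n`, the locus
#' is flagged with `p = NA` unless `resimulate = TRUE`, in which case the
#' null is re-simulated on the locus's complete-data individuals.
#'
#' @param mat a `hap_matrix`.
#' @param null a `null_distribution` computed on `subset`.
#' @param threshold significance threshold on `-log10(p)`.
#' @param labels integer labels to test (default all `1..K+1`).
#' @param subset individuals to test; default the null's subset.
#' @param alternative sidedness, see [empirical_pvalue()].
#' @param resimulate re-simulate the null per mismatched-n locus (requires
#'   `ped` and `scheme`).
#' @param ped,scheme pedigree and label scheme, only for `resimulate`.
#' @return data.frame, one row per (locus, label), ordered by (locus, label):
#'   `chrom`, `pos`, `snp_id`, `label`, `observed_count`, `expected_count`,
#'   `n`, `p_value`, `neg_log10_p`, `direction`, `significant`, `flagged`.
#' @export
test_bias <- function(mat, null, threshold = 4, labels = NULL,
                      subset = NULL, alternative = "occurrence",
                      resimulate = FALSE, ped = NULL, scheme = NULL) {
  K1 <- mat$K + 1L
  if (nrow(null$marginal) != K1)
    stop("null has ", nrow(null$marginal), " labels but matrix implies ", K1)
  if (is.null(subset)) subset <- null$subset
  if (!setequal(subset, null$subset))
    stop("tested subset differs from the null's subset")
  rows <- match(subset, mat$ids)
  if (anyNA(rows))
    stop("subset individual(s) missing from matrix: ",
         paste(subset[is.na(rows)], collapse = ", "))
  if (is.null(labels)) labels <- seq_len(K1)

  p_tab <- pvalue_table(null, labels, alternative)

  L <- nrow(mat$loci)
  out <- vector("list", L)
  for (l in seq_len(L)) {
    oc <- observed_counts(mat, l, rows, K1)
    flagged <- oc$n != null$n
    nl <- null
    resim <- FALSE
    if (flagged && resimulate) {
      if (is.null(ped) || is.null(scheme))
        stop("resimulate = TRUE requires ped and scheme")
      complete <- subset[!is.na(mat$A[rows, l]) & !is.na(mat$B[rows, l])]
      oc <- list(x = {
        labs <- c(mat$A[match(complete, mat$ids), l],
                  mat$B[match(complete, mat$ids), l])
        tabulate(labs[!is.na(labs)], nbins = K1)
      }, n = 2L * length(complete))
      nl <- simulate_null(ped, scheme, complete,
                          n_iterations = null$iterations, seed = null$seed)
      flagged <- FALSE
      resim <- TRUE
    }
    x <- oc$x[labels]
    if (!flagged && !resim) {
      p <- p_tab[cbind(labels, x + 1L)]
    } else if (!flagged) {
      ptl <- pvalue_table(nl, labels, alternative)
      p <- ptl[cbind(labels, x + 1L)]
    } else {
      p <- rep(NA_real_, length(labels))
    }
    dev <- x - nl$mean[labels] * oc$n / nl$n
    out[[l]] <- data.frame(
      chrom = mat$loci$chrom[l], pos = mat$loci$pos[l],
      snp_id = mat$loci$snp_id[l],
      label = labels,
      observed_count = x,
      expected_count = nl$mean[labels] * oc$n / nl$n,
      n = oc$n,
      p_value = p,
      neg_log10_p = -log10(p),
      direction = ifelse(dev > 0, "+", ifelse(dev < 0, "-", "0")),
      significant = !is.na(p) & -log10(p) > threshold,
      flagged = flagged,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "threshold") <- threshold
  attr(res, "alternative") <- alternative
  res
}

#' Test for bias within each breeding generation separately
#'
#' Repeats [test_bias()] with the tested subset restricted to each
#' generation's individuals, simulating a separate null per subset.
#' Generations with fewer than 2 individuals (with genotype data) are
#' skipped with a warning.
#'
#' @inheritParams test_bias
#' @param ped a `gd_pedigree`.
#' @param scheme a `founder_scheme`.
#' @param generations generation map (from [assign_generations()], possibly
#'   merged); default `ped$generation`.
#' @param start_generation first generation to test (default 1).
#' @param n_iterations iterations per generation's null.
#' @param seed root seed; generation `g` uses `seed + g`.
#' @return Named list of bias tables, one per tested generation.
#' @export
test_by_generation <- function(mat, ped, scheme, generations = NULL,
                               threshold = 4, start_generation = 1L,
                               n_iterations = 1e5, seed = 1L,
                               alternative = "occurrence") {
  if (is.null(generations)) generations <- ped$generation
  gens <- sort(unique(generations[generations >= start_generation]))
  out <- list()
  for (g in gens) {
    members <- intersect(names(generations)[generations == g], mat$ids)
    if (length(members) < 2L) {
      warning("generation ", g, " has ", length(members),
              " genotyped individual(s); skipped")
      next
    }
    null_g <- simulate_null(ped, scheme, members,
                            n_iterations = n_iterations, seed = seed + g)
    out[[as.character(g)]] <- test_bias(mat, null_g, threshold = threshold,
                                        alternative = alternative)
  }
  out
}

#' Stability of significant-SNP detection across iteration counts
#'
#' Re-runs the null simulation and bias test at each iteration count in an
#' ascending grid and reports, per count, the significant SNP set's size and
#' Jaccard similarity to the set obtained at the largest count, plus the
#' smallest count whose set already equals the largest count's.
#'
#' @inheritParams test_bias
#' @param ped,scheme pedigree and label scheme.
#' @param subset tested individuals.
#' @param grid ascending iteration counts,
#'   e.g. `c(1e4, 1e5, 1e6)`.
#' @param seed root seed; grid entry `i` uses `seed + i - 1`.
#' @return List with `table` (data.frame: iterations, n_significant,
#'   jaccard_to_max), `sets` (the significant SNP-ID sets), and `stable_at`
#'   (smallest grid count matching the largest; `NA` if only the largest
#'   matches itself).
#' @export
iteration_stability <- function(mat, ped, scheme, subset = "all",
                                grid = c(1e4, 1e5, 1e6), threshold = 4,
                                seed = 1L, alternative = "occurrence") {
  grid <- sort(as.integer(grid))
  sets <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    null_i <- simulate_null(ped, scheme, subset, n_iterations = grid[i],
                            seed = seed + i - 1L)
    bt <- test_bias(mat, null_i, threshold = threshold,
                    alternative = alternative)
    sets[[i]] <- sort(unique(bt$snp_id[bt$significant]))
  }
  ref <- sets[[length(grid)]]
  jac <- vapply(sets, function(s) {
    u <- union(s, ref)
    if (!length(u)) 1 else length(intersect(s, ref)) / length(u)
  }, numeric(1))
  eq <- vapply(sets, identical, logical(1), y = ref)
  list(table = data.frame(iterations = grid,
                          n_significant = lengths(sets),
                          jaccard_to_max = jac),
       sets = stats::setNames(sets, grid),
       stable_at = if (any(eq)) grid[which(eq)[1L]] else NA_integer_)
}

#' Founder-haplotype frequency trajectory across generations
#'
#' Frequency of one label at one locus within each generation, over
#' non-missing haplotypes.
#'
#' @param mat a `hap_matrix`.
#' @param generations named generation map.
#' @param snp_id locus ID.
#' @param label integer label.
#' @return data.frame with columns `generation`, `n_haplotypes`, `count`,
#'   `frequency`.
#' @export
frequency_trajectory <- function(mat, generations, snp_id, label) {
  l <- match(snp_id, mat$loci$snp_id)
  if (is.na(l)) stop("unknown SNP ID: ", snp_id)
  if (label < 1L || label > mat$K + 1L)
    stop("label must be in 1..", mat$K + 1L)
  gens <- sort(unique(generations[names(generations) %in% mat$ids]))
  rowsfor <- function(g) match(
    intersect(names(generations)[generations == g], mat$ids), mat$ids)
  out <- lapply(gens, function(g) {
    labs <- c(mat$A[rowsfor(g), l], mat$B[rowsfor(g), l])
    labs <- labs[!is.na(labs)]
    data.frame(generation = g, n_haplotypes = length(labs),
               count = sum(labs == label),
               frequency = if (length(labs)) sum(labs == label) / length(labs)
                           else NA_real_)
  })
  do.call(rbind, out)
}
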