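# Monte Carlo gene-drop null distributions, single drops, exact enumeration
# oracle, and the multinomial pmf.

#' Single gene drop at one locus
#'
#' Propagates founder labels once through the pedigree: founders emit their
#' fixed label pair; each non-founder receives, from each known parent, one of
#' that parent's two simulated labels with probability 1/2, and the unknown
#' label from each unknown parent. Uses R's RNG (seed with [set.seed()]).
#'
#' @inheritParams expected_contribution
#' @return Integer matrix, individuals x 2, of founder labels.
#' @export
drop_single_locus <- function(ped, scheme) {
  fix <- fixed_label_pairs(ped, scheme)
  n <- length(ped$id)
  A <- integer(n); B <- integer(n)
  u <- scheme$unknown_label
  for (i in ped$ord) {
    if (!is.na(fix$A[i])) {
      A[i] <- fix$A[i]; B[i] <- fix$B[i]
    } else {
      s <- ped$sire[i]; d <- ped$dam[i]
      A[i] <- if (is.na(s)) u else if (stats::runif(1) < 0.5) A[s] else B[s]
      B[i] <- if (is.na(d)) u else if (stats::runif(1) < 0.5) A[d] else B[d]
    }
  }
  matrix(c(A, B), ncol = 2L, dimnames = list(ped$id, c("A", "B")))
}

new_null_distribution <- function(marginal, ped, scheme, idx, iterations,
                                  seed, exact, samples = NULL) {
  n <- 2L * length(idx)
  counts <- 0:n
  mass <- if (exact) marginal else marginal / iterations
  structure(list(
    marginal = marginal,
    mean = as.numeric(mass %*% counts),
    iterations = iterations,
    seed = seed,
    subset = ped$id[idx],
    n = n,
    K = scheme$K,
    unknown_label = scheme$unknown_label,
    exact = exact,
    samples = samples), class = "null_distribution")
}

#' Simulate the gene-drop null distribution
#'
#' Runs `n_iterations` independent single-locus gene drops, counting founder
#' labels over the tested individuals' `2 * |subset|` haplotypes at each
#' iteration, and accumulates the per-label marginal count histograms used as
#' the empirical null for the bias test. Under the per-meiosis 1/2 rule the
#' null does not depend on the locus, so one null per tested subset serves
#' all SNPs.
#'
#' @inheritParams expected_contribution
#' @param subset individual IDs, `"all"` (default) or `"nonfounders"`.
#' @param n_iterations number of gene drops (default `1e6`; detection is
#'   typically stable well before that, see [iteration_stability()]).
#' @param seed integer seed; identical seeds give identical nulls.
#' @param keep_samples store the full per-iteration count vectors (memory
#'   grows as `n_iterations x (K+1)`); marginal histograms are always kept.
#' @return A `null_distribution`: list with `marginal` (matrix `(K+1) x
#'   (n+1)` of counts over iterations), `mean` (null mean count per label),
#'   `iterations`, `seed`, `subset`, `n`, and optionally `samples`.
#' @export
simulate_null <- function(ped, scheme, subset = "all", n_iterations = 1e6,
                          seed = 1L, keep_samples = FALSE) {
  idx <- resolve_subset(ped, subset)
  if (!length(idx)) stop("subset is empty")
  n_iterations <- as.integer(n_iterations)
  if (is.na(n_iterations) || n_iterations < 1L)
    stop("n_iterations must be >= 1")
  fix <- fixed_label_pairs(ped, scheme)
  fa <- ifelse(is.na(fix$A), -1L, fix$A)
  fb <- ifelse(is.na(fix$B), -1L, fix$B)
  set.seed(seed)
  res <- cpp_simulate_null(ped$ord - 1L,
                           ifelse(is.na(ped$sire), -1L, ped$sire - 1L),
                           ifelse(is.na(ped$dam), -1L, ped$dam - 1L),
                           fa, fb, scheme$unknown_label,
                           idx - 1L, scheme$unknown_label,
                           n_iterations, keep_samples)
  marg <- res$marginal
  dimnames(marg) <- list(label = seq_len(scheme$unknown_label),
                         count = 0:(2L * length(idx)))
  new_null_distribution(marg, ped, scheme, idx, n_iterations, seed,
                        exact = FALSE,
                        samples = if (keep_samples) res$samples)
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(if (isTRUE(x$exact)) "Exact" else "Empirical",
      "gene-drop null:", nrow(x$marginal), "labels, n =", x$n,
      "haplotypes over", length(x$subset), "individuals")
  if (!isTRUE(x$exact)) cat(",", x$iterations, "iterations, seed", x$seed)
  cat("\n")
  invisible(x)
}

# number of Bernoulli meioses needed to drop through this pedigree:
# one per known-parent link of a non-founder
count_meioses <- function(ped) {
  sum(!is.na(ped$sire[!ped$founder])) + sum(!is.na(ped$dam[!ped$founder]))
}

#' Exact gene-drop null by exhaustive enumeration
#'
#' Enumerates all `2^m` equally likely outcomes of the `m` meioses in the
#' pedigree and returns the exact per-label count distributions. Intended as
#' a test oracle for [simulate_null()] on small pedigrees; the cost is
#' exponential in the meiosis count.
#'
#' @inheritParams simulate_null
#' @param max_meioses refuse pedigrees needing more meioses than this
#'   (default 20).
#' @return A `null_distribution` whose `marginal` holds exact probabilities
#'   (`exact = TRUE`, `iterations = NA`).
#' @export
exact_null_small <- function(ped, scheme, subset = "all", max_meioses = 20L) {
  idx <- resolve_subset(ped, subset)
  if (!length(idx)) stop("subset is empty")
  m <- count_meioses(ped)
  if (m > max_meioses)
    stop("pedigree needs ", m, " meioses (> max_meioses = ", max_meioses,
         "); use simulate_null() instead")
  n_out <- 2L^m
  fix <- fixed_label_pairs(ped, scheme)
  u <- scheme$unknown_label
  n <- length(ped$id)
  # labels for every outcome simultaneously: A[[i]], B[[i]] length n_out
  A <- vector("list", n); B <- vector("list", n)
  bit <- 0L
  next_bits <- function() {
    # bit values of meiosis `bit` across all 2^m outcomes
    v <- as.logical(bitwAnd(seq_len(n_out) - 1L, bitwShiftL(1L, bit)))
    bit <<- bit + 1L
    v
  }
  for (i in ped$ord) {
    if (!is.na(fix$A[i])) {
      A[[i]] <- rep(fix$A[i], n_out)
      B[[i]] <- rep(fix$B[i], n_out)
      next
    }
    s <- ped$sire[i]; d <- ped$dam[i]
    A[[i]] <- if (is.na(s)) rep(u, n_out) else
      ifelse(next_bits(), A[[s]], B[[s]])
    B[[i]] <- if (is.na(d)) rep(u, n_out) else
      ifelse(next_bits(), A[[d]], B[[d]])
  }
  n_hap <- 2L * length(idx)
  marg <- matrix(0, nrow = u, ncol = n_hap + 1L,
                 dimnames = list(label = seq_len(u), count = 0:n_hap))
  hap <- do.call(rbind, c(A[idx], B[idx]))  # (2|subset|) x n_out
  for (k in seq_len(u)) {
    cnt <- colSums(hap == k)
    tab <- tabulate(cnt + 1L, nbins = n_hap + 1L)
    marg[k, ] <- tab / n_out
  }
  new_null_distribution(marg, ped, scheme, idx, NA_integer_, NA_integer_,
                        exact = TRUE)
}

#' Total variation distance between two null distributions
#'
#' Compares the per-label marginal count distributions of two nulls on the
#' same subset; returns the TV distance per label.
#'
#' @param a,b `null_distribution` objects with equal `n`.
#' @return Named numeric vector of TV distances, one per label.
#' @export
tv_distance <- function(a, b) {
  if (a$n != b$n) stop("null distributions have different pool sizes")
  norm <- function(x) {
    m <- x$marginal
    if (isTRUE(x$exact)) m else m / x$iterations
  }
  pa <- norm(a); pb <- norm(b)
  stats::setNames(rowSums(abs(pa - pb)) / 2, rownames(pa))
}

#' Multinomial probability mass function
#'
#' Evaluates `n! / prod(x_k!) * prod(pi_k^x_k)` in log space, the probability
#' of drawing count vector `x` of founder-haplotype labels given cell
#' probabilities `prob`.
#'
#' @param x non-negative integer count vector.
#' @param prob probability vector of the same length, summing to 1.
#' @param log return the log probability.
#' @return The (log) probability.
#' @export
multinomial_pmf <- function(x, prob, log = FALSE) {
  if (length(x) != length(prob)) stop("x and prob must have equal length")
  if (any(x < 0) || any(x != round(x))) stop("x must be non-negative integers")
  if (any(prob < 0 | prob > 1)) stop("prob must lie in [0, 1]")
  if (abs(sum(prob) - 1) > 1e-8) stop("prob must sum to 1")
  lp <- ifelse(x == 0, 0, x * base::log(prob))  # 0 * log(0) := 0
  if (any(is.infinite(lp))) return(if (log) -Inf else 0)
  ll <- lgamma(sum(x) + 1) - sum(lgamma(x + 1)) + sum(lp)
  if (log) ll else exp(ll)
}

#' Single recombination-aware genome drop
#'
#' Propagates whole-genome label mosaics once through the pedigree: each
#' meiosis transmits a crossover mosaic of the parent's two label sequences,
#' with inter-locus recombination fractions derived from map distances via
#' the Haldane map function `r = (1 - exp(-2 d)) / 2` (`d` in Morgans);
#' loci on different chromosomes recombine freely (`r = 0.5`). The per-locus
#' marginal behaviour is identical to [drop_single_locus()].
#'
#' @inheritParams expected_contribution
#' @param map data.frame with columns `chrom`, `snp_id`, `cM`, one row per
#'   locus in order (see [read_genetic_map()]).
#' @return List of two integer matrices `A`, `B` (individuals x loci).
#' @export
drop_genome_linked <- function(ped, scheme, map) {
  rec <- recomb_fractions(map)
  L <- nrow(map)
  fix <- fixed_label_pairs(ped, scheme)
  u <- scheme$unknown_label
  n <- length(ped$id)
  A <- matrix(NA_integer_, n, L, dimnames = list(ped$id, map$snp_id))
  B <- A
  gamete <- function(p) {
    if (is.na(p)) return(rep(u, L))
    from_a <- stats::runif(1) < 0.5
    sw <- stats::runif(L) < rec
    sw[1L] <- FALSE
    from_a <- xor(from_a, cumsum(sw) %% 2 == 1)
    ifelse(from_a, A[p, ], B[p, ])
  }
  for (i in ped$ord) {
    if (!is.na(fix$A[i])) {
      A[i, ] <- fix$A[i]; B[i, ] <- fix$B[i]
    } else {
      A[i, ] <- gamete(ped$sire[i])
      B[i, ] <- gamete(ped$dam[i])
    }
  }
  list(A = A, B = B)
}

# Haldane recombination fraction between consecutive map rows; 0.5 across
# chromosome boundaries; rec[1] unused.
recomb_fractions <- function(map) {
  if (!all(c("chrom", "cM") %in% names(map)))
    stop("genetic map needs columns chrom and cM")
  L <- nrow(map)
  if (L == 0L) stop("empty genetic map")
  d <- c(0, diff(map$cM)) / 100  # Morgans
  if (any(d < 0 & map$chrom == c(map$chrom[1], head(map$chrom, -1L))))
    stop("map positions must be non-decreasing within a chromosome")
  rec <- (1 - exp(-2 * d)) / 2
  newchrom <- map$chrom != c(map$chrom[1], head(map$chrom, -1L))
  rec[newchrom] <- 0.5
  rec[1L] <- 0
  rec
}

#' Simulate per-locus nulls under linkage
#'
#' Recombination-aware analogue of [simulate_null()]: accumulates one
#' marginal histogram per locus from repeated genome drops. Per-locus
#' marginals coincide with the unlinked null; linkage only affects the joint
#' distribution across loci (used e.g. for max-statistic FWER nulls).
#'
#' @inheritParams simulate_null
#' @inheritParams drop_genome_linked
#' @return List of `null_distribution` objects, one per locus.
#' @export
simulate_null_linked <- function(ped, scheme, map, subset = "all",
                                 n_iterations = 1e4, seed = 1L) {
  idx <- resolve_subset(ped, subset)
  if (!length(idx)) stop("subset is empty")
  rec <- recomb_fractions(map)
  fix <- fixed_label_pairs(ped, scheme)
  fa <- ifelse(is.na(fix$A), -1L, fix$A)
  fb <- ifelse(is.na(fix$B), -1L, fix$B)
  set.seed(seed)
  arr <- cpp_simulate_null_linked(ped$ord - 1L,
                                  ifelse(is.na(ped$sire), -1L, ped$sire - 1L),
                                  ifelse(is.na(ped$dam), -1L, ped$dam - 1L),
                                  fa, fb, scheme$unknown_label,
                                  idx - 1L, scheme$unknown_label,
                                  as.integer(n_iterations), rec)
  dim(arr) <- c(scheme$unknown_label, 2L * length(idx) + 1L, nrow(map))
  out <- lapply(seq_len(nrow(map)), function(l) {
    m <- arr[, , l]
    dimnames(m) <- list(label = seq_len(scheme$unknown_label),
                        count = 0:(2L * length(idx)))
    new_null_distribution(m, ped, scheme, idx, as.integer(n_iterations),
                          seed, exact = FALSE)
  })
  stats::setNames(out, map$snp_id)
}
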