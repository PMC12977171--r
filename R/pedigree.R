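# Pedigree representation, validation, generation layering, founder-label
# scheme, and analytic expected founder contributions.

#' Build and validate a pedigree
#'
#' Constructs a validated pedigree from parallel vectors of individual and
#' parent IDs. The parentage graph must be acyclic, every named parent must
#' itself be an individual, and IDs must be unique. Founders are individuals
#' designated as the source of traceable haplotypes; every founder must have
#' both parents unknown. Individuals with both parents unknown that are *not*
#' designated founders are "uninformed": their haplotypes are untraceable and
#' carry the pooled unknown label.
#'
#' @param id character vector of individual IDs.
#' @param sire,dam character vectors of parent IDs; `NA`, `""` or `"0"` mean
#'   unknown.
#' @param founders character vector of founder IDs (order defines label
#'   assignment, see [founder_label_scheme()]). Default: all individuals with
#'   both parents unknown, in input order.
#' @return An object of class `gd_pedigree`: a list with elements `id`,
#'   `sire`, `dam` (integer indices, `NA` = unknown), `founder` (logical),
#'   `uninformed` (logical), `ord` (topological order, parents first), and
#'   `generation` (see [assign_generations()]).
#' @examples
#' ped <- pedigree(c("F1", "F2", "C"), c(NA, NA, "F1"), c(NA, NA, "F2"))
#' ped$founder
#' @export
pedigree <- function(id, sire, dam, founders = NULL) {
  id <- as.character(id)
  if (anyDuplicated(id))
    stop("duplicate individual ID(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  norm <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & (x == "" | x == "0")] <- NA_character_
    x
  }
  sire <- norm(sire); dam <- norm(dam)
  if (length(sire) != length(id) || length(dam) != length(id))
    stop("id, sire and dam must have equal length")
  bad <- setdiff(c(sire[!is.na(sire)], dam[!is.na(dam)]), id)
  if (length(bad))
    stop("parent ID(s) not present as individuals: ",
         paste(unique(bad), collapse = ", "))
  si <- match(sire, id)
  di <- match(dam, id)

  parentless <- is.na(si) & is.na(di)
  if (is.null(founders)) {
    founders <- id[parentless]
  } else {
    founders <- as.character(founders)
    miss <- setdiff(founders, id)
    if (length(miss))
      stop("founder ID(s) not present as individuals: ",
           paste(miss, collapse = ", "))
    if (any(!parentless[match(founders, id)]))
      stop("founder(s) with a known parent: ",
           paste(founders[!parentless[match(founders, id)]], collapse = ", "))
  }
  is_founder <- id %in% founders
  ord <- topo_order(si, di, id)

  ped <- structure(
    list(id = id, sire = si, dam = di,
         founder = is_founder,
         founders = founders,
         uninformed = parentless & !is_founder,
         ord = ord,
         generation = NULL),
    class = "gd_pedigree")
  ped$generation <- assign_generations(ped)
  ped
}

# Kahn topological sort; on failure names a cycle found by parent-walking.
topo_order <- function(si, di, id) {
  n <- length(id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        if (p == i) stop("cycle detected: ", id[i], " is its own parent")
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (w in children[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(ord) < n) {
    # walk parents from an unresolved node until we revisit one
    start <- setdiff(seq_len(n), ord)[1L]
    path <- integer(0)
    v <- start
    while (!v %in% path) {
      path <- c(path, v)
      v <- if (!is.na(si[v]) && !si[v] %in% ord) si[v] else di[v]
    }
    cyc <- path[which(path == v)[1L]:length(path)]
    stop("cycle detected in pedigree: ",
         paste(id[c(cyc, v)], collapse = " -> "))
  }
  ord
}

#' Read a pedigree file
#'
#' Expects delimited text with columns `id`, `sire`, `dam` and an optional
#' fourth column flagging founders (non-zero / `TRUE` = founder); `"0"` or
#' empty fields mean unknown parents, compatible with the parentage columns
#' of a PLINK-style `.ped` convention.
#'
#' @param path file path.
#' @param ... passed to [pedigree()].
#' @return A `gd_pedigree`.
#' @export
read_pedigree <- function(path, ...) {
  tab <- data.table::fread(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = c("NA", ""))
  if (ncol(tab) < 3L)
    stop("pedigree file must have at least 3 columns (id, sire, dam)")
  founders <- NULL
  if (ncol(tab) >= 4L) {
    flag <- tab[[4L]]
    founders <- tab[[1L]][!is.na(flag) & !flag %in% c("0", "FALSE", "false")]
  }
  pedigree(tab[[1L]], tab[[2L]], tab[[3L]], founders = founders, ...)
}

#' Write a pedigree file
#'
#' @param ped a `gd_pedigree`.
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  tab <- data.table::data.table(
    id = ped$id,
    sire = ifelse(is.na(ped$sire), "0", ped$id[ped$sire]),
    dam = ifelse(is.na(ped$dam), "0", ped$id[ped$dam]),
    founder = as.integer(ped$founder))
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}

#' @export
print.gd_pedigree <- function(x, ...) {
  cat("Pedigree:", length(x$id), "individuals,",
      sum(x$founder), "founders,",
      max(x$generation), "generations\n")
  if (any(x$uninformed))
    cat("  uninformed (both parents unknown, non-founder):",
        sum(x$uninformed), "\n")
  invisible(x)
}

#' Assign breeding generations by topological layering
#'
#' Founders (and uninformed individuals without known parents) are generation
#' 1; every other individual is one more than the maximum generation of its
#' *known* parents. `merge_spec` relabels layers after assignment, e.g.
#' `c("6" = 5)` pools layer 6 into generation 5 (used when a late layer holds
#' too few individuals to test on its own).
#'
#' @param ped a `gd_pedigree`.
#' @param merge_spec named vector mapping source layer (name) to target layer
#'   (value), or `NULL`.
#' @return Named integer vector of generations.
#' @export
assign_generations <- function(ped, merge_spec = NULL) {
  gen <- integer(length(ped$id))
  for (i in ped$ord) {
    pg <- c(if (!is.na(ped$sire[i])) gen[ped$sire[i]],
            if (!is.na(ped$dam[i]))  gen[ped$dam[i]])
    gen[i] <- if (length(pg)) 1L + max(pg) else 1L
  }
  if (!is.null(merge_spec)) {
    from <- as.integer(names(merge_spec))
    to <- as.integer(merge_spec)
    missing_layer <- setdiff(from, gen)
    if (length(missing_layer))
      stop("merge_spec references nonexistent layer(s): ",
           paste(missing_layer, collapse = ", "))
    for (j in seq_along(from)) gen[gen == from[j]] <- to[j]
  }
  stats::setNames(gen, ped$id)
}

#' Founder-haplotype label scheme
#'
#' Founder `i` (in founder order) carries the ordered label pair
#' `(2i - 1, 2i)`; with `F` founders there are `K = 2F` traceable founder
#' labels and the pooled label for haplotypes of unknown origin is `K + 1`
#' (so 7 founders give 14 founder labels plus unknown label 15).
#'
#' @param ped a `gd_pedigree`.
#' @return An object of class `founder_scheme`: list with `founders`,
#'   `labels` (matrix founders x 2), `K`, `unknown_label`.
#' @export
founder_label_scheme <- function(ped) {
  nf <- length(ped$founders)
  if (nf == 0L) stop("pedigree has no designated founders")
  labels <- matrix(seq_len(2L * nf), ncol = 2L, byrow = TRUE,
                   dimnames = list(ped$founders, c("A", "B")))
  structure(list(founders = ped$founders, labels = labels,
                 K = 2L * nf, unknown_label = 2L * nf + 1L),
            class = "founder_scheme")
}

#' @export
print.founder_scheme <- function(x, ...) {
  cat("Founder label scheme:", length(x$founders), "founders, K =", x$K,
      ", unknown label =", x$unknown_label, "\n")
  invisible(x)
}

# Fixed label pairs for founders and uninformed individuals; NA elsewhere.
fixed_label_pairs <- function(ped, scheme) {
  n <- length(ped$id)
  fa <- rep(NA_integer_, n); fb <- rep(NA_integer_, n)
  fi <- match(ped$founders, ped$id)
  fa[fi] <- scheme$labels[, 1L]
  fb[fi] <- scheme$labels[, 2L]
  fa[ped$uninformed] <- scheme$unknown_label
  fb[ped$uninformed] <- scheme$unknown_label
  list(A = fa, B = fb)
}

resolve_subset <- function(ped, subset) {
  if (is.null(subset)) return(seq_along(ped$id))
  if (is.character(subset) && length(subset) == 1L &&
      subset %in% c("all", "nonfounders")) {
    return(if (subset == "all") seq_along(ped$id) else which(!ped$founder))
  }
  idx <- match(as.character(subset), ped$id)
  if (anyNA(idx))
    stop("subset individual(s) not in pedigree: ",
         paste(subset[is.na(idx)], collapse = ", "))
  idx
}

#' Analytic expected frequency of a founder label
#'
#' Computes the exact expected frequency of `label` among the `2 * |subset|`
#' haplotypes of a set of individuals, by the recursion
#' `e(i) = (e(sire) + e(dam)) / 2` with `e(founder)` equal to the fraction of
#' the founder's two labels matching `label`, and an unknown parent
#' contributing 1 for the unknown label and 0 otherwise. This is the mean of
#' the gene-drop null and serves as its analytic oracle.
#'
#' @param ped a `gd_pedigree`.
#' @param scheme a `founder_scheme`.
#' @param label integer label in `1..K+1`.
#' @param subset individual IDs, `"all"` (default) or `"nonfounders"`.
#' @return Expected frequency in `[0, 1]`.
#' @export
expected_contribution <- function(ped, scheme, label, subset = "all") {
  if (length(label) != 1L || is.na(label) || label < 1L ||
      label > scheme$unknown_label)
    stop("label must be in 1..", scheme$unknown_label)
  idx <- resolve_subset(ped, subset)
  if (!length(idx)) stop("subset is empty")
  fix <- fixed_label_pairs(ped, scheme)
  e <- numeric(length(ped$id))
  for (i in ped$ord) {
    if (!is.na(fix$A[i])) {
      e[i] <- ((fix$A[i] == label) + (fix$B[i] == label)) / 2
    } else {
      par_e <- function(p) {
        if (is.na(p)) as.numeric(label == scheme$unknown_label) else e[p]
      }
      e[i] <- (par_e(ped$sire[i]) + par_e(ped$dam[i])) / 2
    }
  }
  mean(e[idx])
}
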