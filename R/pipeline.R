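# End-to-end pipeline orchestration with a machine-readable run manifest.

default_run_config <- function() {
  list(
    out_dir = "haplodrop_run",
    seed = 1L,
    iterations = 1e5,
    threshold = 4,
    subset = "all",
    alternative = "occurrence",
    merge_spec = NULL,
    by_generation = FALSE,
    synth = list(),                 # synth_config() overrides
    scenario = NULL,                # list(locus, label, k, mode)
    effects = list(markers = NULL, trait = NULL,
                   iters = 10000L, burnin = 2000L, thin = 10L),
    paths = list(pedigree = NULL, matrix = NULL, phenotypes = NULL,
                 gff3 = NULL, peaks = NULL),
    window = 0)
}

#' Run the gene-drop bias pipeline
#'
#' Executes, in dependency order: synthetic-data generation (when no input
#' paths are given), null simulation, the genome-wide bias test, optional
#' per-generation tests, BayesB effect estimation (when phenotypes are
#' available), gene-annotation overlap and GWAS-peak concordance. Writes all
#' result tables plus a JSON run manifest recording inputs, parameters, and
#' output MD5 hashes; a rerun with the same manifest parameters reproduces
#' the outputs bit-exactly.
#'
#' @param config named list (see the vignette) or path to a YAML file with
#'   the same structure; omitted entries take defaults.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(default_run_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(cfg$out_dir, f)
  log_msg <- function(...) message("[haplodrop] ", ...)
  log_msg("seed ", cfg$seed, ", iterations ", cfg$iterations,
          ", threshold ", cfg$threshold)

  # inputs: read or synthesize
  if (!is.null(cfg$paths$pedigree)) {
    if (!file.exists(cfg$paths$pedigree))
      stop("pedigree file not found: ", cfg$paths$pedigree,
           " (run the synth stage or point paths$pedigree at a file)")
    ped <- read_pedigree(cfg$paths$pedigree)
  } else {
    ped <- generate_pedigree(do.call(synth_config,
                                     c(cfg$synth, list(seed = cfg$seed))))
    write_pedigree(ped, outp("pedigree.tsv"))
  }
  scheme <- founder_label_scheme(ped)
  if (!is.null(cfg$paths$matrix)) {
    if (!file.exists(cfg$paths$matrix))
      stop("haplotype matrix not found: ", cfg$paths$matrix)
    mat <- read_haplotype_matrix(cfg$paths$matrix, K = scheme$K)
  } else {
    sc <- if (!is.null(cfg$scenario))
      list(do.call(selection_scenario, cfg$scenario)) else list()
    synth <- do.call(synth_config, c(cfg$synth, list(seed = cfg$seed)))
    mat <- generate_haplotype_data(ped, scheme, n_loci = synth$n_loci,
                                   scenarios = sc,
                                   missing_rate = synth$missing_rate,
                                   n_chrom = synth$n_chrom,
                                   seed = cfg$seed + 1L)
    write_haplotype_matrix(mat, outp("matrix.tsv"))
  }

  null <- simulate_null(ped, scheme, subset = cfg$subset,
                        n_iterations = cfg$iterations, seed = cfg$seed)
  write_null_distribution(null, outp("null.json"))
  bias <- test_bias(mat, null, threshold = cfg$threshold,
                    alternative = cfg$alternative)
  write_bias_table(bias, outp("bias.tsv"))
  log_msg(sum(bias$significant), " significant (locus, label) pairs")

  if (isTRUE(cfg$by_generation)) {
    gens <- assign_generations(ped, merge_spec = cfg$merge_spec)
    bygen <- test_by_generation(mat, ped, scheme, generations = gens,
                                threshold = cfg$threshold,
                                n_iterations = cfg$iterations,
                                seed = cfg$seed,
                                alternative = cfg$alternative)
    for (g in names(bygen))
      write_bias_table(bygen[[g]], outp(sprintf("bias_gen%s.tsv", g)))
  }

  if (!is.null(cfg$paths$phenotypes)) {
    pheno <- read_phenotypes(cfg$paths$phenotypes)
    trait <- cfg$effects$trait %||% names(pheno)[1L]
    markers <- cfg$effects$markers %||%
      unique(bias$snp_id[bias$significant])
    if (length(markers) >= 2L) {
      des <- build_design(mat, markers)
      fit <- fit_bayesb(stats::setNames(pheno[[trait]], rownames(pheno)),
                        des, iters = cfg$effects$iters,
                        burnin = cfg$effects$burnin,
                        thin = cfg$effects$thin, seed = cfg$seed)
      eff <- do.call(rbind, fit$beta)
      eff$gamma <- fit$gamma[eff$snp_id]
      data.table::fwrite(eff, outp("effects.tsv"), sep = "\t")
    } else {
      log_msg("fewer than 2 significant markers; effects stage skipped")
    }
  }

  sig <- bias[bias$significant, , drop = FALSE]
  if (!is.null(cfg$paths$gff3)) {
    genes <- read_gff3_genes(cfg$paths$gff3)
    sg <- overlap_snps_genes(sig, genes)
    data.table::fwrite(sg, outp("snp_genes.tsv"), sep = "\t")
    write_gene_list(sg, outp("gene_list.txt"))
  }
  if (!is.null(cfg$paths$peaks)) {
    peaks <- read_gwas_peaks(cfg$paths$peaks)
    conc <- match_gwas_peaks(sig, peaks, window = cfg$window)
    data.table::fwrite(conc, outp("concordance.tsv"), sep = "\t")
  }

  outputs <- list.files(cfg$out_dir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  manifest <- list(parameters = cfg,
                   outputs = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
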