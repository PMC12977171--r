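test_that("empirical p-values follow the pseudo-count definition", {
  # null with 9999 iterations, observation above every simulated count
  ped <- trio_pedigree()
  sch <- founder_label_scheme(ped)
  null <- simulate_null(ped, sch, "C", n_iterations = 9999, seed = 1)
  # label 5 (unknown) never occurs in the trio: count 2 observed
  pv <- empirical_pvalue(2, null, 5, alternative = "greater")
  expect_equal(pv$p, 1 / 10000)
  expect_equal(-log10(pv$p), 4)
  # point mass at the observed value -> p = 1 under every convention
  pv0 <- empirical_pvalue(0, null, 5)
  expect_equal(pv0$p, 1)
  expect_equal(empirical_pvalue(0, null, 5, "two.sided")$p, 1)

  # trio child against the exact (1/2, 1/2) null
  ex <- exact_null_small(ped, sch, "C")
  expect_equal(empirical_pvalue(1, ex, 1, "greater")$p, 0.5)
  expect_equal(empirical_pvalue(1, ex, 1, "two.sided")$p, 1)
  expect_equal(empirical_pvalue(1, ex, 1, "occurrence")$p, 1)
  expect_error(empirical_pvalue(3, ex, 1), "outside")
})

test_that("bias test flags a distorted locus and nothing else", {
  b <- default_bundle()
  null <- default_null()
  fav <- favored_label()
  scen <- selection_scenario(locus = 10, label = fav, k = 0.9)
  mat <- generate_haplotype_data(b$ped, b$scheme, n_loci = 50,
                                 scenarios = scen, seed = 7)
  bias <- test_bias(mat, null)  # default threshold 4
  expect_equal(attr(bias, "threshold"), 4)
  tgt <- bias[bias$snp_id == "SNP_0010" & bias$label == fav, ]
  expect_true(tgt$significant)
  expect_equal(tgt$direction, "+")
  expect_gt(tgt$neg_log10_p, 4)
  expect_equal(sum(bias$significant[bias$snp_id != "SNP_0010"]), 0)
  # structural checks
  expect_equal(nrow(bias), 50 * 15)
  expect_true(all(bias$p_value >= 1 / (null$iterations + 1), na.rm = TRUE))
  expect_true(all(tapply(bias$observed_count, bias$snp_id, sum) == null$n))
})

test_that("p-values are invariant under a consistent founder relabelling", {
  b <- default_bundle()
  mat <- generate_haplotype_data(b$ped, b$scheme, n_loci = 10, seed = 23)
  null <- simulate_null(b$ped, b$scheme, "all", 2e4, seed = 5)
  bias <- test_bias(mat, null)

  # reverse founder order: founder i gets the labels of founder F+1-i
  fo <- rev(b$ped$founders)
  ped2 <- pedigree(b$ped$id,
                   ifelse(is.na(b$ped$sire), NA, b$ped$id[b$ped$sire]),
                   ifelse(is.na(b$ped$dam), NA, b$ped$id[b$ped$dam]),
                   founders = fo)
  sch2 <- founder_label_scheme(ped2)
  old_labels <- founder_label_scheme(b$ped)$labels
  remap <- integer(15)
  for (f in rownames(old_labels)) remap[old_labels[f, ]] <- sch2$labels[f, ]
  remap[15] <- 15L
  mat2 <- hap_matrix(mat$loci, mat$ids,
                     matrix(remap[mat$A], nrow(mat$A)),
                     matrix(remap[mat$B], nrow(mat$B)), K = 14)
  null2 <- simulate_null(ped2, sch2, "all", 2e4, seed = 5)
  bias2 <- test_bias(mat2, null2)
  # row for (locus, old label k) equals row for (locus, remap[k])
  key1 <- paste(bias$snp_id, remap[bias$label])
  key2 <- paste(bias2$snp_id, bias2$label)
  expect_equal(bias$p_value, bias2$p_value[match(key1, key2)])
})

test_that("the null p-value distribution is super-uniform", {
  b <- default_bundle()
  null <- default_null()
  mat <- generate_haplotype_data(b$ped, b$scheme, n_loci = 300, seed = 31)
  bias <- test_bias(mat, null)
  n <- nrow(bias)
  for (alpha in c(0.05, 0.01, 1e-3)) {
    rate <- mean(bias$p_value <= alpha)
    expect_lte(rate, alpha + 3 * sqrt(alpha * (1 - alpha) / n))
  }
})

test_that("power increases with distortion strength", {
  b <- default_bundle()
  null <- default_null()
  fav <- favored_label()
  med <- vapply(c(0.6, 0.75, 0.9), function(k) {
    nl <- vapply(1:8, function(r) {
      scen <- selection_scenario(locus = 3, label = fav, k = k)
      mat <- generate_haplotype_data(b$ped, b$scheme, n_loci = 5,
                                     scenarios = scen,
                                     seed = 1000 * k + r)
      bt <- test_bias(mat, null)
      bt$neg_log10_p[bt$snp_id == "SNP_0003" & bt$label == fav]
    }, numeric(1))
    median(nl)
  }, numeric(1))
  expect_true(all(diff(med) >= 0))
  expect_gt(med[3], 4)  # k = 0.9 is decisively detected
})

test_that("per-generation tests: founders are deterministic, neutral data calibrated", {
  b <- default_bundle()
  mat <- generate_haplotype_data(b$ped, b$scheme, n_loci = 30, seed = 53)
  res <- test_by_generation(mat, b$ped, b$scheme, n_iterations = 2e4,
                            seed = 19)
  # generation 1 = founders: fixed labels, p = 1 everywhere
  expect_true(all(res[["1"]]$p_value == 1))
  expect_true(all(!res[["1"]]$significant))
  # neutral data: no generation shows hits beyond the type-I expectation
  hits <- sum(vapply(res, function(r) sum(r$significant), numeric(1)))
  expect_lte(hits, stats::qpois(0.999, 2e-4 * 30 * 15 * length(res)))
})

test_that("strong distortion found genome-wide is echoed in a later generation", {
  b <- default_bundle()
  fav <- favored_label()
  scen <- selection_scenario(locus = 2, label = fav, k = 0.95)
  mat <- generate_haplotype_data(b$ped, b$scheme, n_loci = 5,
                                 scenarios = scen, seed = 61)
  null <- default_null()
  all_pop <- test_bias(mat, null)
  expect_true(all_pop$significant[all_pop$snp_id == "SNP_0002" &
                                    all_pop$label == fav])
  res <- test_by_generation(mat, b$ped, b$scheme, n_iterations = 1e5,
                            seed = 29, start_generation = 3)
  echo <- vapply(res, function(r)
    r$significant[r$snp_id == "SNP_0002" & r$label == fav], logical(1))
  expect_true(any(echo))
})

test_that("a generation with fewer than two members is skipped with a warning", {
  ped <- chain_pedigree()
  sch <- founder_label_scheme(ped)
  mat <- generate_haplotype_data(ped, sch, n_loci = 2, seed = 3, n_chrom = 1)
  expect_warning(expect_warning(
    res <- test_by_generation(mat, ped, sch, n_iterations = 500, seed = 1),
    "skipped"))
  expect_false("2" %in% names(res) && nrow(res[["2"]]) == 0)
})

test_that("mismatched-n loci are flagged, or re-simulated on request", {
  b <- default_bundle()
  null <- simulate_null(b$ped, b$scheme, "all", 5000, seed = 77)
  mat <- generate_haplotype_data(b$ped, b$scheme, n_loci = 4,
                                 missing_rate = 0.1, seed = 99)
  bias <- test_bias(mat, null)
  miss <- bias$n < null$n
  expect_true(any(miss))
  expect_true(all(bias$flagged[miss]))
  expect_true(all(is.na(bias$p_value[miss])))
  re <- test_bias(mat, null, resimulate = TRUE, ped = b$ped,
                  scheme = b$scheme)
  expect_true(all(!re$flagged))
  expect_true(all(!is.na(re$p_value)))
  # subset mismatch is an error
  expect_error(test_bias(mat, null, subset = b$ped$id[1:10]),
               "differs from the null")
})

test_that("detection is deterministic and unresolvable below the p floor", {
  b <- default_bundle()
  fav <- favored_label()
  scen <- selection_scenario(locus = 2, label = fav, k = 0.95)
  mat <- generate_haplotype_data(b$ped, b$scheme, n_loci = 5,
                                 scenarios = scen, seed = 41)
  st1 <- iteration_stability(mat, b$ped, b$scheme, grid = c(2000, 2000),
                             seed = 13)
  expect_equal(st1$table$jaccard_to_max, c(1, 1))
  # 1000 iterations: p >= 1/1001 so -log10(p) < 4 is unattainable
  st2 <- iteration_stability(mat, b$ped, b$scheme, grid = 1000, seed = 13)
  expect_equal(st2$table$n_significant, 0L)
})

test_that("frequency trajectories track selection and handle edge cases", {
  b <- default_bundle()
  gens <- b$ped$generation
  fav <- favored_label()
  # absent label -> all-zero series (label 15 never occurs here)
  mat <- generate_haplotype_data(b$ped, b$scheme, n_loci = 3, seed = 3)
  tr <- frequency_trajectory(mat, gens, "SNP_0002", 15)
  expect_true(all(tr$frequency == 0))
  expect_equal(nrow(tr), 5L)
  # single-generation input
  ped1 <- trio_pedigree()
  sch1 <- founder_label_scheme(ped1)
  m1 <- generate_haplotype_data(ped1, sch1, n_loci = 1, seed = 5,
                                n_chrom = 1)
  t1 <- frequency_trajectory(m1, c(F1 = 1L, F2 = 1L, C = 1L), "SNP_0001", 1)
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$frequency, t1$count / t1$n_haplotypes)
  # under selection the trajectory rises on average across replicates
  slopes <- vapply(1:10, function(r) {
    scen <- selection_scenario(locus = 1, label = fav, k = 0.9)
    m <- generate_haplotype_data(b$ped, b$scheme, n_loci = 2,
                                 scenarios = scen, seed = 500 + r)
    tr <- frequency_trajectory(m, gens, "SNP_0001", fav)
    unname(coef(lm(frequency ~ generation, tr))[2])
  }, numeric(1))
  expect_gt(mean(slopes > 0), 0.8)
  expect_error(frequency_trajectory(mat, gens, "nope", 1), "unknown SNP")
})
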