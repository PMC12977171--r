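test_that("pedigree generation has the configured size and is seed-stable", {
  cfg <- synth_config(n_founders = 7, n_generations = 4,
                      matings_per_gen = 10, offspring_per_mating = 3)
  ped <- generate_pedigree(cfg)
  expect_equal(length(ped$id), 7 + 3 * 10 * 3)  # 3 breeding rounds
  expect_equal(sum(ped$founder), 7L)
  expect_equal(max(ped$generation), 4L)
  ped2 <- generate_pedigree(cfg)
  expect_identical(ped$id, ped2$id)
  expect_identical(ped$sire, ped2$sire)
  expect_identical(ped$dam, ped2$dam)
  expect_error(generate_pedigree(synth_config(n_founders = 1,
                                              n_generations = 3)),
               "infeasible")
})

test_that("popular-parent skew concentrates matings relative to uniform", {
  n_off <- function(skew, seed) {
    cfg <- synth_config(popularity_skew = skew, seed = seed)
    ped <- generate_pedigree(cfg)
    cnt <- table(factor(c(ped$id[ped$sire], ped$id[ped$dam]),
                        levels = ped$id))
    var(as.numeric(cnt))
  }
  skewed <- mean(vapply(1:10, function(s) n_off(1.5, s), numeric(1)))
  uniform <- mean(vapply(1:10, function(s) n_off(0, s), numeric(1)))
  expect_gt(skewed, uniform)
})

test_that("neutral transmission reproduces the analytic expectations", {
  b <- default_bundle()
  reps <- 40
  fav <- favored_label()
  ec <- expected_contribution(b$ped, b$scheme, fav, "all")
  freqs <- vapply(seq_len(reps), function(r) {
    m <- generate_haplotype_data(b$ped, b$scheme, n_loci = 2, seed = 3000 + r)
    mean(c(m$A[, 1], m$B[, 1]) == fav)
  }, numeric(1))
  n_hap <- 2 * length(b$ped$id)
  se <- sqrt(ec * (1 - ec) / (n_hap * reps))
  # pedigree-induced correlation inflates the SE; 6x is ample
  expect_lt(abs(mean(freqs) - ec), 6 * se)
})

test_that("k = 1 gametic distortion makes every carrier's offspring a carrier", {
  b <- default_bundle()
  fav <- favored_label()
  scen <- selection_scenario(locus = 1, label = fav, k = 1)
  m <- generate_haplotype_data(b$ped, b$scheme, n_loci = 1,
                               scenarios = scen, seed = 71)
  carrier <- m$A[, 1] == fav | m$B[, 1] == fav
  for (i in which(!b$ped$founder & !b$ped$uninformed)) {
    for (p in c(b$ped$sire[i], b$ped$dam[i])) {
      if (!is.na(p) && carrier[p]) expect_true(carrier[i])
    }
  }
})

test_that("sustained distortion raises the favoured frequency above neutral", {
  b <- default_bundle()
  fav <- favored_label()
  gens <- b$ped$generation
  last <- names(gens)[gens == max(gens)]
  rows <- match(last, b$ped$id)
  neutral_exp <- expected_contribution(b$ped, b$scheme, fav, last)
  above <- vapply(1:100, function(r) {
    scen <- selection_scenario(locus = 1, label = fav, k = 0.9)
    m <- generate_haplotype_data(b$ped, b$scheme, n_loci = 1,
                                 scenarios = scen, seed = 5000 + r)
    mean(c(m$A[rows, 1], m$B[rows, 1]) == fav) > neutral_exp
  }, logical(1))
  expect_gte(mean(above), 0.95)
})

test_that("viability selection also enriches the favoured label", {
  b <- default_bundle()
  fav <- favored_label()
  gens <- b$ped$generation
  last <- names(gens)[gens == max(gens)]
  rows <- match(last, b$ped$id)
  neutral_exp <- expected_contribution(b$ped, b$scheme, fav, last)
  above <- vapply(1:20, function(r) {
    scen <- selection_scenario(locus = 1, label = fav, k = 0.9,
                               mode = "viability")
    m <- generate_haplotype_data(b$ped, b$scheme, n_loci = 1,
                                 scenarios = scen, seed = 7000 + r)
    mean(c(m$A[rows, 1], m$B[rows, 1]) == fav) > neutral_exp
  }, logical(1))
  expect_gte(mean(above), 0.9)
  expect_error(selection_scenario(1, 1, k = 0.4), "0.5")
  expect_error(generate_haplotype_data(b$ped, b$scheme, n_loci = 3,
                                       scenarios = selection_scenario(9, 1,
                                                                      0.9)),
               "n_loci")
})

test_that("unknown-parent matings inject the pooled unknown label", {
  cfg <- synth_config(unknown_parent_rate = 0.3, seed = 5)
  ped <- generate_pedigree(cfg)
  expect_true(any(is.na(ped$dam[!ped$founder])))
  sch <- founder_label_scheme(ped)
  m <- generate_haplotype_data(ped, sch, n_loci = 5, seed = 6)
  expect_true(any(m$B == sch$unknown_label))
})

test_that("phenotypes hit the target heritability", {
  cfg <- synth_config(matings_per_gen = 25, offspring_per_mating = 5)
  ped <- generate_pedigree(cfg)
  sch <- founder_label_scheme(ped)
  mat <- generate_haplotype_data(ped, sch, n_loci = 10, seed = 2)
  fav <- names(which.max(table(c(mat$A[, 5], mat$B[, 5]))))
  eff <- data.frame(snp_id = "SNP_0005", label = as.integer(fav),
                    effect = 1.5)
  # h2 = 1: no noise
  ph1 <- generate_phenotypes(mat, eff, h2 = 1, seed = 1)
  expect_equal(ph1$trait, ph1$genotypic_value)
  # realized h2 within 0.1 of target, averaged over 20 seeds, n > 500
  h2hat <- vapply(1:20, function(s) {
    ph <- generate_phenotypes(mat, eff, h2 = 0.7, seed = s)
    var(ph$genotypic_value) / var(ph$trait)
  }, numeric(1))
  expect_lt(abs(mean(h2hat) - 0.7), 0.1)
  # degenerate: no genetic variance
  eff0 <- data.frame(snp_id = "SNP_0001", label = 1L, effect = 0)
  expect_error(generate_phenotypes(mat, eff0, h2 = 0.5), "zero genetic")
  expect_error(generate_phenotypes(mat, eff, h2 = 1.5), "h2")
})

test_that("matrix generation is bit-reproducible by seed", {
  b <- default_bundle()
  m1 <- generate_haplotype_data(b$ped, b$scheme, n_loci = 10,
                                missing_rate = 0.05, seed = 12)
  m2 <- generate_haplotype_data(b$ped, b$scheme, n_loci = 10,
                                missing_rate = 0.05, seed = 12)
  expect_identical(m1$A, m2$A)
  expect_identical(m1$B, m2$B)
})
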