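# BayesB fits in this file use shortened chains (2000-3000 iterations) on
# small marker panels so each fit runs in a few seconds; the full-length
# defaults are exercised in the acceptance suite.

make_effect_data <- function(n_loci = 20, causal = NULL, eff = 2,
                             h2 = 0.8, seed = 5) {
  b <- default_bundle()
  mat <- generate_haplotype_data(b$ped, b$scheme, n_loci = n_loci,
                                 seed = seed)
  if (is.null(causal)) causal <- sprintf("SNP_%04d", ceiling(n_loci / 2))
  fav <- favored_label()
  effects <- data.frame(snp_id = causal, label = fav, effect = eff)
  ph <- generate_phenotypes(mat, effects, h2 = h2, seed = seed + 1)
  list(mat = mat, ph = ph, fav = fav, effects = effects)
}

test_that("the haplotype design is one-hot with dosages summing to two", {
  ids <- c("I1", "I2", "I3")
  m <- hap_matrix(data.frame(chrom = "chr1", pos = c(100L, 200L),
                             snp_id = c("s1", "s2")),
                  ids,
                  A = matrix(c(1L, 1L, 3L, 1L, 1L, 1L), 3, 2),
                  B = matrix(c(1L, 15L, 4L, 1L, 1L, 1L), 3, 2), K = 14)
  expect_warning(des <- build_design(m), "single observed label")
  expect_named(des$markers, "s1")
  D <- des$markers$s1$D
  # homozygous label 1 -> dosage 2; (1,15) -> 1 and 1
  expect_equal(unname(D["I1", "1"]), 2L)
  expect_equal(unname(D["I2", "1"]), 1L)
  expect_equal(unname(D["I2", "15"]), 1L)
  expect_true(all(rowSums(D) == 2))
  expect_true(all(rowSums(des$markers$s1$X) == 1))
  expect_error(build_design(m, "zzz"), "unknown marker")
})

test_that("a constant phenotype yields near-zero effects without divergence", {
  d <- make_effect_data(n_loci = 8)
  y <- setNames(rep(3.14, length(d$mat$ids)), d$mat$ids)
  des <- build_design(d$mat)
  fit <- fit_bayesb(y, des, iters = 2000, burnin = 500, thin = 5, seed = 2)
  allb <- unlist(lapply(fit$beta, function(b) b$effective))
  expect_true(all(abs(allb) < 1e-6))
  expect_lt(fit$sigma2_e, 1e-6)
  expect_true(all(is.finite(fit$gamma)))
})

test_that("BayesB recovers a single causal marker and its effect sign", {
  d <- make_effect_data()
  des <- build_design(d$mat)
  fit <- fit_bayesb(setNames(d$ph$trait, rownames(d$ph)), des,
                    iters = 3000, burnin = 1000, thin = 5, seed = 7)
  expect_equal(names(which.max(fit$gamma)), d$effects$snp_id)
  bq <- fit$beta[[d$effects$snp_id]]
  expect_gt(bq$post_mean[bq$label == d$fav], 0)
  # genotypic values identity u = mu + sum_j gamma_j sum_l d beta
  u <- genotypic_values(fit, des)
  manual <- rep(fit$mu, length(fit$individuals))
  keep <- match(fit$individuals, des$ids)
  for (j in names(fit$beta))
    manual <- manual + fit$gamma[j] *
      as.numeric(des$markers[[j]]$D[keep, ] %*% fit$beta[[j]]$post_mean)
  expect_equal(unname(u), manual)
})

test_that("MCMC summaries are reproducible by seed", {
  d <- make_effect_data(n_loci = 6)
  des <- build_design(d$mat)
  y <- setNames(d$ph$trait, rownames(d$ph))
  f1 <- fit_bayesb(y, des, iters = 1500, burnin = 500, thin = 5, seed = 31)
  f2 <- fit_bayesb(y, des, iters = 1500, burnin = 500, thin = 5, seed = 31)
  f3 <- fit_bayesb(y, des, iters = 1500, burnin = 500, thin = 5, seed = 32)
  expect_identical(f1$gamma, f2$gamma)
  expect_identical(f1$beta, f2$beta)
  # a different seed moves the (continuous) posterior effect summaries
  expect_false(identical(f1$beta, f3$beta))
})

test_that("input validation rejects bad phenotypes and settings", {
  d <- make_effect_data(n_loci = 4)
  des <- build_design(d$mat)
  y <- setNames(d$ph$trait, rownames(d$ph))
  expect_error(fit_bayesb(y, des, iters = 500, burnin = 500), "exceed")
  ybad <- y; ybad[1] <- Inf
  expect_error(fit_bayesb(ybad, des, iters = 1000, burnin = 100),
               "non-finite")
  des1 <- build_design(d$mat, d$mat$loci$snp_id[1])
  expect_error(fit_bayesb(y, des1, iters = 1000, burnin = 100),
               "at least 2 markers")
})

test_that("with inclusion forced on, posterior means track a ridge solution", {
  d <- make_effect_data(n_loci = 4, h2 = 0.9)
  des <- build_design(d$mat)
  y <- setNames(d$ph$trait, rownames(d$ph))
  nu_big <- 1e8  # pins every sigma2_beta_j at the prior scale
  s2b <- 1.0
  fit <- fit_bayesb(y, des, pi_incl = 1, nu = nu_big, s2_beta = s2b,
                    iters = 4000, burnin = 1000, thin = 5, seed = 17)
  expect_true(all(fit$gamma == 1))
  # closed-form ridge with the sampler's residual variance
  Dall <- do.call(cbind, lapply(des$markers, `[[`, "D"))
  yc <- y[fit$individuals] - fit$mu
  lam <- fit$sigma2_e / s2b
  bhat <- solve(crossprod(Dall) + diag(lam, ncol(Dall)), crossprod(Dall, yc))
  est <- unlist(lapply(fit$beta, function(b) b$post_mean))
  expect_gt(stats::cor(as.numeric(bhat), est), 0.95)
})

test_that("phenotype trends and consistency classes follow their definitions", {
  gens <- setNames(rep(1:5, each = 10), sprintf("I%02d", 1:50))
  set.seed(8)
  rising <- setNames(as.numeric(gens) * 0.5 + rnorm(50, 0, 0.1),
                     names(gens))
  tr <- phenotype_trend(rising, gens)
  expect_gt(tr$slope, 0)
  expect_lt(tr$p, 0.05)
  flat <- setNames(rnorm(50, 5, 0.1), names(gens))
  trf <- phenotype_trend(flat, gens)

  expect_equal(classify_consistency("+", 1.2, tr$slope, tr$p), "consistent")
  expect_equal(classify_consistency("+", -1.2, tr$slope, tr$p),
               "inconsistent")
  expect_equal(classify_consistency("-", -1.2, tr$slope, tr$p), "consistent")
  expect_equal(classify_consistency("+", 1.2, trf$slope, max(trf$p, 0.06)),
               "no-trend")
  expect_error(classify_consistency("+", NA, 1, 0.01), "missing")
})
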