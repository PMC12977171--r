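# BayesB MCMC estimation of founder-haplotype effects at markers, and
# consistency classification between frequency shifts, effect signs and
# phenotype trends.

#' Build the haplotype design for marker regression
#'
#' For each selected marker, builds one-hot maternal and paternal indicator
#' matrices over the labels observed there, plus the combined dosage
#' `d = x + x'` in `{0, 1, 2}` (each individual contributes exactly one
#' maternal and one paternal label, so dosages at a marker sum to 2).
#' Individuals with a missing label at a marker are masked out for that
#' marker; markers with a single observed label carry no contrast and are
#' excluded with a warning.
#'
#' @param mat a `hap_matrix`.
#' @param markers character vector of SNP IDs (default: all loci).
#' @return Object of class `design_tensor`: list with `ids` and per-marker
#'   entries (`snp_id`, `labels`, `X` maternal one-hot, `Xp` paternal,
#'   `D = X + Xp`, `mask` of usable individuals).
#' @export
build_design <- function(mat, markers = NULL) {
  if (is.null(markers)) markers <- mat$loci$snp_id
  idx <- match(markers, mat$loci$snp_id)
  if (anyNA(idx))
    stop("unknown marker(s): ", paste(markers[is.na(idx)], collapse = ", "))
  n <- length(mat$ids)
  entries <- list()
  dropped <- character(0)
  for (j in seq_along(idx)) {
    l <- idx[j]
    a <- mat$A[, l]; b <- mat$B[, l]
    mask <- !is.na(a) & !is.na(b)
    labs <- sort(unique(c(a[mask], b[mask])))
    if (length(labs) < 2L) {
      dropped <- c(dropped, markers[j])
      next
    }
    X <- matrix(0L, n, length(labs), dimnames = list(mat$ids, labs))
    Xp <- X
    X[cbind(which(mask), match(a[mask], labs))] <- 1L
    Xp[cbind(which(mask), match(b[mask], labs))] <- 1L
    entries[[markers[j]]] <- list(snp_id = markers[j], labels = labs,
                                  X = X, Xp = Xp, D = X + Xp, mask = mask)
  }
  if (length(dropped))
    warning("marker(s) with a single observed label excluded: ",
            paste(dropped, collapse = ", "))
  structure(list(ids = mat$ids, markers = entries), class = "design_tensor")
}

#' @export
print.design_tensor <- function(x, ...) {
  cat("Haplotype design:", length(x$markers), "markers,",
      length(x$ids), "individuals\n")
  invisible(x)
}

#' Fit founder-haplotype effects with BayesB
#'
#' Marker-regression model in which the genotypic value is the linear sum of
#' marker effects, `u_i = sum_j gamma_j sum_l (x_ijl + x'_ijl) beta_jl`, with
#' a per-marker inclusion indicator `gamma_j` (prior probability `pi_incl`)
#' and Gaussian haplotype effects `beta_jl ~ N(0, sigma2_beta_j)` sharing a
#' marker-specific variance with a scaled inverse chi-square prior — the
#' BayesB construction, sampled by Gibbs with the indicator drawn from its
#' conditional with the marker's effects integrated out.
#'
#' @param y numeric phenotype vector named by (or aligned to) the design's
#'   individuals; per-cultivar means across years.
#' @param design a [build_design()] result. Individuals with a missing label
#'   at any fitted marker (or missing phenotype) are dropped from the fit.
#' @param pi_incl prior marker-inclusion probability.
#' @param nu degrees of freedom of the scaled-inv-chi-square effect-variance
#'   prior.
#' @param s2_beta prior scale; default set from the phenotypic variance
#'   (`R2 = 0.5` heuristic spread over the expected number of included
#'   dosage contrasts).
#' @param iters,burnin,thin chain length, burn-in and thinning.
#' @param seed integer seed; identical settings and seed give identical
#'   summaries.
#' @return Object of class `bayesb_fit`: `gamma` (posterior inclusion
#'   probability per marker), `beta` (per-marker data.frame with posterior
#'   mean/sd conditional on inclusion and the unconditional `effective`
#'   effect `E[gamma beta]`), `mu`, `sigma2_e`, `settings`, `individuals`.
#' @export
fit_bayesb <- function(y, design, pi_incl = 0.05, nu = 4.2, s2_beta = NULL,
                       iters = 10000L, burnin = 2000L, thin = 10L,
                       seed = 1L) {
  mk <- design$markers
  if (length(mk) < 2L) stop("need at least 2 markers")
  if (iters <= burnin) stop("iters must exceed burnin")
  if (!is.null(names(y))) y <- y[design$ids]
  if (length(y) != length(design$ids))
    stop("phenotypes do not align with design individuals")
  keep <- !is.na(y) & Reduce(`&`, lapply(mk, `[[`, "mask"))
  if (sum(keep) < 10L) stop("fewer than 10 complete observations")
  y <- as.numeric(y[keep])
  if (any(!is.finite(y))) stop("non-finite phenotypes")
  n <- length(y)
  J <- length(mk)

  D <- lapply(mk, function(m) m$D[keep, , drop = FALSE])
  DtD <- lapply(D, crossprod)
  Lj <- vapply(D, ncol, integer(1))

  vy <- stats::var(y)
  if (vy == 0) vy <- 1e-8
  if (is.null(s2_beta)) {
    # mean dosage variance summed over markers; expected model R2 of 0.5
    msx <- sum(vapply(D, function(d) sum(apply(d, 2L, stats::var)), numeric(1)))
    s2_beta <- vy * 0.5 * (nu - 2) / nu / max(pi_incl * msx, 1e-8)
  }
  nu_e <- 5
  s2_e <- vy * 0.5

  set.seed(seed)
  mu <- mean(y)
  beta <- lapply(Lj, numeric)
  delta <- rep(FALSE, J)
  sig2j <- rep(s2_beta, J)
  sig2e <- vy / 2
  e <- y - mu

  n_keep <- (iters - burnin) %/% thin
  sum_delta <- numeric(J)
  sum_beta <- lapply(Lj, numeric)       # conditional on inclusion
  sum_beta2 <- lapply(Lj, numeric)
  n_incl <- numeric(J)
  sum_db <- lapply(Lj, numeric)         # unconditional delta * beta
  sum_mu <- 0; sum_sig2e <- 0
  kept <- 0L

  rinvchisq <- function(df, scale) df * scale / stats::rchisq(1L, df)

  for (it in seq_len(iters)) {
    # intercept
    e <- e + mu
    mu <- stats::rnorm(1L, mean(e), sqrt(sig2e / n))
    e <- e - mu
    for (j in seq_len(J)) {
      if (delta[j]) e <- e + D[[j]] %*% beta[[j]]
      # marker variance from its prior when excluded, else from conditional
      rhs <- crossprod(D[[j]], e) / sig2e
      Aj <- DtD[[j]] / sig2e + diag(1 / sig2j[j], Lj[j])
      ch <- chol(Aj)
      m_j <- backsolve(ch, forwardsolve(t(ch), rhs))
      # log odds of inclusion with beta integrated out
      logodds <- log(pi_incl / (1 - pi_incl)) +
        0.5 * sum(rhs * m_j) -
        sum(log(diag(ch))) - 0.5 * Lj[j] * log(sig2j[j])
      delta[j] <- stats::runif(1L) < 1 / (1 + exp(-logodds))
      if (delta[j]) {
        z <- stats::rnorm(Lj[j])
        beta[[j]] <- as.numeric(m_j + backsolve(ch, z))
        e <- e - D[[j]] %*% beta[[j]]
        sig2j[j] <- rinvchisq(nu + Lj[j],
                              (nu * s2_beta + sum(beta[[j]]^2)) /
                                (nu + Lj[j]))
      } else {
        beta[[j]] <- numeric(Lj[j])
        sig2j[j] <- rinvchisq(nu, s2_beta)
      }
    }
    sig2e <- rinvchisq(nu_e + n, (nu_e * s2_e + sum(e^2)) / (nu_e + n))
    if (it > burnin && (it - burnin) %% thin == 0L) {
      kept <- kept + 1L
      sum_delta <- sum_delta + delta
      sum_mu <- sum_mu + mu
      sum_sig2e <- sum_sig2e + sig2e
      for (j in which(delta)) {
        n_incl[j] <- n_incl[j] + 1
        sum_beta[[j]] <- sum_beta[[j]] + beta[[j]]
        sum_beta2[[j]] <- sum_beta2[[j]] + beta[[j]]^2
      }
      for (j in seq_len(J))
        sum_db[[j]] <- sum_db[[j]] + (if (delta[j]) beta[[j]] else 0)
    }
  }

  beta_out <- lapply(seq_len(J), function(j) {
    m <- if (n_incl[j] > 0) sum_beta[[j]] / n_incl[j] else rep(0, Lj[j])
    v <- if (n_incl[j] > 1)
      pmax(sum_beta2[[j]] / n_incl[j] - m^2, 0) else rep(NA_real_, Lj[j])
    data.frame(snp_id = mk[[j]]$snp_id, label = mk[[j]]$labels,
               post_mean = m, post_sd = sqrt(v),
               effective = sum_db[[j]] / kept,
               stringsAsFactors = FALSE)
  })
  structure(list(
    gamma = stats::setNames(sum_delta / kept, names(mk)),
    beta = stats::setNames(beta_out, names(mk)),
    mu = sum_mu / kept,
    sigma2_e = sum_sig2e / kept,
    settings = list(pi_incl = pi_incl, nu = nu, s2_beta = s2_beta,
                    iters = iters, burnin = burnin, thin = thin, seed = seed),
    individuals = design$ids[keep]),
    class = "bayesb_fit")
}

#' @export
print.bayesb_fit <- function(x, ...) {
  cat("BayesB fit:", length(x$gamma), "markers,",
      length(x$individuals), "individuals\n")
  top <- head(sort(x$gamma, decreasing = TRUE), 5L)
  cat("top inclusion probabilities:\n")
  print(round(top, 3))
  invisible(x)
}

#' Genotypic values under posterior means
#'
#' `u_i = mu + sum_j gamma_hat_j sum_l d_ijl beta_hat_jl` with `beta_hat`
#' the posterior mean conditional on inclusion.
#'
#' @param fit a `bayesb_fit`.
#' @param design the design used for fitting.
#' @return Named numeric vector over the fitted individuals.
#' @export
genotypic_values <- function(fit, design) {
  keep <- match(fit$individuals, design$ids)
  u <- rep(fit$mu, length(keep))
  for (j in names(fit$beta)) {
    b <- fit$beta[[j]]
    u <- u + fit$gamma[j] *
      as.numeric(design$markers[[j]]$D[keep, , drop = FALSE] %*% b$post_mean)
  }
  stats::setNames(u, fit$individuals)
}

#' Generational trend of a phenotype
#'
#' Ordinary least-squares slope of generation-mean phenotype on generation
#' index, with its t-test p-value.
#'
#' @param y named phenotype vector (names = individual IDs).
#' @param generations named generation map.
#' @return List with `slope`, `p`, `means` (per-generation data.frame).
#' @export
phenotype_trend <- function(y, generations) {
  ids <- intersect(names(y)[!is.na(y)], names(generations))
  if (length(ids) < 3L) stop("too few phenotyped individuals with generations")
  g <- generations[ids]
  means <- tapply(y[ids], g, mean)
  gm <- data.frame(generation = as.integer(names(means)),
                   mean = as.numeric(means))
  if (nrow(gm) < 3L) stop("need at least 3 generations for a trend")
  fit <- stats::lm(mean ~ generation, data = gm)
  sm <- summary(fit)$coefficients
  list(slope = unname(coef(fit)["generation"]),
       p = unname(sm["generation", "Pr(>|t|)"]),
       means = gm)
}

#' Classify consistency of a frequency shift with trait change
#'
#' A biased (marker, haplotype) pair is `consistent` when the direction of
#' its frequency change times the sign of its estimated effect matches the
#' direction of the phenotype's generational trend (e.g. an increasing
#' haplotype with a positive effect alongside a rising trait mean);
#' `inconsistent` when it opposes it; `no-trend` when the trend is not
#' significant at `alpha`.
#'
#' @param freq_direction `"+"`/`"-"` (or a signed number) for the haplotype
#'   frequency change.
#' @param effect signed haplotype effect estimate.
#' @param trend_slope,trend_p phenotype trend slope and p-value (see
#'   [phenotype_trend()]).
#' @param alpha trend significance level.
#' @return `"consistent"`, `"inconsistent"` or `"no-trend"`.
#' @export
classify_consistency <- function(freq_direction, effect, trend_slope,
                                 trend_p, alpha = 0.05) {
  if (is.na(effect) || is.na(trend_slope) || is.na(trend_p))
    stop("missing effect or trend")
  fd <- if (is.character(freq_direction))
    switch(freq_direction, "+" = 1, "-" = -1,
           stop("freq_direction must be '+' or '-'"))
  else sign(freq_direction)
  if (trend_p > alpha) return("no-trend")
  if (fd == 0 || effect == 0 || trend_slope == 0) return("no-trend")
  if (fd * sign(effect) == sign(trend_slope)) "consistent" else "inconsistent"
}
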