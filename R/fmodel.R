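#' MCMC settings for the outlier scan
#'
#' Chain-length and prior settings for [run_scan()]. Proposal scales are
#' tuned automatically during `pilot_runs` batches of `pilot_length` sweeps
#' towards a 25-45% acceptance band. The default chain (20 x 1,000 pilot
#' sweeps, 10,000 burn-in, 5,000 samples at thinning 10) is sized for
#' desk-scale panels of a few thousand loci.
#'
#' @param pilot_runs Number of pilot tuning batches.
#' @param pilot_length Sweeps per pilot batch.
#' @param burn_in Sweeps discarded after tuning.
#' @param n_samples Posterior samples retained.
#' @param thinning Sweeps between retained samples.
#' @param prior_odds_neutral Prior odds in favour of excluding each
#'   per-locus selection effect in the reversible-jump move (10 by
#'   convention: selection is a priori rare).
#' @param alpha_prior_sd Standard deviation of the Normal(0, sd) prior on
#'   locus effects alpha; also the reversible-jump birth proposal.
#' @param beta_prior_mean,beta_prior_sd Normal prior on the population
#'   effects beta and group effects beta_ct (logit-scale; the default
#'   Normal(-1, 1) keeps prior F mass at moderate differentiation).
#' @param seed Integer seed driving pilot and main chains.
#' @param n_chains Chains run with derived seeds; posteriors are averaged
#'   and a convergence warning is raised if chains disagree.
#' @return A validated list of class `scan_config`.
#' @export
scan_config <- function(pilot_runs = 20L, pilot_length = 1000L,
                        burn_in = 10000L, n_samples = 5000L, thinning = 10L,
                        prior_odds_neutral = 10, alpha_prior_sd = 1,
                        beta_prior_mean = -1, beta_prior_sd = 1,
                        seed = 1L, n_chains = 1L) {
  cfg <- list(pilot_runs = as.integer(pilot_runs),
              pilot_length = as.integer(pilot_length),
              burn_in = as.integer(burn_in),
              n_samples = as.integer(n_samples),
              thinning = as.integer(thinning),
              prior_odds_neutral = as.numeric(prior_odds_neutral),
              alpha_prior_sd = as.numeric(alpha_prior_sd),
              beta_prior_mean = as.numeric(beta_prior_mean),
              beta_prior_sd = as.numeric(beta_prior_sd),
              seed = as.integer(seed), n_chains = as.integer(n_chains))
  pos <- c("pilot_runs", "pilot_length", "burn_in", "n_samples", "thinning",
           "prior_odds_neutral", "alpha_prior_sd", "beta_prior_sd", "n_chains")
  for (nm in pos) if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0)
    stop("scan_config: `", nm, "` must be positive")
  class(cfg) <- "scan_config"
  cfg
}

#' Remove monomorphic and rare SNPs from a panel
#'
#' Retains loci whose minor-allele frequency in all populations pooled
#' together is at least `min_maf` ("below" the cutoff is discarded, so a
#' pooled MAF exactly at the cutoff is kept). Monomorphic loci are always
#' removed, even at `min_maf = 0`. Locus order is preserved.
#'
#' @param panel An [allele_panel()].
#' @param min_maf Pooled minor-allele-frequency cutoff in `[0, 0.5]`.
#' @return The filtered `allele_panel`.
#' @export
filter_maf <- function(panel, min_maf = 0.05) {
  stopifnot(inherits(panel, "allele_panel"))
  if (min_maf < 0 || min_maf > 0.5) stop("min_maf must lie in [0, 0.5]")
  alt_tot <- rowSums(panel$alt)
  all_tot <- rowSums(panel$ref + panel$alt)
  f <- alt_tot / all_tot
  maf <- pmin(f, 1 - f)
  keep <- maf > 0 & maf >= min_maf
  if (!any(keep)) {
    cond <- simpleError("filter_maf: no locus left after filtering")
    class(cond) <- c("empty_panel_error", class(cond))
    stop(cond)
  }
  allele_panel(panel$map[keep, , drop = FALSE], panel$pops,
               panel$ref[keep, , drop = FALSE],
               panel$alt[keep, , drop = FALSE])
}

#' Beta-binomial log-likelihood for one locus in one group
#'
#' Sum over populations of the beta-binomial log-probability of the
#' observed alternate count out of the total alleles, with shape parameters
#' `theta * p_pool` and `theta * (1 - p_pool)`, where
#' `theta = (1 - F) / F` and `F = plogis(alpha + beta)` per population.
#' This is the exact marginal of a binomial draw whose latent population
#' frequency follows the island-model Beta around the group pool.
#'
#' @param alt,tot Integer vectors of alternate and total allele counts, one
#'   entry per population in the group.
#' @param p_pool Group migrant-pool frequency, strictly inside (0, 1).
#' @param alpha Locus-specific selection effect (0 when excluded).
#' @param beta Population effects, recycled against `alt`.
#' @return The log-likelihood (0 when all totals are 0).
#' @export
locus_loglik <- function(alt, tot, p_pool, alpha, beta) {
  if (any(alt < 0) || any(tot < 0) || any(alt > tot))
    stop("locus_loglik: counts must satisfy 0 <= alt <= tot")
  if (p_pool <= 0 || p_pool >= 1)
    stop("locus_loglik: p_pool must lie strictly inside (0, 1)")
  beta <- rep_len(beta, length(alt))
  f <- stats::plogis(alpha + beta)
  theta <- (1 - f) / f
  s1 <- theta * p_pool
  s2 <- theta * (1 - p_pool)
  ll <- lchoose(tot, alt) + lbeta(s1 + alt, s2 + tot - alt) - lbeta(s1, s2)
  ll[tot == 0] <- 0
  sum(ll)
}

#' Run the reversible-jump MCMC outlier scan
#'
#' Estimates, per locus, the posterior probabilities of the four selection
#' models — neutral, selection in group 1, selection in group 2, selection
#' in both (convergent) — as the visit frequencies of the inclusion
#' configurations of the two per-locus effects alpha, then converts the
#' posterior probability of neutrality to a Bayesian q-value and calls a
#' model per locus at the `fdr` threshold.
#'
#' @param panel An [allele_panel()] with exactly two groups, already passed
#'   through [filter_maf()].
#' @param config A [scan_config()].
#' @param fdr q-value threshold used for the model call (default 0.1).
#' @return Data frame with one row per locus: `snp_id`, `chrom`, `pos`,
#'   `P_neutral`, `P_sel_g1`, `P_sel_g2`, `P_conv`, `alpha_g1`, `alpha_g2`,
#'   `qvalue`, `model_call`. Groups are ordered by first appearance in
#'   `panel$pops`. Attribute `accept` carries final acceptance rates.
#' @export
run_scan <- function(panel, config = scan_config(), fdr = 0.1) {
  stopifnot(inherits(panel, "allele_panel"), inherits(config, "scan_config"))
  groups <- unique(panel$pops$group)
  if (length(groups) != 2L)
    stop("run_scan: the four-model scan needs exactly two groups, got ",
         length(groups))
  gidx <- match(panel$pops$group, groups) - 1L
  storage.mode(panel$alt) <- "integer"
  tot <- panel$ref + panel$alt
  storage.mode(tot) <- "integer"

  gh <- .gauss_hermite(20L)
  one_chain <- function(seed) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    cpp_fmodel_scan(panel$alt, tot, gidx,
                    config$pilot_runs, config$pilot_length,
                    config$burn_in, config$n_samples, config$thinning,
                    config$prior_odds_neutral, config$alpha_prior_sd,
                    config$beta_prior_mean, config$beta_prior_sd,
                    sqrt(2) * config$alpha_prior_sd * gh$nodes, gh$weights)
  }

  seeds <- (config$seed %% 2000000000L) + seq_len(config$n_chains) - 1L
  fits <- lapply(seeds, one_chain)
  post <- Reduce(`+`, lapply(fits, `[[`, "post")) / length(fits)
  amean <- Reduce(`+`, lapply(fits, `[[`, "alpha_mean")) / length(fits)
  if (length(fits) > 1L) {
    pn <- sapply(fits, function(f) f$post[, 1])
    disagreement <- max(apply(pn, 1, function(x) diff(range(x))))
    if (disagreement > 0.15)
      warning(sprintf(paste0("run_scan: chains disagree on P(neutral) by up ",
                             "to %.2f; consider longer chains"), disagreement))
  }

  pep <- post[, 1]
  q <- qvalues_from_posteriors(pep)
  res <- data.frame(
    snp_id = panel$map$snp_id, chrom = panel$map$chrom, pos = panel$map$pos,
    P_neutral = post[, 1], P_sel_g1 = post[, 2],
    P_sel_g2 = post[, 3], P_conv = post[, 4],
    alpha_g1 = amean[, 1], alpha_g2 = amean[, 2],
    qvalue = q, stringsAsFactors = FALSE
  )
  res$model_call <- classify_locus(res, fdr = fdr)
  attr(res, "groups") <- groups
  attr(res, "accept") <- fits[[1]]$accept
  res
}

# Gauss-Hermite nodes/weights for the e^(-x^2) weight via Golub-Welsch;
# weights returned normalised to sum 1 (i.e. divided by sqrt(pi)), so that
# sum(w * f(sqrt(2) * sd * x)) approximates E[f(alpha)] under N(0, sd^2)
.gauss_hermite <- function(n) {
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  o <- order(e$values)
  list(nodes = e$values[o], weights = (e$vectors[1, o])^2)
}

#' Bayesian q-values from posterior error probabilities
#'
#' The posterior error probability (PEP) of a locus is its posterior
#' probability of neutrality. Sorting loci by PEP, the q-value at rank k is
#' the mean of the k smallest PEPs — the expected proportion of false
#' positives if all loci up to rank k are called. Tied PEPs share the
#' larger (most conservative) q. Output is aligned to input order.
#'
#' @param pep Numeric vector of posterior neutrality probabilities in
#'   `[0, 1]`.
#' @return q-values in input order, non-decreasing along the PEP-sorted
#'   order.
#' @export
qvalues_from_posteriors <- function(pep) {
  if (length(pep) == 0L) stop("qvalues_from_posteriors: empty input")
  if (any(!is.finite(pep)) || any(pep < 0) || any(pep > 1))
    stop("qvalues_from_posteriors: PEPs must lie in [0, 1]")
  o <- order(pep)
  q_sorted <- cumsum(pep[o]) / seq_along(pep)
  # the running mean of sorted PEPs is non-decreasing; ties share the
  # larger (last, most conservative) cumulative mean in their tie group
  q_sorted <- stats::ave(q_sorted, pep[o], FUN = max)
  q <- numeric(length(pep))
  q[o] <- q_sorted
  q
}

#' Call the best-supported selection model per locus
#'
#' A locus is neutral unless its q-value is below `fdr`. Among outliers the
#' call is convergent when the both-groups model beats each single-group
#' model, otherwise the better single-group model; an exact tie between the
#' single-group models is broken towards group 1 with a warning.
#'
#' @param posteriors Data frame with columns `P_neutral`, `P_sel_g1`,
#'   `P_sel_g2`, `P_conv`, `qvalue` (one row per locus).
#' @param fdr q-value threshold (strict: `qvalue >= fdr` is neutral).
#' @return Character vector of calls in
#'   `neutral`/`sel_g1`/`sel_g2`/`convergent`.
#' @export
classify_locus <- function(posteriors, fdr = 0.1) {
  need <- c("P_neutral", "P_sel_g1", "P_sel_g2", "P_conv", "qvalue")
  stopifnot(all(need %in% names(posteriors)))
  psum <- rowSums(posteriors[, c("P_neutral", "P_sel_g1", "P_sel_g2", "P_conv")])
  if (any(abs(psum - 1) > 1e-9))
    stop("classify_locus: model probabilities must sum to 1")
  call <- rep("neutral", nrow(posteriors))
  out <- posteriors$qvalue < fdr
  conv <- out & posteriors$P_conv > pmax(posteriors$P_sel_g1, posteriors$P_sel_g2)
  g1 <- out & !conv & posteriors$P_sel_g1 >= posteriors$P_sel_g2
  g2 <- out & !conv & posteriors$P_sel_g1 < posteriors$P_sel_g2
  tie <- out & !conv & posteriors$P_sel_g1 == posteriors$P_sel_g2
  if (any(tie))
    warning("classify_locus: ", sum(tie),
            " locus/loci tie between single-group models; called sel_g1")
  call[conv] <- "convergent"
  call[g1] <- "sel_g1"
  call[g2] <- "sel_g2"
  call
}
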