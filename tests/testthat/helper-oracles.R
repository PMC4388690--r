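# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force loops, quadrature, enumeration.

# beta-binomial log-likelihood by numerical integration of the binomial
# over the latent Beta population frequency
quadrature_loglik <- function(alt, tot, p_pool, alpha, beta) {
  beta <- rep_len(beta, length(alt))
  sum(vapply(seq_along(alt), function(k) {
    if (tot[k] == 0) return(0)
    f <- plogis(alpha + beta[k])
    theta <- (1 - f) / f
    val <- integrate(function(x)
      dbinom(alt[k], tot[k], x) * dbeta(x, theta * p_pool,
                                        theta * (1 - p_pool)),
      0, 1, rel.tol = 1e-12, abs.tol = 1e-300)$value
    log(val)
  }, numeric(1)))
}

# Weir-Cockerham-style per-locus differentiation estimate from allele
# counts (allele-level formulation), one value per locus over a set of
# populations; used as a model-free check on simulated differentiation
wc_fst <- function(alt, tot) {
  r <- ncol(alt)
  vapply(seq_len(nrow(alt)), function(i) {
    n <- tot[i, ]
    p <- alt[i, ] / n
    nbar <- mean(n)
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2) / (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2)
    if (a + b <= 0) NA_real_ else a / (a + b)
  }, numeric(1))
}

# mean within-group differentiation per locus (average of the two groups)
wc_fsc <- function(panel) {
  tot <- panel$ref + panel$alt
  groups <- unique(panel$pops$group)
  f <- sapply(groups, function(g) {
    j <- which(panel$pops$group == g)
    wc_fst(panel$alt[, j, drop = FALSE], tot[, j, drop = FALSE])
  })
  rowMeans(f, na.rm = TRUE)
}

# exhaustive one-sided hypergeometric tail for a 2x2 enrichment table
# [[x, n - x], [K - x, (N - K) - (n - x)]]
hyper_tail <- function(x, n, K, N) {
  ks <- x:min(n, K)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# exact overlap-test p by enumerating every combination of same-size draws
exact_overlap_p <- function(outlier_sets, universes) {
  observed <- length(Reduce(intersect, outlier_sets))
  draws <- lapply(seq_along(universes), function(k) {
    combn(universes[[k]], length(outlier_sets[[k]]), simplify = FALSE)
  })
  grid <- expand.grid(lapply(draws, seq_along))
  hits <- sum(apply(grid, 1, function(ix) {
    inter <- Reduce(intersect, Map(function(d, i) d[[i]], draws, ix))
    length(inter) >= observed
  }))
  hits / nrow(grid)
}

# brute-force window scan: for every grid start on every chromosome,
# collect covered SNPs by a direct interval test and apply the quantile
# and density rules literally
brute_force_windows <- function(map, qvalues, window_bp, step_bp, fdr) {
  out <- list()
  for (ch in unique(map$chrom)) {
    m <- map[map$chrom == ch, ]
    rows <- list()
    for (s in seq(1, max(m$pos), by = step_bp)) {
      ids <- m$snp_id[m$pos >= s & m$pos <= s + window_bp - 1]
      if (!length(ids)) next
      q <- sort(qvalues[ids])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = s, end = s + window_bp - 1,
        n_snps = length(ids), window_q = q[ceiling(0.95 * length(q))],
        stringsAsFactors = FALSE)
    }
    d <- do.call(rbind, rows)
    d$density_ok <- d$n_snps >= 0.2 * mean(d$n_snps)
    d$significant <- d$density_ok & d$window_q < fdr
    out[[ch]] <- d
  }
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  d
}

# small panel builder for targeted fmodel tests
tiny_panel <- function(alt, n_alleles = 60L,
                       groups = c("g1", "g1", "g2", "g2")) {
  L <- nrow(alt)
  map <- data.frame(snp_id = sprintf("s%03d", seq_len(L)),
                    chrom = "chr1", pos = seq_len(L) * 1000L,
                    stringsAsFactors = FALSE)
  pops <- data.frame(pop = paste0("pop", seq_along(groups)), group = groups,
                     stringsAsFactors = FALSE)
  alt <- matrix(as.integer(alt), L, length(groups),
                dimnames = list(map$snp_id, pops$pop))
  ref <- matrix(n_alleles, L, length(groups)) - alt
  dimnames(ref) <- dimnames(alt)
  allele_panel(map, pops, ref, alt)
}
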