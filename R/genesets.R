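#' Gene-level selection scores from SNP posteriors
#'
#' Transforms SNP-based selection probabilities into gene-based scores:
#' for each gene and each model, the score is the highest value among the
#' SNPs assigned to that gene. Models: `af` (selection in group 1), `am`
#' (group 2), `co` (both, convergent), and `sl` (any selection), where a
#' SNP's `sl` value is the sum of its three selection-model probabilities.
#' Genes with no assigned SNP are dropped. Genes are also placed into SNP
#' density bins (quantile bins of the number of assigned SNPs) for the
#' bin-matched null distributions of [test_sets()].
#'
#' @param posteriors Scan result from [run_scan()] (needs `snp_id`,
#'   `P_sel_g1`, `P_sel_g2`, `P_conv`).
#' @param assignment SNP-to-gene assignment from [assign_genes()].
#' @param n_bins Number of SNP-density quantile bins (default 10).
#' @return Data frame `gene_id`, `n_snps`, `p_af`, `p_am`, `p_co`, `p_sl`,
#'   `density_bin`.
#' @export
gene_scores <- function(posteriors, assignment, n_bins = 10L) {
  stopifnot(all(c("snp_id", "P_sel_g1", "P_sel_g2", "P_conv") %in%
                  names(posteriors)),
            all(c("snp_id", "assigned_gene") %in% names(assignment)))
  idx <- match(posteriors$snp_id, assignment$snp_id)
  if (anyNA(idx))
    stop("gene_scores: SNP(s) missing from assignment: ",
         paste(utils::head(posteriors$snp_id[is.na(idx)], 5), collapse = ", "))
  gene <- assignment$assigned_gene[idx]
  keep <- !is.na(gene)
  d <- data.frame(gene_id = gene[keep],
                  p_af = posteriors$P_sel_g1[keep],
                  p_am = posteriors$P_sel_g2[keep],
                  p_co = posteriors$P_conv[keep],
                  stringsAsFactors = FALSE)
  d$p_sl <- d$p_af + d$p_am + d$p_co
  agg <- do.call(rbind, lapply(split(d, d$gene_id), function(x) {
    data.frame(gene_id = x$gene_id[1], n_snps = nrow(x),
               p_af = max(x$p_af), p_am = max(x$p_am),
               p_co = max(x$p_co), p_sl = max(x$p_sl),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg$density_bin <- density_bins(agg$n_snps, n_bins)
  agg
}

# quantile bins of assigned-SNP counts; heavily tied counts collapse bins
density_bins <- function(n_snps, n_bins = 10L) {
  brk <- unique(stats::quantile(n_snps, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(brk) < 2L) return(rep(1L, length(n_snps)))
  as.integer(cut(n_snps, breaks = brk, include.lowest = TRUE))
}

#' Prepare gene sets for the enrichment test
#'
#' Intersects each raw set with the scored-gene universe, drops sets that
#' fall below `min_size` members, and pools (nearly) identical sets —
#' pairs with Jaccard similarity at least `pool_jaccard`, merged
#' transitively — into union sets.
#'
#' @param raw_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param scored_genes Character vector of genes with scores (the
#'   `gene_id` column of [gene_scores()]).
#' @param min_size Minimum set size after intersection (default 10).
#' @param pool_jaccard Jaccard threshold for pooling (default 0.95).
#' @return Named list of character vectors; pooled sets are named by the
#'   joined member ids and carry the originals in attribute `pooled_from`.
#' @export
prepare_sets <- function(raw_sets, scored_genes, min_size = 10L,
                         pool_jaccard = 0.95) {
  if (anyDuplicated(names(raw_sets)))
    stop("prepare_sets: duplicate set ids")
  sets <- lapply(raw_sets, function(s) sort(intersect(unique(s), scored_genes)))
  sets <- sets[lengths(sets) >= min_size]
  n <- length(sets)
  if (n <= 1L) return(sets)

  # union-find over pairs with Jaccard >= threshold
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      if (inter == 0L) next
      jac <- inter / length(union(sets[[i]], sets[[j]]))
      if (jac >= pool_jaccard) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- lapply(split(seq_len(n), roots), function(members) {
    u <- sort(unique(unlist(sets[members])))
    attr(u, "pooled_from") <- names(sets)[members]
    u
  })
  names(out) <- vapply(split(seq_len(n), roots), function(members)
    paste(names(sets)[members], collapse = "+"), character(1))
  # keep original encounter order of the first member of each union
  out[order(vapply(split(seq_len(n), roots), min, integer(1)))]
}

#' SUMSTAT score of a gene set
#'
#' Sum of the member genes' selection scores for one model.
#'
#' @param set Character vector of gene ids.
#' @param scores [gene_scores()] table.
#' @param model One of `"af"`, `"am"`, `"co"`, `"sl"`.
#' @return The SUMSTAT value.
#' @export
sumstat <- function(set, scores, model = c("af", "am", "co", "sl")) {
  model <- match.arg(model)
  col <- paste0("p_", model)
  idx <- match(set, scores$gene_id)
  if (anyNA(idx))
    stop("sumstat: set member(s) without scores: ",
         paste(utils::head(set[is.na(idx)], 5), collapse = ", "))
  sum(scores[[col]][idx])
}

# per-bin member counts of a set, aligned to the universe's bin levels
.bin_counts <- function(set, scores, bins) {
  idx <- match(set, scores$gene_id)
  tabulate(scores$density_bin[idx], nbins = max(bins))
}

# merge bins too small to supply a set's demand into their lower neighbour
.mergeable_bins <- function(scores, need_max) {
  bins <- scores$density_bin
  sizes <- tabulate(bins, nbins = max(bins))
  relabel <- seq_along(sizes)
  for (b in seq_along(sizes)) {
    if (sizes[b] < need_max[b] && b > 1L) {
      relabel[relabel == b] <- b - 1L
      sizes[b - 1L] <- sizes[b - 1L] + sizes[b]
      need_max[b - 1L] <- need_max[b - 1L] + need_max[b]
      sizes[b] <- 0L; need_max[b] <- 0L
    }
  }
  relabel[bins]
}

#' SUMSTAT gene-set test with density-binned sequential nulls
#'
#' For each set and model, compares the observed SUMSTAT with random gene
#' sets matched on the tested set's SNP-density bin composition: each null
#' draw samples, per density bin, the same number of genes (without
#' replacement within a draw) as the set has in that bin. Null sampling is
#' sequential: all sets are first tested against `schedule["init"]` draws;
#' sets whose exceedance count is below `schedule["threshold"]` get
#' `schedule["increment"]` more draws, repeatedly, up to
#' `schedule["max"]`. `p_empirical = (n_exceed + 1) / (n_rand + 1)`; the
#' raw proportion is kept alongside, and q-values per model come from
#' Benjamini-Hochberg over the tested sets.
#'
#' @param sets Named list from [prepare_sets()].
#' @param scores [gene_scores()] table covering all members.
#' @param model Selection score to test (`af`, `am`, `co` or `sl`).
#' @param schedule Named numeric vector `init`, `threshold`, `increment`,
#'   `max` (defaults 10,000 / 5,000 / 10,000 / 500,000).
#' @param seed Integer seed.
#' @return Data frame of class `geneset_result`: `set_id`, `model`,
#'   `n_genes`, `sumstat`, `n_rand`, `n_exceed`, `p_raw`, `p_empirical`,
#'   `q_value`, `significant_10`, `significant_20`.
#' @export
test_sets <- function(sets, scores, model = c("af", "am", "co", "sl"),
                      schedule = c(init = 10000, threshold = 5000,
                                   increment = 10000, max = 500000),
                      seed = 1L) {
  model <- match.arg(model)
  stopifnot(all(c("init", "threshold", "increment", "max") %in% names(schedule)))
  if (length(sets) == 0L)
    return(structure(data.frame(), class = c("geneset_result", "data.frame")))

  # a bin smaller than the largest demand on it cannot supply a null draw:
  # merge it into its neighbour (logged via message)
  nb <- max(scores$density_bin)
  need_max <- Reduce(pmax, lapply(sets, .bin_counts, scores = scores,
                                  bins = scores$density_bin))
  need_max <- c(need_max, rep(0L, nb - length(need_max)))
  sizes <- tabulate(scores$density_bin, nbins = nb)
  if (any(sizes < need_max)) {
    message("test_sets: merging undersized density bin(s) ",
            paste(which(sizes < need_max), collapse = ", "),
            " into lower neighbours")
    scores$density_bin <- .mergeable_bins(scores, need_max)
  }
  col <- paste0("p_", model)
  bin_levels <- sort(unique(scores$density_bin))
  scores$density_bin <- match(scores$density_bin, bin_levels)
  bin_scores <- split(scores[[col]], scores$density_bin)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  obs <- vapply(sets, sumstat, numeric(1), scores = scores, model = model)
  need <- lapply(sets, .bin_counts, scores = scores, bins = scores$density_bin)

  n_rand <- integer(length(sets))
  n_exceed <- integer(length(sets))
  active <- rep(TRUE, length(sets))
  target <- schedule[["init"]]
  while (any(active) && target <= schedule[["max"]]) {
    for (k in which(active)) {
      extra <- target - n_rand[k]
      nulls <- cpp_null_sumstat(bin_scores, need[[k]], as.integer(extra))
      n_exceed[k] <- n_exceed[k] + sum(nulls >= obs[k])
      n_rand[k] <- as.integer(target)
    }
    active <- active & n_exceed < schedule[["threshold"]]
    target <- target + schedule[["increment"]]
  }

  res <- data.frame(
    set_id = names(sets), model = model, n_genes = lengths(sets),
    sumstat = unname(obs), n_rand = n_rand, n_exceed = n_exceed,
    p_raw = n_exceed / n_rand,
    p_empirical = (n_exceed + 1) / (n_rand + 1),
    stringsAsFactors = FALSE)
  res$q_value <- stats::p.adjust(res$p_empirical, method = "BH")
  res$significant_10 <- res$q_value <= 0.10
  res$significant_20 <- res$q_value <= 0.20
  rownames(res) <- NULL
  class(res) <- c("geneset_result", "data.frame")
  res
}

#' Prune shared genes between candidate sets and re-test
#'
#' Removes redundancy among the candidate gene sets (those with
#' pre-pruning q-value at or below `candidate_q`): iteratively the
#' currently best set (smallest empirical p, ties broken by larger
#' SUMSTAT) is frozen, its genes are removed from all remaining
#' candidates, candidates falling below `min_size` are dropped, and the
#' survivors are re-tested against bin-matched nulls of their reduced
#' size. Because pruned tests are no longer independent, q-values are
#' estimated empirically: the identical test-and-prune procedure is run on
#' `n_replicas` score-permuted replicas (gene scores shuffled over the
#' universe), and the q of the observed pruned set at rank r is the mean
#' number of null pruned p-values at or below its p per replica, divided
#' by r (capped at 1 and made monotone in rank).
#'
#' @param results A [test_sets()] result.
#' @param sets The full named set list that was tested.
#' @param scores The [gene_scores()] table used.
#' @param model Model tested.
#' @param schedule Sequential schedule for the pruning re-tests (smaller
#'   than the primary schedule is typical; the pruned p ranks candidates).
#' @param n_replicas Score-permuted replicas for the empirical q
#'   (default 20).
#' @param min_size Minimum surviving set size (default 10).
#' @param candidate_q Pre-pruning q cutoff defining candidates
#'   (default 0.20, the reporting threshold).
#' @param seed Integer seed.
#' @return Data frame: `set_id`, `model`, `rank`, `n_genes_pruned`,
#'   `sumstat_pruned`, `p_pruned`, `q_empirical`, `significant_10`,
#'   `significant_20`; attribute `null_p` keeps the replica p-values.
#'   Zero rows when there is no candidate.
#' @export
prune_and_requalify <- function(results, sets, scores,
                                model = c("af", "am", "co", "sl"),
                                schedule = c(init = 2000, threshold = 1000,
                                             increment = 2000, max = 20000),
                                n_replicas = 20L, min_size = 10L,
                                candidate_q = 0.20, seed = 1L) {
  model <- match.arg(model)
  empty <- data.frame(set_id = character(), model = character(),
                      rank = integer(), n_genes_pruned = integer(),
                      sumstat_pruned = numeric(), p_pruned = numeric(),
                      q_empirical = numeric(), significant_10 = logical(),
                      significant_20 = logical(), stringsAsFactors = FALSE)
  observed <- .prune_pass(results, sets, scores, model, schedule, min_size,
                          candidate_q, seed = seed)
  if (is.null(observed) || nrow(observed) == 0L) return(empty)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 1L)
  col <- paste0("p_", model)
  null_p <- vector("list", n_replicas)
  for (r in seq_len(n_replicas)) {
    perm <- scores
    perm[[col]] <- sample(perm[[col]])
    rep_primary <- test_sets(sets, perm, model, schedule,
                             seed = seed + 1000L + r)
    rep_res <- .prune_pass(rep_primary, sets, perm, model, schedule,
                           min_size, candidate_q, seed = seed + 1L + r)
    null_p[[r]] <- if (is.null(rep_res)) numeric(0) else sort(rep_res$p_pruned)
  }

  # empirical FDR at each observed rank: mean count of null pruned p-values
  # at or below the observed p, per replica, over the observed rank
  q <- vapply(seq_len(nrow(observed)), function(k) {
    p_k <- observed$p_pruned[k]
    exp_false <- mean(vapply(null_p, function(np) sum(np <= p_k), numeric(1)))
    min(1, exp_false / k)
  }, numeric(1))
  observed$q_empirical <- rev(cummin(rev(q)))  # monotone in rank
  observed$significant_10 <- observed$q_empirical <= 0.10
  observed$significant_20 <- observed$q_empirical <= 0.20
  attr(observed, "null_p") <- null_p
  observed
}

# one prune-and-retest pass: freeze best candidate, strip its genes from
# the rest, re-test survivors; returns NULL when there is no candidate
.prune_pass <- function(results, sets, scores, model, schedule, min_size,
                        candidate_q, seed) {
  cand <- results$set_id[results$q_value <= candidate_q]
  if (length(cand) == 0L) return(NULL)
  remaining <- sets[cand]
  res <- results[results$set_id %in% cand, , drop = FALSE]
  taken_genes <- character(0)
  out <- list()
  rank <- 0L
  while (length(remaining) > 0L) {
    o <- order(res$p_empirical, -res$sumstat)
    best <- res$set_id[o[1]]
    rank <- rank + 1L
    out[[rank]] <- data.frame(
      set_id = best, model = model, rank = rank,
      n_genes_pruned = res$n_genes[o[1]],
      sumstat_pruned = res$sumstat[o[1]],
      p_pruned = res$p_empirical[o[1]],
      stringsAsFactors = FALSE)
    taken_genes <- union(taken_genes, remaining[[best]])
    remaining <- remaining[names(remaining) != best]
    remaining <- lapply(remaining, setdiff, y = taken_genes)
    remaining <- remaining[lengths(remaining) >= min_size]
    if (length(remaining) == 0L) break
    res <- test_sets(remaining, scores, model, schedule,
                     seed = seed + rank)
  }
  do.call(rbind, out)
}

#' Edge list of gene-set overlap for graph viewers
#'
#' Connects two sets when at least one of them shares more than
#' `min_share` of its genes with the other.
#'
#' @param sets Named list of gene sets.
#' @param min_share Fraction threshold (default 1/3).
#' @return Data frame `set_a`, `set_b`, `shared_fraction` (the larger of
#'   the two directional fractions).
#' @export
overlap_edges <- function(sets, min_share = 1 / 3) {
  n <- length(sets)
  rows <- list()
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    if (inter == 0L) next
    frac <- max(inter / length(sets[[i]]), inter / length(sets[[j]]))
    if (frac > min_share)
      rows[[length(rows) + 1L]] <- data.frame(
        set_a = names(sets)[i], set_b = names(sets)[j],
        shared_fraction = frac, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(set_a = character(), set_b = character(),
                      shared_fraction = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
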