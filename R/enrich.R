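#' Fisher exact test for genic enrichment of outlier SNPs
#'
#' One-sided (enrichment direction) Fisher exact test on the 2x2 table of
#' outlier/non-outlier against genic/non-genic SNPs over a shared SNP
#' universe.
#'
#' @param outlier,genic Logical vectors aligned to the same SNP universe.
#' @return List of class `enrichment_result`: `table` (2x2 counts),
#'   `odds_ratio` (sample odds ratio), `p_value` (one-sided), `degenerate`
#'   flag (TRUE with `p_value = 1` when a margin is empty or there are no
#'   outliers).
#' @export
genic_fisher <- function(outlier, genic) {
  stopifnot(is.logical(outlier), is.logical(genic),
            length(outlier) == length(genic))
  tab <- matrix(c(sum(outlier & genic), sum(outlier & !genic),
                  sum(!outlier & genic), sum(!outlier & !genic)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("outlier", "non_outlier"),
                                c("genic", "non_genic")))
  res <- list(table = tab, degenerate = FALSE)
  if (sum(outlier) == 0L || all(genic) || !any(genic)) {
    res$odds_ratio <- NA_real_
    res$p_value <- 1
    res$degenerate <- TRUE
    warning("genic_fisher: degenerate 2x2 margins; p set to 1")
  } else {
    ft <- stats::fisher.test(tab, alternative = "greater")
    res$p_value <- ft$p.value
    res$odds_ratio <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  }
  class(res) <- "enrichment_result"
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Genic enrichment (one-sided Fisher): p =", format(x$p_value), "\n")
  print(x$table)
  if (!is.null(x$resampled))
    cat(sprintf("LD-controlled resampling (%d reps): mean p = %.4g, 90%% CI [%.3g, %.3g]\n",
                x$resampled$n_reps, x$resampled$mean_p,
                x$resampled$ci90_low, x$resampled$ci90_high))
  invisible(x)
}

#' LD-controlled resampled Fisher test
#'
#' Physical linkage makes nearby SNPs non-independent, so the plain Fisher
#' test can overstate enrichment. Each chromosome is tiled into disjoint
#' `block_bp` blocks anchored at position 1; each replicate draws at most
#' one outlier and one non-outlier SNP per block uniformly, repeats the
#' one-sided Fisher test on the draw, and the replicate p-values are
#' summarised by their mean and empirical 5%/95% order statistics.
#'
#' @param map SNP map data frame aligned with the flags.
#' @param outlier,genic Logical vectors aligned to `map`.
#' @param block_bp Block size in bp (default 100 kb).
#' @param n_reps Number of resampling replicates.
#' @param seed Integer seed.
#' @return An `enrichment_result` (full-table test) with a `resampled`
#'   element: `n_reps`, `n_skipped`, `mean_p`, `ci90_low`, `ci90_high`,
#'   `p_values`.
#' @export
ld_resampled_fisher <- function(map, outlier, genic, block_bp = 100000,
                                n_reps = 1000, seed = 1L) {
  stopifnot(nrow(map) == length(outlier), length(outlier) == length(genic),
            n_reps >= 1)
  block <- paste0(map$chrom, ":", (map$pos - 1) %/% block_bp)
  out_idx <- split(which(outlier), block[outlier])
  non_idx <- split(which(!outlier), block[!outlier])

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draw_one <- function(idx_list) {
    vapply(idx_list, function(ix) ix[sample.int(length(ix), 1L)], integer(1))
  }
  p <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    take <- c(draw_one(out_idx), draw_one(non_idx))
    o <- outlier[take]; g <- genic[take]
    if (sum(o) == 0L || all(g) || !any(g)) next  # degenerate draw: skip
    tab <- matrix(c(sum(o & g), sum(o & !g), sum(!o & g), sum(!o & !g)),
                  nrow = 2, byrow = TRUE)
    p[r] <- stats::fisher.test(tab, alternative = "greater")$p.value
  }
  ok <- !is.na(p)
  if (!any(ok)) stop("ld_resampled_fisher: every replicate degenerate")
  res <- genic_fisher(outlier, genic)
  ps <- sort(p[ok])
  n_ok <- length(ps)
  res$resampled <- list(
    n_reps = n_reps, n_skipped = n_reps - n_ok,
    mean_p = mean(ps),
    ci90_low = ps[max(1L, ceiling(0.05 * n_ok))],
    ci90_high = ps[ceiling(0.95 * n_ok)],
    p_values = p)
  res
}

#' Permutation test for cross-run outlier overlap
#'
#' The observed statistic is the size of the intersection of the runs'
#' outlier id sets. Each permutation draws, per run independently and
#' without replacement, a uniform random subset of that run's universe of
#' the same size as its outlier set, and intersects the draws. The p-value
#' is the proportion of permutations with overlap at least as large as
#' observed; with zero exceedances only the resolution bound
#' `1 / n_perms` can be reported.
#'
#' @param outlier_sets List of character vectors of outlier ids (one per
#'   run; gene-level overlap uses gene ids the same way).
#' @param universes List of character vectors, each run's full id universe.
#' @param n_perms Number of permutations (default 50,000).
#' @param seed Integer seed.
#' @return List of class `overlap_result`: `observed_overlap`, `n_perms`,
#'   `n_exceed`, `p_value` (= `n_exceed / n_perms`), `p_report` (the string
#'   `"< 1/n_perms"` when `n_exceed` is 0).
#' @export
overlap_permutation <- function(outlier_sets, universes, n_perms = 50000,
                                seed = 1L) {
  stopifnot(length(outlier_sets) == length(universes), length(outlier_sets) >= 2L)
  sizes <- lengths(outlier_sets)
  for (k in seq_along(outlier_sets)) {
    extra <- setdiff(outlier_sets[[k]], universes[[k]])
    if (length(extra))
      stop("overlap_permutation: run ", k, " has outliers outside its universe")
    if (sizes[k] > length(universes[[k]]))
      stop("overlap_permutation: outlier count exceeds universe size in run ", k)
  }
  observed <- length(Reduce(intersect, outlier_sets))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_exceed <- 0L
  for (b in seq_len(n_perms)) {
    draw <- lapply(seq_along(universes), function(k)
      universes[[k]][sample.int(length(universes[[k]]), sizes[k])])
    if (length(Reduce(intersect, draw)) >= observed) n_exceed <- n_exceed + 1L
  }
  p <- n_exceed / n_perms
  structure(list(observed_overlap = observed, n_perms = n_perms,
                 n_exceed = n_exceed, p_value = p,
                 p_report = if (n_exceed == 0L)
                   sprintf("< %g", 1 / n_perms) else format(p)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Observed overlap %d across runs; p %s (%d/%d permutations)\n",
              x$observed_overlap,
              if (x$n_exceed == 0L) x$p_report else paste("=", x$p_report),
              x$n_exceed, x$n_perms))
  invisible(x)
}
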