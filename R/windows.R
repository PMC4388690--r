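#' Build sliding windows over a SNP map
#'
#' Windows of `window_bp` bp advance by `step_bp` bp per chromosome, with
#' the grid anchored at position 1 (starts 1, 1 + step, ...). Only windows
#' containing at least one SNP are emitted; a SNP belongs to every window
#' covering its position.
#'
#' @param map SNP map data frame (`snp_id`, `chrom`, `pos`), sorted by
#'   position within each chromosome.
#' @param window_bp Window width in bp (default 500 kb).
#' @param step_bp Shift increment in bp (default 25 kb).
#' @return Data frame `chrom`, `start`, `end` (1-based inclusive),
#'   `n_snps`, plus a list column `snp_ids`.
#' @export
build_windows <- function(map, window_bp = 500000, step_bp = 25000) {
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(map)),
            window_bp > 0, step_bp > 0)
  unsorted <- tapply(map$pos, map$chrom, is.unsorted)
  if (any(unsorted)) stop("build_windows: map not sorted within chromosome(s) ",
                          paste(names(unsorted)[unsorted], collapse = ", "))
  res <- lapply(split(map, map$chrom), function(m) {
    if (nrow(m) == 0L) return(NULL)
    # windows covering a SNP at pos start at 1 + k*step with
    # pos - window < start <= pos
    k_max <- (max(m$pos) - 1L) %/% step_bp
    starts <- 1 + step_bp * (0:k_max)
    idx <- lapply(starts, function(s)
      which(m$pos >= s & m$pos <= s + window_bp - 1))
    keep <- lengths(idx) > 0L
    data.frame(chrom = m$chrom[1], start = starts[keep],
               end = starts[keep] + window_bp - 1,
               n_snps = lengths(idx)[keep],
               snp_ids = I(lapply(idx[keep], function(i) m$snp_id[i])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Score windows with the 95% quantile of member SNP q-values
#'
#' The window q-value is the nearest-rank 95th percentile (the
#' `ceiling(0.95 n)`-th smallest q among the window's SNPs), so one
#' isolated outlier cannot make a window significant. Windows whose SNP
#' count falls below 20% of their chromosome's average (over emitted
#' windows) are flagged low-density and set non-significant.
#'
#' @param windows Output of [build_windows()].
#' @param qvalues Named numeric vector of per-SNP q-values (names are
#'   `snp_id`s covering every window member).
#' @param fdr Significance threshold on the window q-value (strict).
#' @return `windows` with columns `window_q`, `density_ok`, `significant`
#'   added.
#' @export
score_windows <- function(windows, qvalues, fdr = 0.1) {
  stopifnot(is.numeric(qvalues), !is.null(names(qvalues)))
  missing <- setdiff(unique(unlist(windows$snp_ids)), names(qvalues))
  if (length(missing))
    stop("score_windows: no q-value for SNP(s) ",
         paste(utils::head(missing, 5), collapse = ", "))
  windows$window_q <- vapply(windows$snp_ids, function(ids) {
    q <- sort(qvalues[ids])
    q[ceiling(0.95 * length(q))]
  }, numeric(1))
  avg <- stats::ave(windows$n_snps, windows$chrom, FUN = mean)
  windows$density_ok <- windows$n_snps >= 0.2 * avg
  windows$significant <- windows$density_ok & windows$window_q < fdr
  windows
}

#' Refine an outlier SNP set by the significant windows
#'
#' Keeps only outlier SNPs that lie in at least one significant window;
#' refinement only removes, never adds (isolated outliers and outliers in
#' low-density regions drop out).
#'
#' @param outliers Character vector of outlier SNP ids (q below the scan
#'   threshold).
#' @param windows Scored windows from [score_windows()].
#' @return Character vector, a subset of `outliers`.
#' @export
refine_outliers <- function(outliers, windows) {
  sig <- windows[windows$significant, , drop = FALSE]
  if (nrow(sig) == 0L) return(character(0))
  keep <- unique(unlist(sig$snp_ids))
  outliers[outliers %in% keep]
}

# merge overlapping/abutting significant windows of one run into regions
.merge_significant <- function(windows) {
  sig <- windows[windows$significant, , drop = FALSE]
  if (nrow(sig) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    sig$chrom, IRanges::IRanges(sig$start, sig$end)))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Clusters of outlier SNPs concordant across runs
#'
#' Per run, significant windows are merged into regions; a cluster is a
#' maximal genomic interval covered by regions from at least
#' `runs_required` runs. When per-run refined outlier SNP maps are
#' supplied, each cluster's reported span runs from the first to the last
#' supporting outlier SNP inside the covered interval (the merged-window
#' bounds are kept as `win_start`/`win_end`); otherwise the window bounds
#' are reported. `length_kb = (end - start) / 1000`, rounded to 1 decimal.
#'
#' @param window_runs Named list of scored window tables (one per run).
#' @param runs_required Minimum number of runs whose regions must cover a
#'   position (default: all runs).
#' @param outlier_runs Optional named list (same names) of data frames
#'   `snp_id`, `chrom`, `pos` with each run's refined outlier SNPs.
#' @return Data frame `chrom`, `start`, `end`, `length_kb`, `n_runs`,
#'   `runs_supporting`, `win_start`, `win_end`, `snp_ids` (list column).
#' @export
concordant_clusters <- function(window_runs, runs_required = length(window_runs),
                                outlier_runs = NULL) {
  stopifnot(length(window_runs) >= 1L, runs_required >= 1L,
            runs_required <= length(window_runs))
  if (is.null(names(window_runs)))
    names(window_runs) <- paste0("run", seq_along(window_runs))
  regions <- lapply(window_runs, .merge_significant)
  grl <- lapply(regions, function(r)
    GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$start, r$end)))
  all_gr <- do.call(c, unname(grl))
  if (length(all_gr) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      length_kb = numeric(), n_runs = integer(),
                      runs_supporting = character(), stringsAsFactors = FALSE))
  }
  cov_ok <- IRanges::slice(GenomicRanges::coverage(all_gr),
                           lower = runs_required, rangesOnly = TRUE)
  cl <- GenomicRanges::GRanges(cov_ok)
  if (length(cl) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      length_kb = numeric(), n_runs = integer(),
                      runs_supporting = character(), stringsAsFactors = FALSE))
  }

  hit_mat <- sapply(grl, function(g)
    seq_along(cl) %in% S4Vectors::queryHits(GenomicRanges::findOverlaps(cl, g)))
  hit_mat <- matrix(hit_mat, nrow = length(cl),
                    dimnames = list(NULL, names(window_runs)))

  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(cl)),
    win_start = GenomicRanges::start(cl), win_end = GenomicRanges::end(cl),
    stringsAsFactors = FALSE)
  out$n_runs <- rowSums(hit_mat)
  out$runs_supporting <- apply(hit_mat, 1, function(h)
    paste(colnames(hit_mat)[h], collapse = ","))

  out$start <- out$win_start
  out$end <- out$win_end
  out$snp_ids <- vector("list", nrow(out))
  if (!is.null(outlier_runs)) {
    snp <- do.call(rbind, lapply(names(outlier_runs), function(r) {
      d <- outlier_runs[[r]]
      if (is.null(d) || nrow(d) == 0L) return(NULL)
      data.frame(run = r, snp_id = d$snp_id, chrom = d$chrom, pos = d$pos,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(snp)) {
      bad <- setdiff(unique(snp$chrom), unique(unlist(lapply(window_runs,
                                                             `[[`, "chrom"))))
      if (length(bad))
        stop("concordant_clusters: outlier chromosome(s) unknown to windows: ",
             paste(bad, collapse = ", "))
      for (k in seq_len(nrow(out))) {
        sup <- strsplit(out$runs_supporting[k], ",")[[1]]
        m <- snp$run %in% sup & snp$chrom == out$chrom[k] &
          snp$pos >= out$win_start[k] & snp$pos <= out$win_end[k]
        if (any(m)) {
          out$start[k] <- min(snp$pos[m])
          out$end[k] <- max(snp$pos[m])
          out$snp_ids[[k]] <- sort(unique(snp$snp_id[m]))
        }
      }
    }
  }
  out$length_kb <- cluster_span_kb(out$start, out$end)
  out[, c("chrom", "start", "end", "length_kb", "n_runs", "runs_supporting",
          "win_start", "win_end", "snp_ids")]
}

#' Cluster span in kb
#'
#' Span between the first and last supporting SNP position, in kb rounded
#' to one decimal: `round((end - start) / 1000, 1)`.
#'
#' @param start,end 1-based positions of the first and last supporting SNP.
#' @return Numeric vector of spans in kb.
#' @export
cluster_span_kb <- function(start, end) {
  if (any(end < start)) stop("cluster_span_kb: end < start")
  round((end - start) / 1000, 1)
}
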