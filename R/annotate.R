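#' Assign SNPs to their nearest gene within a distance cutoff
#'
#' A SNP inside a gene span is assigned to that gene at distance 0;
#' otherwise it is assigned to the closest gene whose gap is at most
#' `max_dist` bp. SNPs with no gene in range stay unassigned. A SNP covered
#' by several overlapping genes goes to the gene whose midpoint is nearest;
#' ties at exactly equal gap distance are broken towards the gene with the
#' smaller start.
#'
#' Coordinates: the SNP map is 1-based, gene intervals follow the BED
#' convention (0-based half-open). The distance between a SNP and an
#' interval is the number of bases strictly between them (0 when covered).
#'
#' @param map SNP map data frame (`snp_id`, `chrom`, `pos`).
#' @param genes Gene data frame in BED convention (`chrom`, `start`, `end`,
#'   `name`); one row per gene, outermost span for multi-location genes.
#' @param max_dist Maximum assignment distance in bp (default 50 kb); a gap
#'   of exactly `max_dist` is still assigned.
#' @return Data frame `snp_id`, `assigned_gene` (NA when unassigned),
#'   `distance_bp`, `genic` (TRUE iff assigned), in map order.
#' @export
assign_genes <- function(map, genes, max_dist = 50000) {
  stopifnot(is.data.frame(map), all(c("snp_id", "chrom", "pos") %in% names(map)))
  stopifnot(is.data.frame(genes),
            all(c("chrom", "start", "end", "name") %in% names(genes)))
  if (any(genes$start >= genes$end)) stop("gene with start >= end")
  if (anyDuplicated(genes$name)) stop("duplicate gene ids")

  snp_gr <- GenomicRanges::GRanges(map$chrom,
                                   IRanges::IRanges(map$pos, map$pos))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start + 1L, genes$end))

  assigned <- rep(NA_character_, nrow(map))
  dist_bp <- rep(NA_real_, nrow(map))

  # containment first: among covering genes, nearest midpoint, then start
  ov <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  if (length(ov)) {
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    mid <- (genes$start[sh] + genes$end[sh]) / 2
    o <- order(qh, abs(map$pos[qh] - mid), genes$start[sh])
    keep <- !duplicated(qh[o])
    assigned[qh[o][keep]] <- genes$name[sh[o][keep]]
    dist_bp[qh[o][keep]] <- 0
  }

  todo <- which(is.na(assigned))
  if (length(todo)) {
    # rank candidate genes per SNP by (gap, gene start) and keep the best
    # within max_dist; distanceToNearest alone cannot apply the start tie-break
    hits <- GenomicRanges::findOverlaps(snp_gr[todo], gene_gr,
                                        maxgap = max_dist)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      d <- GenomicRanges::distance(snp_gr[todo][qh], gene_gr[sh])
      o <- order(qh, d, genes$start[sh])
      keep <- !duplicated(qh[o])
      sel_q <- todo[qh[o][keep]]
      assigned[sel_q] <- genes$name[sh[o][keep]]
      dist_bp[sel_q] <- d[o][keep]
    }
  }

  data.frame(snp_id = map$snp_id,
             assigned_gene = assigned,
             distance_bp = dist_bp,
             genic = !is.na(assigned),
             stringsAsFactors = FALSE)
}

#' Distance from each SNP to its nearest regulatory interval
#'
#' @param map SNP map data frame (`snp_id`, `chrom`, `pos`, 1-based).
#' @param regulatory Data frame in BED convention (`chrom`, `start`, `end`).
#' @return Data frame `snp_id`, `nearest_regulatory_distance_bp` (0 when
#'   the SNP is covered; NA when the interval table is empty or the SNP's
#'   chromosome has no interval).
#' @export
nearest_regulatory <- function(map, regulatory) {
  stopifnot(is.data.frame(map), all(c("snp_id", "chrom", "pos") %in% names(map)))
  out <- data.frame(snp_id = map$snp_id,
                    nearest_regulatory_distance_bp = NA_real_,
                    stringsAsFactors = FALSE)
  if (is.null(regulatory) || nrow(regulatory) == 0L) return(out)
  if (any(regulatory$start >= regulatory$end)) stop("interval with start >= end")
  snp_gr <- GenomicRanges::GRanges(map$chrom,
                                   IRanges::IRanges(map$pos, map$pos))
  reg_gr <- GenomicRanges::GRanges(regulatory$chrom,
                                   IRanges::IRanges(regulatory$start + 1L,
                                                    regulatory$end))
  nearest <- GenomicRanges::distanceToNearest(snp_gr, reg_gr)
  out$nearest_regulatory_distance_bp[S4Vectors::queryHits(nearest)] <-
    as.numeric(S4Vectors::mcols(nearest)$distance)
  out
}

#' Attach functional classes from an optional lookup table
#'
#' A passive join of dbSNP-style consequence classes; SNPs absent from the
#' table get class `"none"`.
#'
#' @param annotation Output of [assign_genes()].
#' @param functional Optional data frame `snp_id`, `functional_class` with
#'   classes among missense/nonsense/frameshift/splice_site; `NULL` for none.
#' @return `annotation` with a `functional_class` column added.
#' @export
attach_functional <- function(annotation, functional = NULL) {
  classes <- c("missense", "nonsense", "frameshift", "splice_site", "none")
  annotation$functional_class <- "none"
  if (!is.null(functional) && nrow(functional)) {
    stopifnot(all(c("snp_id", "functional_class") %in% names(functional)))
    bad <- setdiff(unique(functional$functional_class), classes)
    if (length(bad)) stop("unknown functional class: ", paste(bad, collapse = ", "))
    idx <- match(annotation$snp_id, functional$snp_id)
    hit <- !is.na(idx)
    annotation$functional_class[hit] <- functional$functional_class[idx[hit]]
  }
  annotation
}
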