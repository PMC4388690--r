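#' Published reference values from the HGDP convergent-selection scan
#'
#' Summary numbers reported by the original genome-wide scan of
#' tropical-forest versus non-forest HGDP populations, kept here as
#' arithmetic fixtures: SNP filter bookkeeping, per-population-set filtered
#' SNP totals and outlier counts, the gene-universe bookkeeping, and the
#' hg19 coordinates and printed sizes of the seven outlier-SNP clusters
#' concordant across all four population sets. The pipeline never consumes
#' these as inputs; they anchor consistency checks on the arithmetic the
#' pipeline performs (outlier fractions, cluster spans, filter counts,
#' permutation resolution).
#'
#' @return A list:
#' \describe{
#'   \item{snp_total}{SNPs on the genotyping array (660,918).}
#'   \item{snp_monomorphic}{monomorphic markers discarded (250).}
#'   \item{snp_retained}{markers retained (660,668).}
#'   \item{ps}{data frame per population set: `label`, `n_filtered` (after
#'     the per-set 5% MAF filter), `n_outliers` (q < 0.1).}
#'   \item{gene_universe}{protein-coding genes considered (19,683).}
#'   \item{genes_unassigned}{genes with no SNP assigned (1,922).}
#'   \item{genes_scored}{genes with at least one SNP (17,761).}
#'   \item{clusters}{data frame per concordant cluster: `cluster`, `chrom`,
#'     `start`, `end` (1-based hg19 SNP positions), `printed_kb` (the size
#'     as published), `consistent` (FALSE for cluster 4, whose printed size
#'     does not match its printed coordinates).}
#'   \item{overlap_n_perms}{permutations used in the published overlap test
#'     (50,000).}
#' }
#' @export
reference_values <- function() {
  list(
    snp_total = 660918L,
    snp_monomorphic = 250L,
    snp_retained = 660668L,
    ps = data.frame(
      label = c("PS1", "PS2", "PS3", "PS4"),
      n_filtered = c(582074L, 581855L, 584205L, 577345L),
      n_outliers = c(1482L, 1222L, 1579L, 1365L),
      stringsAsFactors = FALSE),
    gene_universe = 19683L,
    genes_unassigned = 1922L,
    genes_scored = 17761L,
    clusters = data.frame(
      cluster = 1:7,
      chrom = c("chr1", "chr2", "chr4", "chr4", "chr5", "chr6", "chr7"),
      start = c(53476720, 184608065, 48960613, 52758044, 43497655,
                122738019, 72722731),
      end = c(53520376, 184633769, 48972901, 52935931, 43862944,
              122869764, 72750595),
      printed_kb = c(43.7, 25.7, 12.3, 117.9, 365.3, 131.7, 27.9),
      consistent = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
      stringsAsFactors = FALSE),
    overlap_n_perms = 50000L
  )
}

#' Outlier fractions per population set
#'
#' Percentage of analysed SNPs called outliers, `100 * n_outliers /
#' n_filtered`, rounded to `digits` decimals.
#'
#' @param n_outliers,n_filtered Integer vectors (recycled together).
#' @param digits Decimals to round to (default 2, the published precision).
#' @return Numeric vector of percentages.
#' @export
outlier_fraction_pct <- function(n_outliers, n_filtered, digits = 2) {
  if (any(n_filtered <= 0)) stop("n_filtered must be positive")
  round(100 * n_outliers / n_filtered, digits)
}
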