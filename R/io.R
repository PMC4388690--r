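#' @useDynLib convergescan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# One TSV dialect throughout: tab-separated, header, no quoting.
.read_tsv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "")
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  d
}

.write_tsv <- function(d, path) {
  # list columns (snp_ids and the like) are flattened to comma strings
  for (nm in names(d)) if (is.list(d[[nm]]))
    d[[nm]] <- vapply(d[[nm]], function(x)
      paste(x, collapse = ","), character(1))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an allele-count table
#'
#' Long TSV with columns `snp_id`, `pop`, `ref_count`, `alt_count`; every
#' locus needs a row for every population.
#'
#' @param counts_path Path to the counts TSV.
#' @param map_path Path to the SNP map TSV (`snp_id`, `chrom`, `pos`,
#'   1-based).
#' @param design_path Path to the design TSV (`pop`, `group`).
#' @return An [allele_panel()].
#' @export
read_panel <- function(counts_path, map_path, design_path) {
  counts <- .read_tsv(counts_path, c("snp_id", "pop", "ref_count", "alt_count"))
  map <- read_snp_map(map_path)
  design <- .read_tsv(design_path, c("pop", "group"))
  if (anyDuplicated(design$pop)) stop(design_path, ": duplicate population ids")

  unmapped <- setdiff(unique(counts$snp_id), map$snp_id)
  if (length(unmapped))
    stop(counts_path, ": counts reference unmapped SNP id(s): ",
         paste(utils::head(unmapped, 5), collapse = ", "))
  unknown_pop <- setdiff(unique(counts$pop), design$pop)
  if (length(unknown_pop))
    stop(counts_path, ": unknown population(s): ",
         paste(unknown_pop, collapse = ", "))

  map <- map[map$snp_id %in% counts$snp_id, , drop = FALSE]
  li <- match(counts$snp_id, map$snp_id)
  pj <- match(counts$pop, design$pop)
  ref <- matrix(NA_integer_, nrow(map), nrow(design),
                dimnames = list(map$snp_id, design$pop))
  alt <- ref
  ref[cbind(li, pj)] <- as.integer(counts$ref_count)
  alt[cbind(li, pj)] <- as.integer(counts$alt_count)
  if (anyNA(ref) || anyNA(alt)) {
    hole <- which(is.na(ref), arr.ind = TRUE)[1, ]
    stop(counts_path, ": no counts for locus ", rownames(ref)[hole[1]],
         " in population ", colnames(ref)[hole[2]])
  }
  allele_panel(map, design, ref, alt)
}

#' Read a SNP map
#'
#' Tab-separated `snp_id chrom pos` with 1-based positions, sorted by
#' position within chromosome on return.
#'
#' @param path Path to the map TSV.
#' @return Data frame `snp_id`, `chrom`, `pos`.
#' @export
read_snp_map <- function(path) {
  map <- .read_tsv(path, c("snp_id", "chrom", "pos"))
  if (anyDuplicated(map$snp_id)) stop(path, ": duplicate snp_id")
  if (any(map$pos < 1)) stop(path, ": positions must be 1-based (>= 1)")
  map[order(map$chrom, map$pos), , drop = FALSE]
}

#' Read a BED file of genomic intervals
#'
#' 0-based half-open intervals via `rtracklayer`; malformed intervals
#' (start >= end) are rejected with their location.
#'
#' @param path Path to the BED file.
#' @return Data frame `chrom`, `start` (0-based), `end` (exclusive),
#'   `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  bad <- which(raw[[2]] >= raw[[3]])
  if (length(bad))
    stop(path, ": start >= end at line ", bad[1])
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else
               sprintf("iv%05d", seq_along(gr)),
             stringsAsFactors = FALSE)
}

#' Write intervals as BED
#'
#' @param d Data frame `chrom`, `start` (0-based), `end`, `name`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(d, path) {
  gr <- GenomicRanges::GRanges(d$chrom,
                               IRanges::IRanges(d$start + 1L, d$end),
                               name = d$name)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path Path to the GMT file (set id, description, member genes,
#'   tab-separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) stop(path, ": duplicate set ids")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions
#'   (defaults to the set ids).
#' @return The path, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  if (anyDuplicated(names(sets))) stop("write_gmt: duplicate set ids")
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated panel and its companions to a directory
#'
#' Emits the allele-count TSV (`snp_id, pop, ref_count, alt_count`), SNP
#' map TSV, design TSV, truth TSV, gene and regulatory BED files and the
#' gene-set GMT — the exact dialects [read_panel()] and friends read back.
#'
#' @param sim Result of [simulate_panel()].
#' @param annotation Result of [simulate_annotation()].
#' @param sets Result of [simulate_gene_sets()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_simulation <- function(sim, annotation, sets, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  panel <- sim$panel
  long <- data.frame(
    snp_id = rep(panel$map$snp_id, times = nrow(panel$pops)),
    pop = rep(panel$pops$pop, each = nrow(panel$map)),
    ref_count = as.vector(panel$ref),
    alt_count = as.vector(panel$alt), stringsAsFactors = FALSE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    map = file.path(dir, "snp_map.tsv"),
    design = file.path(dir, "design.tsv"),
    truth = file.path(dir, "truth.tsv"),
    genes = file.path(dir, "genes.bed"),
    regulatory = file.path(dir, "regulatory.bed"),
    gmt = file.path(dir, "gene_sets.gmt"))
  .write_tsv(long, paths["counts"])
  .write_tsv(panel$map, paths["map"])
  .write_tsv(panel$pops, paths["design"])
  .write_tsv(sim$truth, paths["truth"])
  write_bed(annotation$genes, paths["genes"])
  write_bed(annotation$regulatory, paths["regulatory"])
  write_gmt(sets, paths["gmt"])
  paths
}
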