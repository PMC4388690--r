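#' Simulation settings for a synthetic scan experiment
#'
#' Collects the generative parameters of the hierarchical island model used
#' to simulate allele-count panels, together with the layout of the
#' synthetic genome annotation (genes, regulatory intervals) and gene sets.
#'
#' The generative hierarchy deliberately matches the inference model: for
#' each locus an ancestral frequency is drawn uniformly; each group's
#' migrant-pool frequency is a Beta draw centred on it with dispersion
#' `(1 - F_CT) / F_CT` where `logit(F_CT) = beta_ct`; each population's
#' frequency is a Beta draw centred on its group pool with dispersion
#' `(1 - F) / F` where `logit(F) = alpha_g + beta_pop`; observed alternate
#' counts are binomial out of `2 * sample_size_per_pop` alleles. Loci
#' selected in a group receive `alpha_g = alpha_effect` there, so that
#' parameter recovery by the scan is a clean calibration surface.
#'
#' @param n_loci Number of biallelic SNP loci.
#' @param n_chromosomes Number of chromosomes the loci are spread over.
#' @param chrom_length_bp Length of each chromosome in bp.
#' @param groups Character vector of exactly two group (continent) labels.
#' @param pops_per_group Populations sampled per group.
#' @param sample_size_per_pop Diploid individuals per population.
#' @param beta_pop Population-specific logit-F_SC baseline shared by all
#'   loci (drift/demography); `plogis(beta_pop)` is the neutral F_SC.
#' @param beta_ct Group-level logit-F_CT divergence effect.
#' @param prop_selected_g1,prop_selected_g2,prop_selected_both Fractions of
#'   loci under selection in group 1 only, group 2 only, or both groups
#'   (convergent). Must sum to at most 1.
#' @param alpha_effect Locus-specific selection effect added on the logit
#'   scale in the designated group(s) of selected loci.
#' @param n_genes Genes tiled (without overlap) across the chromosomes.
#' @param gene_length_bp Length of each synthetic gene in bp.
#' @param n_gene_sets Number of gene sets to simulate.
#' @param genes_per_set Members per gene set.
#' @param n_planted_sets Sets preferentially built from genes that harbour
#'   truly selected SNPs (planted enrichment signal).
#' @param seed Integer seed; fully determines all simulated output.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 2000L,
                       n_chromosomes = 4L,
                       chrom_length_bp = 5e7,
                       groups = c("africa", "america"),
                       pops_per_group = 2L,
                       sample_size_per_pop = 30L,
                       beta_pop = -2,
                       beta_ct = -2,
                       prop_selected_g1 = 0.02,
                       prop_selected_g2 = 0.02,
                       prop_selected_both = 0.01,
                       alpha_effect = 2.5,
                       n_genes = 600L,
                       gene_length_bp = 20000L,
                       n_gene_sets = 200L,
                       genes_per_set = 25L,
                       n_planted_sets = 3L,
                       seed = 1L) {
  cfg <- list(
    n_loci = as.integer(n_loci), n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp), groups = as.character(groups),
    pops_per_group = as.integer(pops_per_group),
    sample_size_per_pop = as.integer(sample_size_per_pop),
    beta_pop = as.numeric(beta_pop), beta_ct = as.numeric(beta_ct),
    prop_selected_g1 = prop_selected_g1, prop_selected_g2 = prop_selected_g2,
    prop_selected_both = prop_selected_both,
    alpha_effect = as.numeric(alpha_effect),
    n_genes = as.integer(n_genes), gene_length_bp = as.integer(gene_length_bp),
    n_gene_sets = as.integer(n_gene_sets),
    genes_per_set = as.integer(genes_per_set),
    n_planted_sets = as.integer(n_planted_sets), seed = as.integer(seed)
  )
  counts <- c("n_loci", "n_chromosomes", "chrom_length_bp", "pops_per_group",
              "sample_size_per_pop", "n_genes", "gene_length_bp",
              "n_gene_sets", "genes_per_set")
  for (nm in counts) {
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop("sim_config: `", nm, "` must be a single positive number")
  }
  if (length(cfg$groups) != 2L) stop("sim_config: exactly two groups required")
  props <- c(cfg$prop_selected_g1, cfg$prop_selected_g2, cfg$prop_selected_both)
  if (any(props < 0) || any(props > 1))
    stop("sim_config: selected fractions must lie in [0, 1]")
  if (sum(props) > 1)
    stop("sim_config: selected fractions sum to more than 1")
  if (cfg$n_planted_sets > cfg$n_gene_sets)
    stop("sim_config: n_planted_sets exceeds n_gene_sets")
  class(cfg) <- "sim_config"
  cfg
}

# Seed sub-streams: the SNP map must be identical between simulate_panel()
# and simulate_annotation(), so each simulated component draws from its own
# deterministic offset of the master seed (kept below 2^31).
.sim_seed <- function(config, component) {
  offset <- c(map = 11L, panel = 23L, genes = 37L, regulatory = 41L,
              sets = 53L)[[component]]
  (config$seed %% 2000000000L) + offset
}

.sim_map <- function(config) {
  withr_seed <- .sim_seed(config, "map")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(withr_seed)
  chrom <- sort(rep_len(seq_len(config$n_chromosomes), config$n_loci))
  pos <- unlist(lapply(split(chrom, chrom), function(x) {
    sort(sample.int(config$chrom_length_bp, length(x), replace = FALSE))
  }), use.names = FALSE)
  data.frame(
    snp_id = sprintf("snp%05d", seq_len(config$n_loci)),
    chrom = paste0("chr", chrom),
    pos = pos,
    stringsAsFactors = FALSE
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate an allele-count panel under the hierarchical island model
#'
#' Draws, per locus, an ancestral frequency, group migrant-pool frequencies,
#' population frequencies and binomial allele counts as described in
#' [sim_config()]. A fraction of loci carries a locus-specific selection
#' effect `alpha_effect` in one or both groups; the returned truth table
#' records each locus's true model label and per-group effects.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `panel` (an `allele_panel`; see
#'   [allele_panel()]) and `truth` (data frame `snp_id`, `label`,
#'   `alpha_g1`, `alpha_g2`, with `label` in
#'   `neutral`/`sel_g1`/`sel_g2`/`convergent`).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  map <- .sim_map(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.sim_seed(config, "panel"))

  L <- config$n_loci
  G <- 2L
  J <- G * config$pops_per_group
  pops <- data.frame(
    pop = paste0(rep(config$groups, each = config$pops_per_group),
                 "_pop", rep(seq_len(config$pops_per_group), times = G)),
    group = rep(config$groups, each = config$pops_per_group),
    stringsAsFactors = FALSE
  )

  # truth labels
  n_g1 <- round(config$prop_selected_g1 * L)
  n_g2 <- round(config$prop_selected_g2 * L)
  n_co <- round(config$prop_selected_both * L)
  lab <- rep("neutral", L)
  picked <- sample.int(L, n_g1 + n_g2 + n_co)
  lab[picked[seq_len(n_g1)]] <- "sel_g1"
  lab[picked[n_g1 + seq_len(n_g2)]] <- "sel_g2"
  lab[picked[n_g1 + n_g2 + seq_len(n_co)]] <- "convergent"
  a1 <- ifelse(lab %in% c("sel_g1", "convergent"), config$alpha_effect, 0)
  a2 <- ifelse(lab %in% c("sel_g2", "convergent"), config$alpha_effect, 0)
  # labels must stay consistent with which alpha is nonzero: when
  # alpha_effect == 0 the loci are selected in name only (null calibration)
  truth <- data.frame(snp_id = map$snp_id, label = lab,
                      alpha_g1 = a1, alpha_g2 = a2, stringsAsFactors = FALSE)

  f_ct <- stats::plogis(config$beta_ct)
  theta_ct <- (1 - f_ct) / f_ct
  n_alleles <- 2L * config$sample_size_per_pop

  p_anc <- stats::runif(L)
  alt <- matrix(0L, L, J, dimnames = list(map$snp_id, pops$pop))
  alpha_mat <- cbind(a1, a2)
  for (g in seq_len(G)) {
    p_pool <- stats::rbeta(L, theta_ct * p_anc, theta_ct * (1 - p_anc))
    p_pool <- pmin(pmax(p_pool, 1e-12), 1 - 1e-12)
    for (k in seq_len(config$pops_per_group)) {
      j <- (g - 1L) * config$pops_per_group + k
      f <- stats::plogis(alpha_mat[, g] + config$beta_pop)
      theta <- (1 - f) / f
      p_pop <- stats::rbeta(L, theta * p_pool, theta * (1 - p_pool))
      p_pop <- pmin(pmax(p_pop, 0), 1)
      alt[, j] <- stats::rbinom(L, n_alleles, p_pop)
    }
  }
  ref <- matrix(n_alleles, L, J) - alt
  dimnames(ref) <- dimnames(alt)

  panel <- allele_panel(map, pops, ref, alt)
  list(panel = panel, truth = truth)
}

#' Construct an allele-count panel
#'
#' The panel is the scan's observed data: a SNP map, a population-to-group
#' design, and per-(locus, population) reference/alternate allele counts.
#'
#' @param map Data frame `snp_id`, `chrom`, `pos` (1-based).
#' @param pops Data frame `pop`, `group`.
#' @param ref,alt Integer matrices, loci x populations.
#' @return An object of class `allele_panel`.
#' @export
allele_panel <- function(map, pops, ref, alt) {
  stopifnot(is.data.frame(map), all(c("snp_id", "chrom", "pos") %in% names(map)),
            is.data.frame(pops), all(c("pop", "group") %in% names(pops)),
            is.matrix(ref), is.matrix(alt),
            nrow(ref) == nrow(map), ncol(ref) == nrow(pops),
            all(dim(ref) == dim(alt)))
  if (any(ref < 0) || any(alt < 0)) stop("allele counts must be non-negative")
  if (anyDuplicated(map$snp_id)) stop("duplicate snp_id in map")
  tot <- ref + alt
  if (any(rowSums(tot) == 0))
    stop("every locus needs counts in at least one population")
  structure(list(map = map, pops = pops,
                 ref = ref, alt = alt),
            class = "allele_panel")
}

#' @export
print.allele_panel <- function(x, ...) {
  cat("allele_panel:", nrow(x$map), "loci,", nrow(x$pops), "populations (",
      paste(unique(x$pops$group), collapse = " / "), ")\n")
  invisible(x)
}

#' Number of loci in a panel
#' @param panel An `allele_panel`.
#' @return Integer count of loci.
#' @export
n_loci <- function(panel) nrow(panel$map)

#' Simulate a genome annotation matching a panel
#'
#' Places `n_genes` non-overlapping genes per genome with variable
#' inter-gene gaps (so that per-gene SNP densities vary), scatters
#' regulatory intervals (some of which cover SNPs), and emits the same SNP
#' map that [simulate_panel()] uses for the same config.
#'
#' @param config A [sim_config()] object.
#' @return A list with `genes` and `regulatory` (data frames in BED
#'   convention: `chrom`, `start` 0-based, `end` exclusive, `name`) and
#'   `map` (the SNP map, 1-based positions).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  map <- .sim_map(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  per_chrom <- diff(floor(seq(0, config$n_genes,
                              length.out = config$n_chromosomes + 1L)))
  if (any(per_chrom * config$gene_length_bp > config$chrom_length_bp))
    stop("simulate_annotation: genes do not fit on chromosome (",
         max(per_chrom), " x ", config$gene_length_bp, " bp > ",
         config$chrom_length_bp, " bp)")

  set.seed(.sim_seed(config, "genes"))
  genes <- do.call(rbind, lapply(seq_len(config$n_chromosomes), function(ci) {
    ng <- per_chrom[ci]
    if (ng == 0L) return(NULL)
    slack <- config$chrom_length_bp - ng * config$gene_length_bp
    # variable gaps: a skewed split of the slack clusters genes unevenly,
    # giving the gene set analysis a real density gradient to bin on
    w <- stats::rexp(ng + 1L)^2
    gaps <- as.integer(slack * w / sum(w))
    starts <- as.integer(cumsum(gaps + c(0L, rep(config$gene_length_bp, ng)))[seq_len(ng)])
    data.frame(chrom = paste0("chr", ci),
               start = starts, end = as.integer(starts + config$gene_length_bp),
               name = NA_character_, stringsAsFactors = FALSE)
  }))
  genes$name <- sprintf("gene%04d", seq_len(nrow(genes)))

  set.seed(.sim_seed(config, "regulatory"))
  n_reg <- max(10L, config$n_genes %/% 2L)
  reg_chrom <- sample(paste0("chr", seq_len(config$n_chromosomes)),
                      n_reg, replace = TRUE)
  reg_len <- sample(200:2000, n_reg, replace = TRUE)
  reg_start <- as.integer(stats::runif(n_reg, 0, config$chrom_length_bp - reg_len))
  # anchor a handful of intervals directly on SNPs so covered SNPs exist
  n_on <- min(n_reg %/% 5L, nrow(map))
  if (n_on > 0L) {
    idx <- sample.int(nrow(map), n_on)
    reg_chrom[seq_len(n_on)] <- map$chrom[idx]
    reg_start[seq_len(n_on)] <- as.integer(
      pmax(0L, map$pos[idx] - reg_len[seq_len(n_on)] %/% 2L))
  }
  regulatory <- data.frame(chrom = reg_chrom, start = reg_start,
                           end = as.integer(reg_start + reg_len),
                           name = sprintf("dnase%04d", seq_len(n_reg)),
                           stringsAsFactors = FALSE)
  regulatory <- regulatory[order(regulatory$chrom, regulatory$start), ]
  rownames(regulatory) <- NULL

  stopifnot(all(genes$start >= 0), all(genes$start < genes$end),
            all(genes$end <= config$chrom_length_bp),
            all(regulatory$start >= 0), all(regulatory$start < regulatory$end),
            all(regulatory$end <= config$chrom_length_bp))
  list(genes = genes, regulatory = regulatory, map = map)
}

#' Simulate gene sets with optional planted selection signal
#'
#' Builds `n_gene_sets` sets of `genes_per_set` genes. The first
#' `n_planted_sets` sets draw at least half of their members from genes
#' that contain (or lie nearest to) truly selected SNPs, planting a signal
#' the SUMSTAT enrichment should recover; the rest are uniform draws.
#'
#' @param config A [sim_config()] object.
#' @param truth Truth table from [simulate_panel()].
#' @param annotation Result of [simulate_annotation()].
#' @return Named list of character vectors of gene ids (a GMT-shaped
#'   object); names are set ids, planted sets are named `planted###`.
#' @export
simulate_gene_sets <- function(config, truth, annotation) {
  stopifnot(inherits(config, "sim_config"))
  if (config$genes_per_set > nrow(annotation$genes))
    stop("simulate_gene_sets: genes_per_set exceeds number of genes")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.sim_seed(config, "sets"))

  assign <- assign_genes(annotation$map, annotation$genes)
  sel_snps <- truth$snp_id[truth$label != "neutral"]
  sel_genes <- unique(stats::na.omit(
    assign$assigned_gene[assign$snp_id %in% sel_snps]))
  all_genes <- annotation$genes$name

  sets <- vector("list", config$n_gene_sets)
  names(sets) <- sprintf("set%03d", seq_len(config$n_gene_sets))
  for (i in seq_len(config$n_gene_sets)) {
    if (i <= config$n_planted_sets && length(sel_genes) > 0L) {
      n_sel <- min(length(sel_genes),
                   max(ceiling(config$genes_per_set / 2), 1L))
      core <- sample(sel_genes, n_sel)
      rest <- sample(setdiff(all_genes, core), config$genes_per_set - n_sel)
      sets[[i]] <- sort(c(core, rest))
      names(sets)[i] <- sprintf("planted%03d", i)
    } else {
      sets[[i]] <- sort(sample(all_genes, config$genes_per_set))
    }
  }
  if (anyDuplicated(names(sets))) stop("duplicate gene set ids")
  sets
}
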