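#' Configuration of an end-to-end pipeline run
#'
#' Bundles input paths, thresholds and the scan settings for
#' [run_pipeline()]. Several run labels map to several counts files
#' (population sets) analysed independently before the cross-run stages.
#'
#' @param counts Named character vector of allele-count TSV paths; names
#'   are the run labels (e.g. `PS1`..`PS4`).
#' @param map,design,genes,regulatory,gmt Paths to the shared SNP map TSV,
#'   design TSV, gene BED, regulatory BED and gene-set GMT.
#' @param functional Optional path to a functional-class TSV.
#' @param fdr q-value threshold (default 0.1).
#' @param min_maf Pooled MAF filter cutoff (default 0.05).
#' @param window_bp,step_bp Sliding-window size and step.
#' @param max_dist Gene-assignment distance cutoff (default 50 kb).
#' @param scan A [scan_config()].
#' @param geneset_model Score used in the gene-set stage (default `"co"`,
#'   convergent selection).
#' @param geneset_schedule,prune_schedule Sequential null schedules for
#'   [test_sets()] and [prune_and_requalify()].
#' @param n_perms Permutations for the cross-run overlap test.
#' @param seed Master seed for the downstream randomised stages.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(counts, map, design, genes, regulatory, gmt,
                       functional = NULL, fdr = 0.1, min_maf = 0.05,
                       window_bp = 500000, step_bp = 25000,
                       max_dist = 50000, scan = scan_config(),
                       geneset_model = "co",
                       geneset_schedule = c(init = 10000, threshold = 5000,
                                            increment = 10000, max = 500000),
                       prune_schedule = c(init = 2000, threshold = 1000,
                                          increment = 2000, max = 20000),
                       n_perms = 50000, seed = 1L) {
  if (is.null(names(counts)) || anyDuplicated(names(counts)))
    stop("run_config: counts must be a named vector with unique run labels")
  paths <- c(counts, map = map, design = design, genes = genes,
             regulatory = regulatory, gmt = gmt)
  if (!is.null(functional)) paths <- c(paths, functional = functional)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("run_config: missing input file(s): ",
         paste(missing, collapse = ", "))
  structure(list(counts = counts, map = map, design = design, genes = genes,
                 regulatory = regulatory, gmt = gmt, functional = functional,
                 fdr = fdr, min_maf = min_maf, window_bp = window_bp,
                 step_bp = step_bp, max_dist = max_dist, scan = scan,
                 geneset_model = geneset_model,
                 geneset_schedule = geneset_schedule,
                 prune_schedule = prune_schedule,
                 n_perms = n_perms, seed = as.integer(seed)),
            class = "run_config")
}

#' Read and cross-validate all pipeline inputs
#'
#' Parses every file referenced by a [run_config()] under the declared
#' dialects and checks cross-file consistency (SNP ids shared between
#' counts and map, chromosome names shared between map and annotation).
#'
#' @param config A [run_config()].
#' @return List with `panels` (named list of [allele_panel()]s), `genes`,
#'   `regulatory`, `sets`, `functional`.
#' @export
read_inputs <- function(config) {
  stopifnot(inherits(config, "run_config"))
  panels <- lapply(config$counts, function(p)
    read_panel(p, config$map, config$design))
  genes <- read_bed(config$genes)
  regulatory <- read_bed(config$regulatory)
  chroms <- unique(panels[[1]]$map$chrom)
  odd <- setdiff(unique(genes$chrom), chroms)
  if (length(odd))
    warning("read_inputs: gene chromosome(s) absent from the SNP map: ",
            paste(odd, collapse = ", "))
  sets <- read_gmt(config$gmt)
  functional <- if (!is.null(config$functional))
    .read_tsv(config$functional, c("snp_id", "functional_class")) else NULL
  list(panels = panels, genes = genes, regulatory = regulatory,
       sets = sets, functional = functional)
}

#' Run the full convergent-selection pipeline
#'
#' Per run label: MAF filter, MCMC scan with q-values, sliding windows and
#' outlier refinement, gene/regulatory annotation, genic enrichment, gene
#' scores, SUMSTAT gene-set test and pruning. Across runs: outlier-overlap
#' permutation tests (SNP- and gene-level) and concordant clusters. All
#' declared tables are written under `outdir` together with a manifest of
#' parameters and seeds.
#'
#' @param config A [run_config()].
#' @param outdir Output directory.
#' @return Invisibly, the in-memory results list (`scans`, `windows`,
#'   `refined`, `annotation`, `enrichment`, `gene_scores`, `geneset`,
#'   `pruned`, `overlap_snp`, `overlap_gene`, `clusters`).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    r
  }

  inputs <- stage("read_inputs", read_inputs(config))
  labels <- names(config$counts)

  scans <- list(); wins <- list(); refined <- list(); outliers <- list()
  for (lb in labels) {
    panel <- stage(paste0(lb, ":filter_maf"),
                   filter_maf(inputs$panels[[lb]], config$min_maf))
    sc_cfg <- config$scan
    sc_cfg$seed <- config$scan$seed + match(lb, labels) - 1L
    scan <- stage(paste0(lb, ":scan"),
                  run_scan(panel, sc_cfg, fdr = config$fdr))
    w <- stage(paste0(lb, ":windows"), {
      w0 <- build_windows(panel$map, config$window_bp, config$step_bp)
      score_windows(w0, stats::setNames(scan$qvalue, scan$snp_id), config$fdr)
    })
    out_ids <- scan$snp_id[scan$qvalue < config$fdr]
    refined_ids <- refine_outliers(out_ids, w)
    scans[[lb]] <- scan
    wins[[lb]] <- w
    outliers[[lb]] <- out_ids
    refined[[lb]] <- scan[scan$snp_id %in% refined_ids,
                          c("snp_id", "chrom", "pos")]
    .write_tsv(scan, file.path(outdir, paste0("scan_", lb, ".tsv")))
    .write_tsv(w[, setdiff(names(w), "snp_ids")],
               file.path(outdir, paste0("windows_", lb, ".tsv")))
    sig <- w[w$significant, , drop = FALSE]
    if (nrow(sig))
      write_bed(data.frame(chrom = sig$chrom, start = sig$start - 1L,
                           end = sig$end,
                           name = sprintf("win%04d", seq_len(nrow(sig)))),
                file.path(outdir, paste0("significant_windows_", lb, ".bed")))
  }

  annot <- stage("annotate", {
    a <- assign_genes(inputs$panels[[1]]$map, inputs$genes, config$max_dist)
    a <- attach_functional(a, inputs$functional)
    reg <- nearest_regulatory(inputs$panels[[1]]$map, inputs$regulatory)
    merge(a, reg, by = "snp_id", sort = FALSE)
  })
  .write_tsv(annot, file.path(outdir, "annotation.tsv"))

  enr <- list(); gscores <- list(); gsres <- list(); pruned <- list()
  for (lb in labels) {
    scan <- scans[[lb]]
    ann <- annot[match(scan$snp_id, annot$snp_id), ]
    is_out <- scan$snp_id %in% refined[[lb]]$snp_id
    enr[[lb]] <- if (sum(is_out) == 0L) {
      message(lb, ": no refined outliers; genic enrichment skipped")
      NULL
    } else {
      stage(paste0(lb, ":enrich"),
            ld_resampled_fisher(scan[, c("snp_id", "chrom", "pos")],
                                is_out, ann$genic, n_reps = 1000,
                                seed = config$seed))
    }
    gs <- stage(paste0(lb, ":gene_scores"), gene_scores(scan, ann))
    sets <- prepare_sets(inputs$sets, gs$gene_id)
    res <- stage(paste0(lb, ":genesets"),
                 test_sets(sets, gs, config$geneset_model,
                           config$geneset_schedule, seed = config$seed))
    pr <- stage(paste0(lb, ":prune"),
                prune_and_requalify(res, sets, gs, config$geneset_model,
                                    config$prune_schedule,
                                    seed = config$seed))
    gscores[[lb]] <- gs; gsres[[lb]] <- res; pruned[[lb]] <- pr
    .write_tsv(gs, file.path(outdir, paste0("gene_scores_", lb, ".tsv")))
    .write_tsv(res, file.path(outdir, paste0("genesets_", lb, ".tsv")))
    if (!is.null(pr) && nrow(pr))
      .write_tsv(pr, file.path(outdir, paste0("genesets_pruned_", lb, ".tsv")))
    edges <- overlap_edges(sets)
    .write_tsv(edges, file.path(outdir, paste0("set_overlap_", lb, ".tsv")))
  }

  cross <- list(overlap_snp = NULL, overlap_gene = NULL, clusters = NULL)
  if (length(labels) >= 2L) {
    universes <- lapply(scans, `[[`, "snp_id")
    cross$overlap_snp <- stage("overlap_snp",
      overlap_permutation(lapply(refined, `[[`, "snp_id"), universes,
                          n_perms = config$n_perms, seed = config$seed))
    gene_sets_out <- lapply(labels, function(lb) {
      ids <- refined[[lb]]$snp_id
      unique(stats::na.omit(annot$assigned_gene[annot$snp_id %in% ids]))
    })
    gene_universes <- lapply(labels, function(lb)
      unique(stats::na.omit(
        annot$assigned_gene[annot$snp_id %in% scans[[lb]]$snp_id])))
    cross$overlap_gene <- stage("overlap_gene",
      overlap_permutation(gene_sets_out, gene_universes,
                          n_perms = config$n_perms, seed = config$seed + 1L))
    cross$clusters <- stage("clusters",
      concordant_clusters(wins, runs_required = length(labels),
                          outlier_runs = refined))
    .write_tsv(cross$clusters[, setdiff(names(cross$clusters), "snp_ids")],
               file.path(outdir, "clusters.tsv"))
  } else {
    message("single run label: cross-run stages skipped")
  }

  manifest <- c(
    sprintf("convergescan %s", as.character(utils::packageVersion("convergescan"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("runs: %s", paste(labels, collapse = ",")),
    sprintf("fdr: %g  min_maf: %g  window: %d/%d  max_dist: %d",
            config$fdr, config$min_maf, as.integer(config$window_bp),
            as.integer(config$step_bp), as.integer(config$max_dist)),
    sprintf("scan seed: %d  pipeline seed: %d", config$scan$seed, config$seed),
    sprintf("chain: pilot %dx%d, burn-in %d, %d samples, thinning %d",
            config$scan$pilot_runs, config$scan$pilot_length,
            config$scan$burn_in, config$scan$n_samples, config$scan$thinning))
  writeLines(manifest, file.path(outdir, "MANIFEST.txt"))

  invisible(list(scans = scans, windows = wins, refined = refined,
                 annotation = annot, enrichment = enr,
                 gene_scores = gscores, geneset = gsres, pruned = pruned,
                 overlap_snp = cross$overlap_snp,
                 overlap_gene = cross$overlap_gene,
                 clusters = cross$clusters))
}
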