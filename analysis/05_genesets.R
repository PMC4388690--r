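#!/usr/bin/env Rscript
# SUMSTAT gene-set enrichment on the any-selection score: gene scores are
# per-gene maxima of SNP posteriors, null sets are matched on SNP-density
# bins with the sequential 10,000 -> 500,000 randomization schedule, and
# redundancy among candidate sets is pruned with empirical re-qualification.

library(convergescan)

scan <- read.table("results/scan.tsv", header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
ann <- read.table("results/annotation.tsv", header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
gmt <- read_gmt("results/data/gene_sets.gmt")

gs <- gene_scores(scan, ann)
cat(sprintf("scored genes: %d (of %d sets' universe)\n", nrow(gs),
            length(gmt)))
write.table(gs, "results/gene_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

prepped <- prepare_sets(gmt, gs$gene_id)
cat(sprintf("gene sets after size filter and pooling: %d\n", length(prepped)))

res <- test_sets(prepped, gs, "sl", seed = 1)
write.table(res, "results/genesets.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("sets with q <= 0.20 before pruning: %d (planted among them: %d)\n",
            sum(res$significant_20),
            sum(res$significant_20 & grepl("planted", res$set_id))))

pr <- prune_and_requalify(res, prepped, gs, "sl", seed = 1)
if (nrow(pr)) {
  write.table(pr, "results/genesets_pruned.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
  cat(sprintf("sets surviving pruning at q <= 0.20: %d\n",
              sum(pr$significant_20)))
  print(pr[, c("set_id", "rank", "n_genes_pruned", "p_pruned",
               "q_empirical")])
} else {
  cat("no candidate sets to prune\n")
}

edges <- overlap_edges(prepped)
write.table(edges, "results/set_overlap_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("overlap edges (> 33%% sharing): %d\n", nrow(edges)))
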