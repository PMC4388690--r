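#!/usr/bin/env Rscript
# Hierarchical Bayesian F_ST outlier scan of the simulated panel: MAF
# filter, reversible-jump MCMC over the four selection models, q-values
# and model calls; compares calls against the simulation truth.
# Takes several minutes at the default chain length.

library(convergescan)

panel <- read_panel("results/data/counts.tsv", "results/data/snp_map.tsv",
                    "results/data/design.tsv")
truth <- read.table("results/data/truth.tsv", header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)

filtered <- filter_maf(panel, 0.05)
cat(sprintf("MAF filter: %d -> %d loci\n", n_loci(panel), n_loci(filtered)))

scan <- run_scan(filtered, scan_config(seed = 1), fdr = 0.1)
write.table(scan, "results/scan.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

tr <- truth[match(scan$snp_id, truth$snp_id), ]
called <- scan$qvalue < 0.1
cat(sprintf("outliers (q < 0.1): %d of %d (%.2f%%)\n",
            sum(called), nrow(scan), 100 * mean(called)))
cat(sprintf("realized FDR among calls: %.3f\n",
            if (any(called)) mean(tr$label[called] == "neutral") else 0))
for (lb in c("sel_g1", "sel_g2", "convergent"))
  cat(sprintf("recovery of %s loci: %d/%d\n", lb,
              sum(called & tr$label == lb), sum(tr$label == lb)))
print(table(truth = tr$label, call = scan$model_call))
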