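#!/usr/bin/env Rscript
# Sliding-window refinement: 500 kb windows every 25 kb, window q-value =
# nearest-rank 95th percentile of member SNP q-values, low-density windows
# (< 20% of the chromosome average) never significant. Refined outliers
# are the q < 0.1 SNPs inside a significant window.

library(convergescan)

scan <- read.table("results/scan.tsv", header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
map <- scan[, c("snp_id", "chrom", "pos")]
w <- score_windows(build_windows(map), setNames(scan$qvalue, scan$snp_id),
                   fdr = 0.1)
out <- scan$snp_id[scan$qvalue < 0.1]
refined <- refine_outliers(out, w)

cat(sprintf("windows: %d emitted, %d significant\n", nrow(w),
            sum(w$significant)))
cat(sprintf("outliers: %d raw -> %d refined (isolated/low-density removed)\n",
            length(out), length(refined)))

flat <- w[, setdiff(names(w), "snp_ids")]
write.table(flat, "results/windows.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(refined, "results/refined_outliers.txt")

cl <- concordant_clusters(list(run1 = w), runs_required = 1,
                          outlier_runs = list(
                            run1 = scan[scan$snp_id %in% refined,
                                        c("snp_id", "chrom", "pos")]))
cat(sprintf("clusters (single run): %d; spans %s kb\n", nrow(cl),
            paste(cl$length_kb, collapse = ", ")))
write.table(cl[, setdiff(names(cl), "snp_ids")], "results/clusters.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
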