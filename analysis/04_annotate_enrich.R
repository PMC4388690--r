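#!/usr/bin/env Rscript
# Gene and regulatory annotation of the scanned SNPs (50 kb nearest-gene
# rule) and genic-enrichment testing of the refined outliers: one-sided
# Fisher exact test plus the LD-controlled variant that resamples one
# outlier and one non-outlier per 100 kb block (N = 1000).

library(convergescan)

scan <- read.table("results/scan.tsv", header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
genes <- read_bed("results/data/genes.bed")
reg <- read_bed("results/data/regulatory.bed")
map <- scan[, c("snp_id", "chrom", "pos")]

ann <- assign_genes(map, genes, max_dist = 50000)
ann <- attach_functional(ann, NULL)
nr <- nearest_regulatory(map, reg)
ann <- merge(ann, nr, by = "snp_id", sort = FALSE)
write.table(ann, "results/annotation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("genic SNPs (in or within 50 kb of a gene): %.1f%%\n",
            100 * mean(ann$genic)))

refined <- readLines("results/refined_outliers.txt")
is_out <- scan$snp_id %in% refined
if (sum(is_out) > 0) {
  fisher <- genic_fisher(is_out, ann$genic[match(scan$snp_id, ann$snp_id)])
  print(fisher)
  ld <- ld_resampled_fisher(map, is_out,
                            ann$genic[match(scan$snp_id, ann$snp_id)],
                            n_reps = 1000, seed = 1)
  print(ld)
  d <- ann[ann$snp_id %in% refined, ]
  near <- pmin(d$distance_bp, d$nearest_regulatory_distance_bp, na.rm = TRUE)
  cat(sprintf("max distance of a refined outlier to a gene or regulatory element: %.1f kb\n",
              max(near) / 1000))
} else {
  cat("no refined outliers; enrichment skipped\n")
}
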