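#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a 2,000-SNP allele-count panel for
# two continental groups (2 populations each, n = 30 diploids), with 5% of
# loci under selection (2% in each single group, 1% convergent, alpha 2.5
# on the logit scale), plus gene models, regulatory intervals and gene
# sets with three planted high-score sets. All downstream scripts read the
# files written here.

library(convergescan)

cfg <- sim_config(seed = 1)
sim <- simulate_panel(cfg)
ann <- simulate_annotation(cfg)
sets <- simulate_gene_sets(cfg, sim$truth, ann)

paths <- write_simulation(sim, ann, sets, "results/data")
cat("wrote:", paste(basename(paths), collapse = ", "), "\n")
cat(sprintf("panel: %d loci x %d populations; truth: %s\n",
            n_loci(sim$panel), nrow(sim$panel$pops),
            paste(sprintf("%s=%d", names(table(sim$truth$label)),
                          table(sim$truth$label)), collapse = ", ")))
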