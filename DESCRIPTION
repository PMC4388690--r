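Package: convergescan
Title: Hierarchical Bayesian F_ST Scan for Convergent Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genome-wide scan for convergent positive selection between two
    continental groups of populations. Allele counts are modelled with a
    hierarchical island F-model in which logit-transformed differentiation
    coefficients decompose into population effects and locus-specific
    selection effects; a reversible-jump MCMC estimates, per SNP, the
    posterior probability of neutrality, selection in either group, or
    selection in both, and posterior error probabilities are converted to
    Bayesian q-values. Downstream stages refine outliers with a sliding
    window over SNP q-values, annotate SNPs to genes and regulatory
    intervals, test genic enrichment with Fisher and LD-controlled
    resampling tests, test cross-run outlier overlap by permutation, and
    run a SUMSTAT gene-set enrichment with SNP-density-binned sequential
    null distributions, pruning of shared genes and empirical q-values.
    A synthetic-data module generates panels, annotations and gene sets
    under the model the scan assumes, with ground truth for calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    fgsea
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
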