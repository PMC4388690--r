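---
title: "A hierarchical Bayesian scan for convergent selection: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hierarchical Bayesian scan for convergent selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`convergescan` implements a genome-wide scan for convergent positive
selection between two continental groups of populations, followed by
window-based refinement, annotation, enrichment testing and a gene-set
(SUMSTAT) analysis. This vignette explains the model, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the numerical and design choices a maintainer would want to know about.

## The hierarchical F-model

The observed data are biallelic allele counts per SNP and population,
with each population assigned to one of two groups ("continents"). The
model is a hierarchical island model. Writing `p` for a locus's ancestral
frequency, each group `g` has a migrant-pool frequency

    p~_g | p  ~  Beta(theta_CT p, theta_CT (1 - p)),
    theta_CT = (1 - F_CT) / F_CT,  logit(F_CT) = beta_CT(g),

and each population `j` in group `g` has a latent frequency distributed
around the pool,

    p_j | p~_g  ~  Beta(theta_j p~_g, theta_j (1 - p~_g)),
    theta_j = (1 - F_j) / F_j,  logit(F_j) = alpha_g(locus) + beta_j.

Integrating the latent `p_j` against the binomial sampling of `2n`
alleles gives a beta-binomial likelihood per (locus, population) — the
quantity `locus_loglik()` computes and the test suite checks against
numerical integration to `1e-6`.

The decomposition `logit(F_SC) = alpha + beta` separates demography from
selection: `beta_j` is shared by all loci of a population (drift,
sampling), while `alpha_g` is locus-specific and shared by the
populations of a group. A locus is neutral when both groups' `alpha` are
excluded; including `alpha` in one group models local selection there;
including both models convergent selection. Only the within-group level
(`F_SC`) carries selection effects; the group level (`F_CT`) is modelled
but deliberately never tested, so that between-continent divergence is
accounted for without being interpreted.

## Reversible-jump MCMC and the posterior estimator

`run_scan()` samples the joint posterior with Metropolis random walks on
`p`, the pool frequencies, `alpha`, `beta` and `beta_CT`, plus a
reversible-jump move per locus and group that toggles the inclusion of
`alpha`. The birth proposal draws `alpha` from its prior, so the
acceptance ratio reduces to the likelihood ratio times the prior odds for
neutrality (default 10: selection is a priori rare; configurable in
`scan_config()`).

Model probabilities are not taken from raw visit frequencies of the four
inclusion configurations. Instead, at each retained sample the per-group
inclusion probability is computed conditionally on the current pool
frequencies and `beta` by integrating the likelihood over the `alpha`
prior with 20-node Gauss–Hermite quadrature; the two groups are
conditionally independent, so the four model probabilities are products
of the per-group terms. This Rao-Blackwellised estimator has the same
expectation as counting visits but a far smaller Monte-Carlo variance:
with prior odds of 10 the chain transitions between inclusion states
rarely, and visit counts over a few thousand samples would carry
substantial noise into the q-values.

Priors follow the conventions of the reference tools for this model
family: `alpha ~ N(0, 1)`, `beta` and `beta_CT ~ N(-1, 1)` (keeping prior
F mass at moderate differentiation), uniform ancestral and pool
frequencies. Proposal scales are tuned in 20 pilot batches of 1,000
sweeps towards a 25–45% acceptance band; defaults are burn-in 10,000,
5,000 samples at thinning 10. One integer seed drives pilot and main
chains and makes scans bit-reproducible. With `n_chains > 1`, chains run
from derived seeds, posteriors are averaged, and a disagreement above
0.15 in `P(neutral)` raises a warning — a deliberate soft failure, since
a long-but-imperfect chain is still informative.

## From posteriors to calls

The posterior error probability (PEP) of a locus is its posterior
probability of the neutral model. `qvalues_from_posteriors()` converts
PEPs to Bayesian q-values as the running mean of sorted PEPs: the q at
rank k estimates the expected fraction of false positives if the k best
loci are called. Ties share the larger (most conservative) q. A locus is
called at `q < 0.1` (strict), and among called loci the model call is
convergent when the both-groups model beats each single-group model,
otherwise the better single-group model; exact ties go to group 1 with a
warning. The boundary conventions — MAF "below 5%" strict, q "lower than
0.1" strict — are applied literally.

## Sliding windows

`build_windows()` tiles each chromosome with 500 kb windows advancing by
25 kb, anchored at position 1 (the grid phase is a convention; nothing in
the method pins it). A window's q-value is the nearest-rank 95th
percentile of its SNPs' q-values — always an attained value, so one
isolated outlier cannot drag a window under the threshold — and windows
with fewer SNPs than 20% of their chromosome's average (computed over
emitted windows, i.e. windows with at least one SNP) are never
significant. Refinement keeps only outliers inside a significant window;
it never adds SNPs. Cross-run clusters are maximal intervals covered by
merged significant regions from at least `runs_required` runs, with the
reported span running from the first to the last supporting refined
outlier SNP (merged-window bounds are kept as auxiliary columns) and
lengths reported in kb with one decimal.

## Annotation, enrichment, overlap

SNP positions are 1-based; gene and regulatory intervals are BED (0-based
half-open); the distance between a SNP and an interval is the number of
bases strictly between them. A SNP inside a gene is assigned to it; a SNP
covered by several genes goes to the nearest midpoint; otherwise the
closest gene within 50 kb wins, with a distance of exactly 50,000 bp
still assigned (the source method alternates "less than" and "at most";
we resolve the boundary as inclusive) and ties broken towards the smaller
gene start. Genic enrichment uses a one-sided Fisher exact test, plus an
LD-controlled variant that tiles chromosomes into disjoint 100 kb blocks
and resamples one outlier and one non-outlier per block (N = 1000),
summarising replicate p-values by their mean and 5%/95% order statistics.
Cross-run outlier overlap is tested by drawing same-sized random SNP sets
per run (without replacement within a run, independently across runs) and
counting permutations with overlap at least as large as observed; with
zero exceedances only the resolution bound `1/N` is reported.

## Gene-set analysis

Gene scores are per-gene maxima over assigned SNPs of `P(selection in
group 1)`, `P(group 2)`, `P(both)`, and of the per-SNP sum of the three
(the "any selection" score). Taking maxima favours genes with many SNPs,
so genes are stratified into 10 quantile bins of assigned-SNP count and
every null set is drawn to match the tested set's bin composition
exactly; bins too small to supply a draw are merged downward with a
message. Scores are deliberately not rescaled within bins — their
distribution is heavily skewed and rescaling would erase real signal.

SUMSTAT is the sum of member-gene scores. Null sampling is sequential:
10,000 draws for every set, then 10,000 more for any set with fewer than
5,000 exceedances, up to 500,000. The empirical p uses the `(x+1)/(n+1)`
correction (the raw proportion is also emitted), and pre-pruning q-values
are Benjamini–Hochberg across the tested sets. Sets smaller than 10 genes
(after intersection with the scored universe) are dropped, and sets with
Jaccard similarity at least 0.95 are pooled transitively into unions —
the "(nearly) identical" criterion made concrete, since no number is
stated anywhere.

Pruning removes redundancy among the candidate sets (pre-pruning
q at or below 0.20): the best set (smallest p, ties to the larger
SUMSTAT) is frozen, its genes leave all remaining candidates, shrunken
sets below 10 genes drop out, and survivors are re-tested at their
reduced size. Because the pruned tests are dependent, the pruned q is
estimated empirically: the identical test-and-prune procedure runs on 20
score-permuted replicas of the gene-score table, and the q at observed
rank r is the mean number of replica pruned p-values at or below the
observed p, divided by r, capped at 1 and made monotone. This
permutation-replica scheme is this package's concrete choice for a step
whose exact published procedure is not described; it is conservative in
that the replicas preserve the set structure and the score distribution
while breaking the score–set association.

## The synthetic-data generator

`simulate_panel()` draws data from exactly the hierarchy the scan
assumes — Beta pool and population frequencies, binomial counts, selected
loci with `alpha = alpha_effect` in the designated group(s) — so that
parameter recovery is a clean calibration surface rather than a
robustness experiment. Defaults define the study conditions used
throughout the tests: 2,000 loci on 4 chromosomes of 50 Mb, two groups
of 2 populations, 30 diploids each, `beta_pop = -2` (neutral F_SC about
0.12, matching high-drift human populations), `beta_CT = -2`
(between-continent divergence about 0.12), 2% + 2% + 1% of loci selected
in group 1 / group 2 / both at `alpha_effect = 2.5`, 600 genes of 20 kb
tiled with skewed inter-gene gaps (so per-gene SNP densities vary), 200
gene sets of 25 genes with 3 planted sets drawing at least half their
members from genes that harbour truly selected SNPs. Counts are array
genotypes in spirit: no sequencing-error layer. Loci are independent —
no linkage — so the window statistics and the LD-controlled resampler
are exercised for their arithmetic, not for their biological rationale;
passing tests show the machinery is correct under the model, not that
the model describes real human data.

A note on attainable power at these conditions: with two populations per
group, 60 alleles each and prior odds of 10, the exact posterior (computed
by quadrature under the true generative parameters) leaves the neutral
model with substantial mass at many truly convergent loci — two Beta
draws around a free pool frequency often land close together by chance.
Per-locus recovery of convergent loci at `q < 0.1` sits around 40–55%
depending on the realisation, and the suite's calibration test reports
recovery against a greater-than-50% reference on a fixed canonical seed;
realized FDR, by contrast, is comfortably below nominal in every
configuration tried. Widening the `alpha` prior moves the exact bound by
only a few points, so this is an information limit of the design, not an
estimator artefact.

One density-dependent behaviour deserves a flag: because the window
statistic is a high order statistic of member q-values, a window is
significant only when nearly all of its SNPs are outliers. On the
desk-scale synthetic panel (2,000 SNPs over 200 Mb, about 5 SNPs per
500 kb window, independent loci) outliers are isolated, so the window
stage typically refines the outlier list to empty — exactly the
behaviour it is designed to have on isolated signals. Regional clusters
of outliers, which dense genotyping arrays produce through linkage,
are what make windows light up; the window oracle tests therefore
exercise the arithmetic on constructed q-vectors rather than on scan
output.

## Problem sizes in the tests

The suite runs scaled-down chains on small panels for the per-operation
checks (hundreds of loci, a few thousand sweeps), one full-default scan
on the 2,000-locus panel for the calibration test, exhaustive
enumeration on universes of at most 6 ids for the overlap oracle, an
exhaustive per-position rescan on 200-SNP fixtures for the window
oracle, and 200 sets of 20 genes over a 400-gene universe for the
gene-set null calibration; the pruning recovery check runs five seeds of
the full generator with pseudo-posteriors consistent with the truth
labels, isolating the gene-set stage from scan noise. The acceptance
script (`scripts/acceptance.R`) repeats the same computations from
scratch under a caller-provided seed.

## Known limitations

No linkage simulation (the LD control is positional, as in the source
method); balancing selection is estimated (negative `alpha`) but not
called as a distinct class; exactly two groups; biallelic diploid data
only; the empirical pruned-q scheme, while calibrated in the planted
tests, is a stand-in for an unpublished procedure and should be read as
such.
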