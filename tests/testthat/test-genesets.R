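# small score table builder: n genes with given model scores and bins
score_table <- function(p, n_snps = NULL, n_bins = 1L) {
  n <- length(p)
  data.frame(gene_id = sprintf("g%03d", seq_len(n)),
             n_snps = if (is.null(n_snps)) rep(1L, n) else n_snps,
             p_af = p, p_am = p, p_co = p, p_sl = 3 * p,
             density_bin = if (is.null(n_snps)) rep(1L, n)
                           else convergescan:::density_bins(n_snps, n_bins),
             stringsAsFactors = FALSE)
}

test_that("gene scores take per-model maxima and the any-selection sum", {
  posts <- data.frame(
    snp_id = c("s1", "s2", "s3"),
    P_sel_g1 = c(0.1, 0.05, 0.3),
    P_sel_g2 = c(0.2, 0.10, 0.1),
    P_conv = c(0.3, 0.70, 0.2), stringsAsFactors = FALSE)
  assign <- data.frame(snp_id = c("s1", "s2", "s3"),
                       assigned_gene = c("gA", "gA", NA),
                       stringsAsFactors = FALSE)
  gs <- gene_scores(posts, assign)
  expect_identical(nrow(gs), 1L)  # unassigned SNP dropped with its gene
  expect_equal(gs$p_co, 0.7)
  expect_equal(gs$p_af, 0.1)
  expect_equal(gs$p_am, 0.2)
  # p_sl is the max over SNPs of the per-SNP sum, not the sum of maxima
  expect_equal(gs$p_sl, max(0.1 + 0.2 + 0.3, 0.05 + 0.1 + 0.7))
  expect_identical(gs$n_snps, 2L)
  bad <- data.frame(snp_id = "sX", assigned_gene = "gA",
                    stringsAsFactors = FALSE)
  expect_error(gene_scores(posts, bad), "missing from assignment")
})

test_that("set preparation intersects, drops small sets and pools twins", {
  scored <- sprintf("g%03d", 1:100)
  raw <- list(
    ok = sprintf("g%03d", 1:20),
    shrunk = c(sprintf("g%03d", 1:9), "zz1", "zz2"),   # 9 scored -> dropped
    twin_a = sprintf("g%03d", 30:49),
    twin_b = sprintf("g%03d", 30:49),                  # identical -> pooled
    cousin = sprintf("g%03d", c(30:39, 60:69)))        # Jaccard 1/3 -> kept
  prep <- prepare_sets(raw, scored)
  expect_false("shrunk" %in% unlist(strsplit(names(prep), "\\+")))
  pooled <- grep("twin", names(prep), value = TRUE)
  expect_length(pooled, 1L)
  expect_setequal(attr(prep[[pooled]], "pooled_from"), c("twin_a", "twin_b"))
  expect_identical(sort(prep[[pooled]]), sprintf("g%03d", 30:49))
  expect_true(any(grepl("cousin", names(prep))))
  expect_error(prepare_sets(raw[c(1, 1)], scored), "duplicate")
})

test_that("near-identical sets pool at Jaccard 0.95 but not at 0.5", {
  scored <- sprintf("g%03d", 1:100)
  a <- sprintf("g%03d", 1:40)
  near <- list(a = a, b = c(sprintf("g%03d", 2:40), "g050"))  # Jaccard 39/41
  expect_length(prepare_sets(near, scored, pool_jaccard = 0.95), 1L)
  half <- list(a = a, b = sprintf("g%03d", 21:60))            # Jaccard 1/3
  expect_length(prepare_sets(half, scored, pool_jaccard = 0.95), 2L)
})

test_that("SUMSTAT sums member scores and unions dominate components", {
  sc <- score_table(seq(0.01, 1, length.out = 100))
  s1 <- sc$gene_id[1:15]
  s2 <- sc$gene_id[10:25]
  expect_equal(sumstat(s1, sc, "af"), sum(sc$p_af[1:15]))
  expect_equal(sumstat(s1, sc, "sl"), 3 * sum(sc$p_af[1:15]))
  u <- union(s1, s2)
  expect_gte(sumstat(u, sc, "co"),
             max(sumstat(s1, sc, "co"), sumstat(s2, sc, "co")))
  expect_error(sumstat(c("nope"), sc, "af"), "without scores")
})

test_that("sequential nulls stop early for weak sets and escalate for strong", {
  set.seed(2)
  sc <- score_table(runif(120))
  sc$p_af[1:12] <- 1.0   # an unbeatable set: no random set can exceed it
  sets <- list(top = sc$gene_id[1:12], mid = sc$gene_id[13:24])
  sched <- c(init = 1000, threshold = 500, increment = 1000, max = 5000)
  res <- test_sets(sets, sc, "af", sched, seed = 4)
  expect_identical(res$n_rand[res$set_id == "top"], 5000L)
  expect_identical(res$n_exceed[res$set_id == "top"], 0L)
  expect_equal(res$p_empirical[res$set_id == "top"], 1 / 5001)
  # a typical set accumulates >= 500 exceedances in the first round
  expect_identical(res$n_rand[res$set_id == "mid"], 1000L)
  expect_true(all(res$p_empirical ==
                    (res$n_exceed + 1) / (res$n_rand + 1)))
})

test_that("null draws match the tested set's density-bin composition", {
  # scores encode the bin index in powers of ten, so any null draw with the
  # right per-bin counts sums exactly to the observed SUMSTAT
  n_snps <- rep(c(1L, 5L, 25L), each = 20)
  sc <- score_table(rep(0, 60), n_snps = n_snps, n_bins = 3L)
  stopifnot(length(unique(sc$density_bin)) == 3L)
  sc$p_af <- 10^(sc$density_bin - 1)
  set <- sc$gene_id[c(1:4, 21:23, 41:42)]  # 4 + 3 + 2 genes per bin
  res <- test_sets(list(s = set), sc, "af",
                   schedule = c(init = 500, threshold = 251, increment = 500,
                                max = 500), seed = 9)
  # every bin-matched draw ties the observed statistic exactly
  expect_identical(res$n_exceed, res$n_rand)
})

test_that("uniform scores give approximately uniform empirical p-values", {
  set.seed(6)
  sc <- score_table(runif(300))
  sets <- lapply(1:120, function(i) sample(sc$gene_id, 15))
  names(sets) <- sprintf("s%03d", 1:120)
  res <- test_sets(sets, sc, "af",
                   schedule = c(init = 2000, threshold = 1000,
                                increment = 2000, max = 10000), seed = 11)
  expect_gt(suppressWarnings(ks.test(res$p_empirical, "punif"))$p.value,
            0.01)
})

test_that("pruning freezes the best set and reassigns shared genes", {
  set.seed(5)
  sc <- score_table(runif(200, 0, 0.2))
  hi <- sc$gene_id[1:20]
  sc$p_af[1:20] <- runif(20, 0.7, 1)
  # 'winner' holds all high genes; 'rival' shares 8 of them (40%)
  sets <- list(winner = hi,
               rival = c(hi[1:8], sc$gene_id[101:112]),
               lone = sc$gene_id[121:140])
  sched <- c(init = 1000, threshold = 500, increment = 1000, max = 5000)
  res <- test_sets(sets, sc, "af", sched, seed = 3)
  pr <- prune_and_requalify(res, sets, sc, "af", sched, n_replicas = 5,
                            seed = 8)
  expect_identical(pr$set_id[1], "winner")
  expect_identical(pr$n_genes_pruned[pr$set_id == "winner"], 20L)
  if ("rival" %in% pr$set_id)  # re-tested on its 12 private genes only
    expect_identical(pr$n_genes_pruned[pr$set_id == "rival"], 12L)
  # disjoint significant sets pass through pruning unchanged
  sc2 <- score_table(runif(100, 0, 0.2))
  sc2$p_af[1:12] <- 0.95
  sc2$p_af[21:32] <- 0.90
  sets2 <- list(a = sc2$gene_id[1:12], b = sc2$gene_id[21:32])
  res2 <- test_sets(sets2, sc2, "af", sched, seed = 13)
  pr2 <- prune_and_requalify(res2, sets2, sc2, "af", sched, n_replicas = 5,
                             seed = 14)
  expect_setequal(pr2$set_id, c("a", "b"))
  expect_identical(sort(pr2$n_genes_pruned), c(12L, 12L))
  # after pruning every gene belongs to at most one reported set
  expect_identical(anyDuplicated(unlist(sets2[pr2$set_id])), 0L)
})

test_that("sequential stopping does not change the reporting decision", {
  set.seed(10)
  sc <- score_table(runif(150))
  sc$p_af[1:10] <- runif(10, 0.9, 1)
  sets <- c(list(hot = sc$gene_id[1:10]),
            setNames(lapply(1:19, function(i) sample(sc$gene_id, 12)),
                     sprintf("r%02d", 1:19)))
  seq_res <- test_sets(sets, sc, "af",
                       schedule = c(init = 1000, threshold = 500,
                                    increment = 1000, max = 20000), seed = 21)
  full_res <- test_sets(sets, sc, "af",
                        schedule = c(init = 20000, threshold = 20001,
                                     increment = 1, max = 20000), seed = 21)
  expect_identical(seq_res$significant_20, full_res$significant_20)
})

test_that("overlap edges connect sets sharing over a third of their genes", {
  sets <- list(a = letters[1:9], b = c(letters[1:4], letters[10:14]),
               c = c(letters[1:3], letters[16:21]))
  e <- overlap_edges(sets)
  # a/b share 4/9 > 1/3 -> edge; a/c share exactly 3/9 -> no edge (strict)
  expect_identical(nrow(e), 1L)
  expect_identical(e$set_a, "a")
  expect_identical(e$set_b, "b")
  expect_equal(e$shared_fraction, 4 / 9)
  expect_identical(nrow(overlap_edges(sets["a"])), 0L)
})
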