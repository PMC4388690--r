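test_that("window membership matches a direct interval test", {
  map <- data.frame(snp_id = "s1", chrom = "chr1", pos = 600000L,
                    stringsAsFactors = FALSE)
  w <- build_windows(map)
  # oracle: every 25 kb grid start whose 500 kb span covers the position
  starts <- seq(1, 600000, by = 25000)
  covering <- starts[starts <= 600000 & starts + 500000 - 1 >= 600000]
  expect_identical(w$start, covering)
  expect_true(all(vapply(w$snp_ids, identical, logical(1), y = "s1")))
  expect_identical(range(w$start), c(100001, 600001 - 25000))
})

test_that("windows require sorted maps and tolerate odd geometry", {
  bad <- data.frame(snp_id = c("a", "b"), chrom = "chr1",
                    pos = c(500L, 100L), stringsAsFactors = FALSE)
  expect_error(build_windows(bad), "sorted")
  map <- data.frame(snp_id = c("a", "b"), chrom = "chr1",
                    pos = c(100L, 90000L), stringsAsFactors = FALSE)
  # window width not a multiple of the step is fine
  w <- build_windows(map, window_bp = 70000, step_bp = 30000)
  expect_true(all(w$n_snps >= 1))
  expect_identical(build_windows(map[0, , drop = FALSE]), NULL)
})

test_that("window q is the nearest-rank 95% quantile of member q-values", {
  map <- data.frame(snp_id = sprintf("s%02d", 1:20), chrom = "chr1",
                    pos = seq(1000L, by = 100L, length.out = 20),
                    stringsAsFactors = FALSE)
  w <- build_windows(map, window_bp = 500000, step_bp = 500000)
  # one low q among 19 high: the window must not become significant
  q1 <- setNames(c(0.001, rep(0.9, 19)), map$snp_id)
  s1 <- score_windows(w, q1, fdr = 0.1)
  expect_equal(s1$window_q[1], 0.9)
  expect_false(s1$significant[1])
  # 19 low and one high: order statistic ceiling(0.95*20) = 19 -> 0.01
  q2 <- setNames(c(rep(0.01, 19), 0.5), map$snp_id)
  s2 <- score_windows(w, q2, fdr = 0.1)
  expect_equal(s2$window_q[1], 0.01)
  expect_true(s2$significant[1])
  expect_error(score_windows(w, q2[-1]), "no q-value")
})

test_that("low-density windows are never significant", {
  # chr with one dense region and one isolated SNP
  map <- data.frame(snp_id = sprintf("s%02d", 1:21), chrom = "chr1",
                    pos = c(seq(1000L, by = 50L, length.out = 20), 2000001L),
                    stringsAsFactors = FALSE)
  w <- build_windows(map, window_bp = 10000, step_bp = 10000)
  q <- setNames(rep(0.03, 21), map$snp_id)
  s <- score_windows(w, q, fdr = 0.1)
  lone <- s[s$n_snps == 1, ]
  expect_true(nrow(lone) >= 1)
  expect_false(any(lone$density_ok))
  expect_false(any(lone$significant))
  dense <- s[s$n_snps == 20, ]
  expect_true(all(dense$significant))
})

test_that("brute-force window rescan reproduces score_windows exactly", {
  sim <- simulate_panel(sim_config(n_loci = 180, n_chromosomes = 2,
                                   chrom_length_bp = 4e6, seed = 6))
  map <- sim$panel$map
  set.seed(10)
  q <- setNames(runif(nrow(map))^3, map$snp_id)
  w <- score_windows(build_windows(map), q, fdr = 0.1)
  bf <- brute_force_windows(map, q, 500000, 25000, 0.1)
  got <- w[order(w$chrom, w$start),
           c("chrom", "start", "end", "n_snps", "window_q",
             "density_ok", "significant")]
  rownames(got) <- rownames(bf) <- NULL
  expect_equal(got, bf[order(bf$chrom, bf$start), ])
  # nearest-rank property: the window q is an attained member q
  expect_true(all(vapply(seq_len(nrow(w)), function(k)
    w$window_q[k] %in% q[w$snp_ids[[k]]], logical(1))))
})

test_that("refinement keeps only outliers inside significant windows", {
  map <- data.frame(snp_id = c("a", "b", "c", "d"), chrom = "chr1",
                    pos = c(1000L, 2000L, 900000L, 950000L),
                    stringsAsFactors = FALSE)
  q <- setNames(c(0.01, 0.01, 0.02, 0.9), map$snp_id)
  w <- score_windows(build_windows(map, 10000, 10000), q, fdr = 0.1)
  outliers <- c("a", "c")
  refined <- refine_outliers(outliers, w)
  expect_true(all(refined %in% outliers))
  expect_setequal(refined, c("a", "c"))
  # 'd' sits in a non-significant window; 'b' is significant but was never
  # an outlier: refinement only removes, never adds
  expect_false("b" %in% refined)
  none <- w; none$significant <- FALSE
  expect_identical(refine_outliers(outliers, none), character(0))
})

test_that("concordant clusters merge windows and intersect across runs", {
  map1 <- data.frame(snp_id = sprintf("a%d", 1:40), chrom = "chr1",
                     pos = seq(10000L, by = 2000L, length.out = 40),
                     stringsAsFactors = FALSE)
  q_hot <- setNames(rep(0.01, 40), map1$snp_id)
  w_hot <- score_windows(build_windows(map1, 50000, 25000), q_hot, fdr = 0.1)
  # single run: clusters are the merged significant windows
  cl1 <- concordant_clusters(list(run1 = w_hot), runs_required = 1)
  merged <- GenomicRanges::reduce(GenomicRanges::GRanges(
    w_hot$chrom[w_hot$significant],
    IRanges::IRanges(w_hot$start[w_hot$significant],
                     w_hot$end[w_hot$significant])))
  expect_equal(cl1$start, GenomicRanges::start(merged))
  expect_equal(cl1$end, GenomicRanges::end(merged))

  # second run significant only in part of the region
  q_half <- q_hot
  q_half[21:40] <- 0.9
  w_half <- score_windows(build_windows(map1, 50000, 25000), q_half, fdr = 0.1)
  both <- concordant_clusters(list(r1 = w_hot, r2 = w_half), runs_required = 2)
  one <- concordant_clusters(list(r1 = w_hot, r2 = w_half), runs_required = 1)
  # requiring more runs can only shrink the covered intervals
  for (k in seq_len(nrow(both))) {
    hit <- one$chrom == both$chrom[k] & one$start <= both$start[k] &
      one$end >= both$end[k]
    expect_true(any(hit))
  }
})

test_that("cluster spans are reported from supporting outlier SNPs", {
  map <- data.frame(snp_id = c("x1", "x2", "x3"), chrom = "chr1",
                    pos = c(30000L, 45000L, 52000L), stringsAsFactors = FALSE)
  q <- setNames(rep(0.02, 3), map$snp_id)
  w <- score_windows(build_windows(map, 50000, 25000), q, fdr = 0.1)
  out <- data.frame(snp_id = c("x1", "x3"), chrom = "chr1",
                    pos = c(30000L, 52000L), stringsAsFactors = FALSE)
  cl <- concordant_clusters(list(r1 = w), runs_required = 1,
                            outlier_runs = list(r1 = out))
  expect_equal(cl$start, 30000)
  expect_equal(cl$end, 52000)
  expect_equal(cl$length_kb, round((52000 - 30000) / 1000, 1))
  expect_identical(cl$snp_ids[[1]], c("x1", "x3"))
  expect_error(
    concordant_clusters(list(r1 = w), 1,
                        outlier_runs = list(r1 = transform(out, chrom = "chrZ"))),
    "unknown")
})
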