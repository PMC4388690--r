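test_that("gene assignment follows containment, distance and the 50 kb cap", {
  genes <- data.frame(chrom = "chr1",
                      start = c(100000L, 200000L, 400000L),
                      end = c(150000L, 250000L, 450000L),
                      name = c("A", "B", "C"), stringsAsFactors = FALSE)
  map <- data.frame(
    snp_id = c("inside", "between", "far", "gap50k"),
    chrom = "chr1",
    pos = c(120000L, 180000L, 330000L, 100000L + 200000L),
    stringsAsFactors = FALSE)
  ann <- assign_genes(map, genes, max_dist = 50000)
  rownames(ann) <- ann$snp_id
  expect_identical(ann["inside", "assigned_gene"], "A")
  expect_identical(ann["inside", "distance_bp"], 0)
  # 'between': 29,999 bp gap to A vs 20,000 bp to B -> B (closest wins)
  expect_identical(ann["between", "assigned_gene"], "B")
  expect_identical(ann["between", "distance_bp"], 20000)
  # 'far': ~80 kb from B, 70 kb from C -> unassigned (over the cap)
  expect_true(is.na(ann["far", "assigned_gene"]))
  expect_false(ann["far", "genic"])
  # exactly 50,000 bp from C (first base 400001; 400001 - 350000 - 1)
  d <- assign_genes(data.frame(snp_id = "edge", chrom = "chr1",
                               pos = 350000L, stringsAsFactors = FALSE),
                    genes, max_dist = 50000)
  expect_identical(d$assigned_gene, "C")
  expect_identical(d$distance_bp, 50000)
})

test_that("assignment prefers the closest gene and breaks ties by start", {
  genes <- data.frame(chrom = "chr1",
                      start = c(0L, 250000L), end = c(100000L, 350000L),
                      name = c("L", "R"), stringsAsFactors = FALSE)
  # SNP 30 kb right of L, 40 kb left of R
  near_l <- assign_genes(data.frame(snp_id = "s", chrom = "chr1",
                                    pos = 130000L, stringsAsFactors = FALSE),
                         genes)
  expect_identical(near_l$assigned_gene, "L")
  # B2 ends 0-based 100000 (last base 100000), A2 starts 0-based 199999
  # (first base 200000); a SNP at 150000 sits 49,999 bp from both
  sym <- data.frame(chrom = "chr1", start = c(0L, 199999L),
                    end = c(100000L, 299999L), name = c("B2", "A2"),
                    stringsAsFactors = FALSE)
  tie <- assign_genes(data.frame(snp_id = "t", chrom = "chr1",
                                 pos = 150000L, stringsAsFactors = FALSE),
                      sym)
  expect_identical(tie$assigned_gene, "B2")  # smaller start wins the tie
})

test_that("a SNP covered by overlapping genes goes to the nearest midpoint", {
  # midpoints: big 50,000; small 49,000 -> the SNP at 49,000 is nearer to
  # the midpoint of the small nested gene
  genes <- data.frame(chrom = "chr1", start = c(0L, 40000L),
                      end = c(100000L, 58000L), name = c("big", "small"),
                      stringsAsFactors = FALSE)
  ann <- assign_genes(data.frame(snp_id = "s", chrom = "chr1", pos = 49000L,
                                 stringsAsFactors = FALSE), genes)
  expect_identical(ann$assigned_gene, "small")
  expect_identical(ann$distance_bp, 0)
})

test_that("assignment is invariant to gene file order", {
  cfg <- sim_config(n_loci = 300, n_genes = 60, seed = 13)
  ann <- simulate_annotation(cfg)
  a1 <- assign_genes(ann$map, ann$genes)
  set.seed(2)
  a2 <- assign_genes(ann$map, ann$genes[sample.int(nrow(ann$genes)), ])
  expect_identical(a1, a2)
  expect_true(all(a1$distance_bp[a1$genic] <= 50000))
})

test_that("regulatory distances honour BED coordinate conventions", {
  reg <- data.frame(chrom = "chr1", start = 2000L, end = 2100L,
                    name = "r1", stringsAsFactors = FALSE)
  map <- data.frame(snp_id = c("before", "covered"), chrom = "chr1",
                    pos = c(1000L, 2050L), stringsAsFactors = FALSE)
  d <- nearest_regulatory(map, reg)
  # first interval base is 1-based 2001; gap = 2001 - 1000 - 1 = 1000
  expect_identical(d$nearest_regulatory_distance_bp, c(1000, 0))
  # empty interval table -> all distances NA
  none <- nearest_regulatory(map, reg[0, , drop = FALSE])
  expect_true(all(is.na(none$nearest_regulatory_distance_bp)))
  # two equidistant intervals -> that common distance
  reg2 <- rbind(reg, data.frame(chrom = "chr1", start = 0L, end = 101L,
                                name = "r0", stringsAsFactors = FALSE))
  # SNP at 1051: 949 bp from r0 (last base 101) and from r1 (first base 2001)
  d2 <- nearest_regulatory(data.frame(snp_id = "mid", chrom = "chr1",
                                      pos = 1051L, stringsAsFactors = FALSE),
                           reg2)
  expect_identical(d2$nearest_regulatory_distance_bp, 949)
})

test_that("functional classes join passively with 'none' as default", {
  ann <- data.frame(snp_id = c("a", "b"), assigned_gene = c("g", NA),
                    distance_bp = c(0, NA), genic = c(TRUE, FALSE),
                    stringsAsFactors = FALSE)
  fn <- data.frame(snp_id = "a", functional_class = "missense",
                   stringsAsFactors = FALSE)
  out <- attach_functional(ann, fn)
  expect_identical(out$functional_class, c("missense", "none"))
  expect_identical(attach_functional(ann, NULL)$functional_class,
                   c("none", "none"))
  bad <- data.frame(snp_id = "a", functional_class = "weird",
                    stringsAsFactors = FALSE)
  expect_error(attach_functional(ann, bad), "unknown functional class")
})
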