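test_that("MAF filter applies the strict 'below' rule on pooled frequency", {
  # pooled alt counts over 4 pops of 60 alleles each = 240 alleles
  alt <- rbind(c(3, 3, 2, 1),    # pooled 9/240 = 0.0375 < 0.05 -> drop
               c(3, 3, 3, 3),    # pooled 12/240 = 0.05 -> keep (not below)
               c(0, 0, 0, 0),    # monomorphic -> drop always
               c(60, 60, 60, 60),# monomorphic at 1 -> drop always
               c(30, 20, 25, 35))
  panel <- tiny_panel(alt)
  kept <- filter_maf(panel, 0.05)
  expect_identical(kept$map$snp_id, c("s002", "s005"))
  kept0 <- filter_maf(panel, 0)
  expect_false(any(c("s003", "s004") %in% kept0$map$snp_id))
  expect_error(filter_maf(panel, 0.7), "0, 0.5")
  mono <- tiny_panel(rbind(c(0, 0, 0, 0)))
  expect_error(filter_maf(mono, 0), class = "empty_panel_error")
})

test_that("locus log-likelihood matches numerical integration", {
  # frozen grid of 20 single-population cases spanning counts, F and pool
  grid <- expand.grid(n = c(10L, 60L), a_frac = c(0, 0.3, 0.77, 1),
                      f = c(0.05, 0.35), p = c(0.12, 0.6),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[seq_len(20), ]
  for (k in seq_len(nrow(grid))) {
    n <- grid$n[k]; a <- round(grid$a_frac[k] * n)
    alpha <- qlogis(grid$f[k]) + 1  # arbitrary split of logit-F
    beta <- -1
    got <- locus_loglik(a, n, grid$p[k], alpha, beta)
    want <- quadrature_loglik(a, n, grid$p[k], alpha, beta)
    expect_equal(got, want, tolerance = 1e-6)
  }
  # spot check: one population, n=10, alt=3, F=0.1, p=0.4
  got <- locus_loglik(3, 10, 0.4, 0, qlogis(0.1))
  want <- quadrature_loglik(3, 10, 0.4, 0, qlogis(0.1))
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("locus log-likelihood symmetry and degenerate cases", {
  expect_identical(locus_loglik(integer(0), integer(0), 0.4, 0, -1), 0)
  expect_identical(locus_loglik(c(0L, 0L), c(0L, 0L), 0.4, 1, c(-1, -2)), 0)
  a <- c(3L, 41L); n <- c(10L, 60L); b <- c(-1, -0.5)
  expect_equal(locus_loglik(a, n, 0.37, 0.8, b),
               locus_loglik(n - a, n, 1 - 0.37, 0.8, b), tolerance = 1e-12)
  expect_error(locus_loglik(3, 10, 1.2, 0, -1), "inside")
  expect_error(locus_loglik(-1, 10, 0.4, 0, -1), "counts")
})

test_that("q-values are cumulative means of sorted PEPs with shared ties", {
  expect_equal(qvalues_from_posteriors(c(0.01, 0.04, 0.10, 0.50)),
               c(0.01, 0.025, 0.05, 0.1625))
  # input order independence
  expect_equal(qvalues_from_posteriors(c(0.50, 0.01, 0.10, 0.04)),
               c(0.1625, 0.01, 0.05, 0.025))
  expect_equal(qvalues_from_posteriors(rep(0, 5)), rep(0, 5))
  # ties share the larger q
  q <- qvalues_from_posteriors(c(0.1, 0.1, 0.4))
  expect_equal(q[1], q[2])
  expect_equal(q[1], 0.1)
  expect_error(qvalues_from_posteriors(numeric(0)), "empty")
  expect_error(qvalues_from_posteriors(c(0.5, 1.4)), "\\[0, 1\\]")
  # property: non-decreasing along the PEP-sorted order
  set.seed(1)
  for (rep in 1:20) {
    pep <- runif(50)
    q <- qvalues_from_posteriors(pep)
    expect_true(all(diff(q[order(pep)]) >= -1e-12))
    expect_true(all(q <= pep + 1e-12))  # q never exceeds the PEP itself
  }
})

test_that("model calls follow the q-threshold and posterior ordering rules", {
  df <- data.frame(P_neutral = c(0.05, 0.05, 0.30, 0.10),
                   P_sel_g1 = c(0.15, 0.60, 0.30, 0.35),
                   P_sel_g2 = c(0.10, 0.20, 0.20, 0.35),
                   P_conv = c(0.70, 0.15, 0.20, 0.20),
                   qvalue = c(0.02, 0.02, 0.25, 0.02))
  expect_warning(calls <- classify_locus(df, fdr = 0.1), "tie")
  expect_identical(calls, c("convergent", "sel_g1", "neutral", "sel_g1"))
  # tie between single-group models goes to sel_g1
  tie <- data.frame(P_neutral = 0.2, P_sel_g1 = 0.35, P_sel_g2 = 0.35,
                    P_conv = 0.1, qvalue = 0.01)
  expect_warning(expect_identical(classify_locus(tie), "sel_g1"))
  bad <- data.frame(P_neutral = 0.5, P_sel_g1 = 0.4, P_sel_g2 = 0.2,
                    P_conv = 0.2, qvalue = 0.01)
  expect_error(classify_locus(bad), "sum to 1")
})

test_that("scan posteriors sum to one and favour neutrality without signal", {
  alt <- rbind(c(20, 22, 21, 19))
  panel <- tiny_panel(alt)
  scan <- run_scan(panel, scan_config(pilot_runs = 2, pilot_length = 100,
                                      burn_in = 500, n_samples = 500,
                                      thinning = 1, seed = 2))
  probs <- scan[, c("P_neutral", "P_sel_g1", "P_sel_g2", "P_conv")]
  expect_equal(rowSums(probs), rep(1, nrow(scan)), tolerance = 1e-9)
  expect_equal(which.max(unlist(probs[1, ])), c(P_neutral = 1L))
  three_group <- tiny_panel(rbind(c(10, 20, 30, 40)),
                            groups = c("a", "b", "c", "c"))
  expect_error(run_scan(three_group), "two groups")
})

test_that("two chains with different seeds agree on a 5-locus panel", {
  set.seed(4)
  alt <- matrix(rbinom(20, 60, rep(c(0.2, 0.5, 0.8, 0.35, 0.6), 4)), 5, 4)
  panel <- tiny_panel(alt)
  cfg1 <- scan_config(pilot_runs = 3, pilot_length = 200, burn_in = 2000,
                      n_samples = 4000, thinning = 1, seed = 101)
  cfg2 <- cfg1; cfg2$seed <- 707L
  s1 <- run_scan(panel, cfg1)
  s2 <- run_scan(panel, cfg2)
  expect_lt(max(abs(s1$P_neutral - s2$P_neutral)), 0.05)
})

test_that("scan is reproducible for a fixed seed", {
  sim <- simulate_panel(sim_config(n_loci = 60, seed = 12))
  panel <- filter_maf(sim$panel)
  cfg <- scan_config(pilot_runs = 2, pilot_length = 100, burn_in = 300,
                     n_samples = 300, thinning = 1, seed = 9)
  expect_identical(run_scan(panel, cfg), run_scan(panel, cfg))
})

test_that("a fully neutral panel yields almost no outlier calls", {
  cfg <- sim_config(n_loci = 500, prop_selected_g1 = 0, prop_selected_g2 = 0,
                    prop_selected_both = 0, seed = 33)
  sim <- simulate_panel(cfg)
  panel <- filter_maf(sim$panel)
  scan <- run_scan(panel, scan_config(pilot_runs = 5, pilot_length = 200,
                                      burn_in = 2000, n_samples = 1500,
                                      thinning = 3, seed = 14))
  expect_lte(mean(scan$qvalue < 0.1), 0.02)
})

test_that("posterior selection probability increases with true alpha", {
  p_sel <- vapply(c(1, 3), function(a) {
    cfg <- sim_config(n_loci = 400, alpha_effect = a,
                      prop_selected_g1 = 0, prop_selected_g2 = 0,
                      prop_selected_both = 0.25, seed = 44)
    sim <- simulate_panel(cfg)
    panel <- filter_maf(sim$panel)
    scan <- run_scan(panel, scan_config(pilot_runs = 4, pilot_length = 200,
                                        burn_in = 1500, n_samples = 1500,
                                        thinning = 2, seed = 15))
    truth <- sim$truth[match(scan$snp_id, sim$truth$snp_id), ]
    mean(1 - scan$P_neutral[truth$label == "convergent"])
  }, numeric(1))
  expect_gt(p_sel[2], p_sel[1])
})
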