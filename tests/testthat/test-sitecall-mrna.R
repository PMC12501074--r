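# two cellular and two IVT replicates around the worked mRNA scenario:
# cell ratios {0.30, 0.28} at depth 200 each, IVT {0.03, 0.04},
# input2 0.02, background 0.05, motif GATAG
mrna_case <- function(cell_ratios = c(0.30, 0.28),
                      ivt_ratios = c(0.03, 0.04),
                      depth = 200, input2_ratio = 0.02, motif = "GATAG",
                      bg = 0.05, trna_regions = NULL,
                      config = mrna_config()) {
  cell <- do.call(rbind, lapply(seq_along(cell_ratios), function(r) {
    rec_ratio("ref1", 5, cell_ratios[r], depth, "treated", replicate = r)
  }))
  ivt <- do.call(rbind, lapply(seq_along(ivt_ratios), function(r) {
    rec_ratio("ref1", 5, ivt_ratios[r], depth, "ivt", replicate = r)
  }))
  call_sites_mrna(cell, ivt,
                  input2 = rec_ratio("ref1", 5, input2_ratio, depth,
                                     "input2"),
                  reference = motif_ref(motif),
                  background = flat_background(bg, motif),
                  trna_regions = trna_regions, config = config)
}

test_that("the replicate t-test matches closed-form and stats::t.test", {
  a <- c(0.30, 0.28); b <- c(0.03, 0.04)
  # Welch: t from means/variances, Welch-Satterthwaite df, symmetric tail
  se2 <- var(a) / 2 + var(b) / 2
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((var(a) / 2)^2 + (var(b) / 2)^2)
  expected <- 2 * pt(-abs(tstat), df)
  expect_equal(welch_ttest_two_sided(a, b), expected, tolerance = 1e-12)
  expect_equal(welch_ttest_two_sided(a, b),
               t.test(a, b)$p.value, tolerance = 1e-12)
  expect_equal(welch_ttest_two_sided(a, b, var_equal = TRUE),
               t.test(a, b, var.equal = TRUE)$p.value, tolerance = 1e-12)
  # degenerate: identical zero-variance groups
  p <- welch_ttest_two_sided(c(0.3, 0.3), c(0.3, 0.3))
  expect_equal(as.numeric(p), 1)
  expect_true(attr(p, "degenerate"))
  p0 <- welch_ttest_two_sided(c(0.3, 0.3), c(0.1, 0.1))
  expect_equal(as.numeric(p0), 0)
  expect_error(welch_ttest_two_sided(c(0.3), c(0.1, 0.2)),
               "two replicate")
})

test_that("the one-sided binomial test is the exact upper tail", {
  expect_equal(binom_test_greater(3, 3, 0.5), 0.125)
  expect_equal(binom_test_greater(0, 17, 0.3), 1.0)
  # direct summation oracle
  k <- 5; n <- 10; p0 <- 0.07
  oracle <- sum(choose(n, k:n) * p0^(k:n) * (1 - p0)^(n - (k:n)))
  expect_equal(binom_test_greater(k, n, p0), oracle, tolerance = 1e-14)
  expect_error(binom_test_greater(5, 3, 0.5), "k <= n")
  expect_error(binom_test_greater(1, 3, 1.5), "p0")
})

test_that("a clean mRNA site passes all eight criteria", {
  calls <- mrna_case()
  expect_equal(nrow(calls), 1L)
  expect_true(calls$called)
  expect_lt(calls$p_ttest, 0.05)
  expect_lt(calls$p_binom, 0.05)
  expect_gt(calls$fold_ivt, 3)
  expect_false(calls$provisional)
})

test_that("tRNA overlap, high IVT signal and low depth each reject", {
  # site inside a tRNA interval (BED-convention 0-based half-open)
  trna <- data.frame(ref_id = "ref1", start = 0, end = 9)
  c4 <- mrna_case(trna_regions = trna)
  expect_false(c4$crit_not_trna)
  expect_false(c4$called)
  # an interval elsewhere does not touch the site
  away <- data.frame(ref_id = "ref1", start = 6, end = 9)
  expect_true(mrna_case(trna_regions = away)$called)

  # IVT replicate ratios above 0.2 break criteria 2 and 3
  c23 <- mrna_case(ivt_ratios = c(0.22, 0.25))
  expect_false(c23$crit_ratio_ivt)
  expect_false(c23$crit_ttest_fold_ivt)
  expect_false(c23$called)

  # merged cellular depth 24 fails "above 30"
  c6 <- mrna_case(depth = 12)
  expect_false(c6$crit_depth)
  expect_false(c6$called)
})

test_that("single-replicate runs are provisional and never called", {
  cell <- rec_ratio("ref1", 5, 0.30, 200, "treated")
  ivt <- rec_ratio("ref1", 5, 0.03, 200, "ivt")
  expect_warning(
    calls <- call_sites_mrna(cell, ivt,
                             input2 = rec_ratio("ref1", 5, 0.02, 200,
                                                "input2"),
                             reference = motif_ref("GATAG"),
                             background = flat_background(0.05, "GATAG")),
    "provisional")
  expect_true(calls$provisional)
  expect_true(is.na(calls$p_ttest))
  expect_false(calls$called)
})

test_that("the site universe requires coverage in cell and IVT", {
  cell <- rbind(rec_ratio("ref1", 5, 0.3, 200, "treated", replicate = 1),
                rec_ratio("ref1", 5, 0.3, 200, "treated", replicate = 2),
                rec_ratio("ref2", 5, 0.3, 200, "treated", replicate = 1),
                rec_ratio("ref2", 5, 0.3, 200, "treated", replicate = 2))
  ivt <- rbind(rec_ratio("ref1", 5, 0.03, 200, "ivt", replicate = 1),
               rec_ratio("ref1", 5, 0.04, 200, "ivt", replicate = 2))
  ref <- c(motif_ref("GATAG", "ref1"), motif_ref("GATAG", "ref2"))
  calls <- call_sites_mrna(cell, ivt,
                           input2 = rec_ratio("ref1", 5, 0.02, 200,
                                              "input2"),
                           reference = ref,
                           background = flat_background(0.05, "GATAG"))
  expect_equal(calls$ref_id, "ref1")
})

test_that("BH adjustment never rescues a site the raw binomial rejects", {
  cfg <- sim_config(seed = 515, n_refs = 5, ref_length = 500, depth = 150,
                    n_sites = 12, d_fractions = seq(0.15, 0.45,
                                                    length.out = 12),
                    replicates = c(treated = 2, input2 = 1, ivt = 2))
  sim <- simulate_counts(cfg)
  bg <- flat_background(0.05)
  raw <- call_sites_mrna(sim$counts$treated, sim$counts$ivt,
                         input2 = sim$counts$input2,
                         reference = sim$reference, background = bg,
                         config = mrna_config(multiple_testing = "none"))
  bh <- call_sites_mrna(sim$counts$treated, sim$counts$ivt,
                        input2 = sim$counts$input2,
                        reference = sim$reference, background = bg,
                        config = mrna_config(multiple_testing = "bh"))
  expect_true(all(bh$p_binom >= raw$p_binom - 1e-12))
  expect_true(all(bh$crit_binom <= raw$crit_binom, na.rm = TRUE))
  called_bh <- paste(bh$ref_id[bh$called], bh$pos[bh$called])
  called_raw <- paste(raw$ref_id[raw$called], raw$pos[raw$called])
  expect_true(all(called_bh %in% called_raw))
})

test_that("mRNA thresholds are monotone in the called set", {
  cfg <- sim_config(seed = 516, n_refs = 5, ref_length = 500, depth = 150,
                    n_sites = 15, d_fractions = seq(0.1, 0.5,
                                                    length.out = 15),
                    replicates = c(treated = 2, input2 = 1, ivt = 2))
  sim <- simulate_counts(cfg)
  bg <- flat_background(0.05)
  run <- function(...) {
    calls <- call_sites_mrna(sim$counts$treated, sim$counts$ivt,
                             input2 = sim$counts$input2,
                             reference = sim$reference, background = bg,
                             config = mrna_config(...))
    paste(calls$ref_id[calls$called], calls$pos[calls$called])
  }
  base <- run()
  expect_gt(length(base), 0L)
  expect_true(all(run(min_ratio_cell = 0.3) %in% base))
  expect_true(all(run(max_ratio_ivt = 0.1) %in% base))
  expect_true(all(run(max_p_ttest = 0.01) %in% base))
  expect_true(all(run(fold_over_ivt = 6) %in% base))
  expect_true(all(run(fold_over_background = 4) %in% base))
  expect_true(all(run(min_depth_cell = 250) %in% base))
  expect_true(all(run(max_p_binom = 0.001) %in% base))
})
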