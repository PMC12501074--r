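# worked single-site scenario used across criterion checks:
# treated tc ratio 0.25 (25 C / 75 T), inputs at 0.05 / 0.04, depth 100,
# motif GATAG, background 0.07
ncrna_case <- function(treated_ratio = 0.25, depth_treated = 100,
                       input1_ratio = 0.05, input2_ratio = 0.04,
                       depth_inputs = 100, motif = "GATAG", bg = 0.07,
                       config = ncrna_config()) {
  call_sites_ncrna(
    rec_ratio("ref1", 5, treated_ratio, depth_treated, "treated"),
    rec_ratio("ref1", 5, input1_ratio, depth_inputs, "input1"),
    rec_ratio("ref1", 5, input2_ratio, depth_inputs, "input2"),
    reference = motif_ref(motif),
    background = flat_background(bg, motif),
    config = config)
}

test_that("a clean site satisfying all seven criteria is called", {
  calls <- ncrna_case()
  expect_equal(nrow(calls), 1L)
  expect_true(calls$called)
  expect_true(all(unlist(calls[paste0("crit_", c("ratio_treated",
    "input_ratio", "depth", "fold_background", "fold_input2",
    "not_multi_u", "u_site"))])))
  expect_equal(calls$motif, "GATAG")
  expect_equal(calls$ratio_treated, 0.25)
})

test_that("each criterion rejects on its own boundary", {
  # treated ratio at 18% (below the strict 20% cutoff)
  c1 <- ncrna_case(treated_ratio = 0.18)
  expect_false(c1$called)
  expect_false(c1$crit_ratio_treated)
  # misincorporation count must exceed five: ratio 0.25 at depth 20 is
  # only 5 C reads
  c1b <- ncrna_case(depth_treated = 20,
                    config = ncrna_config(min_depth = 10))
  expect_false(c1b$crit_ratio_treated)
  # input ratio at the 15% bound fails strictly
  c2 <- ncrna_case(input1_ratio = 0.16)
  expect_false(c2$crit_input_ratio)
  # treated depth 40 fails "above 50"
  c3 <- ncrna_case(depth_treated = 40)
  expect_false(c3$crit_depth)
  expect_false(c3$called)
  # 3-fold over background: 0.25 < 3 x 0.09 = 0.27
  c4 <- ncrna_case(bg = 0.09)
  expect_false(c4$crit_fold_background)
  expect_true(c4$crit_ratio_treated)
  # 3-fold over Input2: 0.25 < 3 x 0.09
  c5 <- ncrna_case(input2_ratio = 0.09)
  expect_false(c5$crit_fold_input2)
  # multiple-U context excluded
  c6 <- ncrna_case(motif = "GTTAG")
  expect_false(c6$crit_not_multi_u)
  expect_false(c6$called)
})

test_that("multi-U context detection has adjacent and strict modes", {
  expect_false(is_multi_u("GATAG"))
  expect_true(is_multi_u("GTTAG"))   # left neighbour U
  expect_true(is_multi_u("GATTA"))   # right neighbour U
  # distal extra U only flagged in strict mode
  expect_false(is_multi_u("TATAG", mode = "adjacent"))
  expect_true(is_multi_u("TATAG", mode = "any"))
  expect_error(is_multi_u("GAAAG"), "central")
})

test_that("sites missing from an input are reported but never called", {
  calls <- call_sites_ncrna(
    rec_ratio("ref1", 5, 0.25, 100, "treated"),
    rec_ratio("ref1", 5, 0.05, 100, "input1")[0, ],
    rec_ratio("ref1", 5, 0.04, 100, "input2"),
    reference = motif_ref("GATAG"),
    background = flat_background(0.07, "GATAG"))
  expect_equal(nrow(calls), 1L)
  expect_true(calls$missing_data)
  expect_false(calls$called)
  # fully empty treated input -> empty output
  empty <- call_sites_ncrna(
    rec_ratio("ref1", 5, 0.25, 100, "treated")[0, ],
    rec_ratio("ref1", 5, 0.05, 100, "input1"),
    rec_ratio("ref1", 5, 0.04, 100, "input2"),
    reference = motif_ref("GATAG"),
    background = flat_background(0.07, "GATAG"))
  expect_equal(nrow(empty), 0L)
})

test_that("only reference-T sites ever appear in the output", {
  treated <- rbind(rec_ratio("ref1", 5, 0.3, 100, "treated"),
                   rec("ref1", 3, 40, 60, "treated", ref_base = "G"))
  calls <- call_sites_ncrna(
    treated,
    rec_ratio("ref1", 5, 0.05, 100, "input1"),
    rec_ratio("ref1", 5, 0.04, 100, "input2"),
    reference = motif_ref("GATAG"),
    background = flat_background(0.05, "GATAG"))
  expect_equal(calls$pos, 5L)
})

test_that("calling is invariant to how replicates are split", {
  cfg <- sim_config(seed = 402, n_refs = 3, ref_length = 300, depth = 300,
                    n_sites = 8, d_fractions = c(0.3, 0.5, 0.7),
                    replicates = c(treated = 2, input1 = 1, input2 = 1))
  sim <- simulate_counts(cfg)
  bg <- flat_background(0.05)
  a <- call_sites_ncrna(sim$counts$treated, sim$counts$input1,
                        sim$counts$input2, sim$reference, bg)
  merged <- merge_replicates(sim$counts$treated)
  merged$sample_id <- "pooled"
  merged$condition <- "treated"
  merged$replicate <- 1L
  b <- call_sites_ncrna(merged, sim$counts$input1, sim$counts$input2,
                        sim$reference, bg)
  expect_equal(a, b)
})

test_that("raising any threshold never enlarges the called set", {
  cfg <- sim_config(seed = 403, n_refs = 4, ref_length = 400, depth = 120,
                    n_sites = 25,
                    d_fractions = seq(0.1, 0.6, length.out = 25),
                    replicates = c(treated = 1, input1 = 1, input2 = 1))
  sim <- simulate_counts(cfg)
  bg <- flat_background(0.05)
  run <- function(...) {
    calls <- call_sites_ncrna(sim$counts$treated, sim$counts$input1,
                              sim$counts$input2, sim$reference, bg,
                              config = ncrna_config(...))
    paste(calls$ref_id[calls$called], calls$pos[calls$called])
  }
  base <- run()
  expect_true(all(run(min_ratio_treated = 0.3) %in% base))
  expect_true(all(run(min_mis_count = 20) %in% base))
  expect_true(all(run(max_ratio_input = 0.05) %in% base))
  expect_true(all(run(min_depth = 100) %in% base))
  expect_true(all(run(fold_over_background = 6) %in% base))
  expect_true(all(run(fold_over_input2 = 6) %in% base))
})

test_that("position summaries group stoichiometry by annotation label", {
  calls <- data.frame(ref_id = c("t1", "t2", "t3", "t4"),
                      pos = c(47, 47, 47, 20),
                      d_fraction = c(0.6, 0.7, 0.8, 0.5))
  ann <- data.frame(ref_id = c("t1", "t2", "t3"), pos = 47, label = "47")
  s <- summarize_by_position(calls, ann)
  s47 <- s[s$label == "47", ]
  expect_equal(s47$n, 3L)
  expect_equal(s47$mean_fraction, 0.7)
  expect_equal(sort(s47$fractions[[1]]), c(0.6, 0.7, 0.8))
  expect_equal(s$label[s$n == 1], "unannotated")
  expect_equal(nrow(summarize_by_position(calls[0, ], ann)), 0L)
})
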