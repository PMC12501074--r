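#' Configuration for the eight-criterion IVT-background mRNA caller
#'
#' Defaults follow the published cutoffs for mRNA: cellular mutation
#' ratio above 20%; IVT ratio below 20%; replicate t-test p below 0.05
#' together with a 3-fold cellular/IVT ratio; no tRNA-region overlap;
#' 2-fold over the motif background and over Input2; cellular coverage
#' depth above 30; no multiple-U context; and a binomial test of the
#' cellular misincorporation count against the motif background.
#'
#' @param min_ratio_cell cellular tc ratio must exceed this (0.20).
#' @param max_ratio_ivt IVT tc ratio must stay below this (0.20).
#' @param max_p_ttest replicate t-test p-value cutoff (0.05).
#' @param fold_over_ivt required cellular/IVT ratio fold (3; a 2-fold
#'   variant circulates in pipeline flowcharts, the stricter published
#'   cutoff is the default).
#' @param fold_over_background required fold over motif background (2).
#' @param fold_over_input2 required fold over the Input2 ratio (2).
#' @param min_depth_cell cellular depth must exceed this (30, strict,
#'   same literal reading of "above" as the ncRNA caller).
#' @param exclude_multi_u,multi_u_mode,ratio_mode,mis_count_mode,eps as in
#'   [ncrna_config()].
#' @param max_p_binom binomial-test p-value cutoff (0.05).
#' @param multiple_testing `"none"` (published behaviour) or `"bh"`
#'   (Benjamini-Hochberg across tested sites) for the binomial p-values.
#' @param var_equal pooled-variance Student t-test when `TRUE` (default,
#'   the conventional two-sample test with duplicate libraries); `FALSE`
#'   switches to Welch.
#' @param binom_null `"background"` tests against the motif background
#'   rate; `"ivt"` against the site's merged IVT ratio.
#' @return a list of class `craci_mrna_config`.
#' @export
mrna_config <- function(min_ratio_cell = 0.20,
                        max_ratio_ivt = 0.20,
                        max_p_ttest = 0.05,
                        fold_over_ivt = 3.0,
                        fold_over_background = 2.0,
                        fold_over_input2 = 2.0,
                        min_depth_cell = 30,
                        exclude_multi_u = TRUE,
                        multi_u_mode = c("adjacent", "any"),
                        ratio_mode = c("tc", "any_mismatch"),
                        max_p_binom = 0.05,
                        multiple_testing = c("none", "bh"),
                        var_equal = TRUE,
                        binom_null = c("background", "ivt"),
                        mis_count_mode = c("tc", "any"),
                        eps = .fold_eps) {
  stopifnot(max_p_ttest >= 0, max_p_ttest <= 1,
            max_p_binom >= 0, max_p_binom <= 1,
            fold_over_ivt >= 1, fold_over_background >= 1,
            fold_over_input2 >= 1, min_ratio_cell >= 0, max_ratio_ivt >= 0)
  cfg <- list(min_ratio_cell = min_ratio_cell,
              max_ratio_ivt = max_ratio_ivt,
              max_p_ttest = max_p_ttest,
              fold_over_ivt = fold_over_ivt,
              fold_over_background = fold_over_background,
              fold_over_input2 = fold_over_input2,
              min_depth_cell = min_depth_cell,
              exclude_multi_u = isTRUE(exclude_multi_u),
              multi_u_mode = match.arg(multi_u_mode),
              ratio_mode = match.arg(ratio_mode),
              max_p_binom = max_p_binom,
              multiple_testing = match.arg(multiple_testing),
              var_equal = isTRUE(var_equal),
              binom_null = match.arg(binom_null),
              mis_count_mode = match.arg(mis_count_mode),
              eps = eps)
  class(cfg) <- "craci_mrna_config"
  cfg
}

#' Two-sided two-sample t-test on replicate mutation ratios
#'
#' @param a,b numeric vectors of per-replicate ratios, each with at least
#'   two values.
#' @param var_equal `FALSE` (default) gives the Welch unequal-variance
#'   test with Satterthwaite degrees of freedom; `TRUE` the pooled
#'   Student test.
#' @return the two-sided p-value. Degenerate inputs (both groups with
#'   zero variance) return 1 when the means agree and 0 when they differ,
#'   with attribute `"degenerate" = TRUE`.
#' @export
welch_ttest_two_sided <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("t-test requires at least two replicate values per group")
  }
  p <- .ttest_vec(mean(a), stats::var(a), length(a),
                  mean(b), stats::var(b), length(b), var_equal)
  if (attr(p, "degenerate")[1]) {
    out <- as.numeric(p)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  as.numeric(p)
}

# vectorized two-sample t on summary stats; returns p with "degenerate" attr
.ttest_vec <- function(ma, va, na, mb, vb, nb, var_equal) {
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- na + nb - 2
  } else {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  degenerate <- !is.na(se2) & se2 == 0
  t <- (ma - mb) / sqrt(se2)
  p <- 2 * pt(-abs(t), df)
  p[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 1, 0)
  attr(p, "degenerate") <- degenerate
  p
}

#' One-sided (upper tail) exact binomial test
#'
#' Probability of observing `k` or more misincorporations out of `n`
#' trials under a background rate `p0`: `P[X >= k]`, `X ~ Binomial(n, p0)`.
#'
#' @param k observed misincorporation count(s).
#' @param n number of trials (tc denominator).
#' @param p0 null background rate(s) in `[0, 1]`.
#' @return exact upper-tail p-value(s); `k = 0` gives 1 by convention
#'   (the whole outcome space).
#' @export
binom_test_greater <- function(k, n, p0) {
  if (any(k < 0) || any(k > n)) stop("require 0 <= k <= n")
  if (any(p0 < 0 | p0 > 1)) stop("p0 must lie in [0, 1]")
  pbinom(k - 1, n, p0, lower.tail = FALSE)
}

# per-replicate tc ratio summary stats keyed by site
.rep_ratio_stats <- function(records, cfg) {
  records <- validate_count_table(records)
  t_rec <- records[records$ref_base == "T", , drop = FALSE]
  g <- paste(t_rec$ref_id, t_rec$pos, t_rec$strand, t_rec$replicate,
             sep = "\r")
  sums <- rowsum(t_rec[, c("n_A", "n_C", "n_G", "n_T")], group = g,
                 reorder = TRUE)
  parts <- do.call(rbind, strsplit(rownames(sums), "\r", fixed = TRUE))
  site <- paste(parts[, 1], parts[, 2], parts[, 3], sep = "\r")
  den <- if (cfg$ratio_mode == "tc") {
    sums$n_C + sums$n_T
  } else {
    sums$n_A + sums$n_C + sums$n_G + sums$n_T
  }
  num <- if (cfg$ratio_mode == "tc") {
    sums$n_C
  } else {
    den - sums$n_T
  }
  ratio <- ifelse(den > 0, num / den, NA_real_)
  keep <- !is.na(ratio)
  site <- site[keep]; ratio <- ratio[keep]
  f <- factor(site)
  nrep <- as.integer(table(f))
  m <- as.numeric(rowsum(ratio, f) / nrep)
  s2raw <- as.numeric(rowsum(ratio^2, f))
  v <- ifelse(nrep > 1, (s2raw - nrep * m^2) / (nrep - 1), NA_real_)
  v <- pmax(v, 0)  # guard tiny negative from cancellation
  data.frame(key = levels(f), n_rep = nrep, mean = m, var = v,
             stringsAsFactors = FALSE)
}

#' Call D sites in mRNA against an IVT background
#'
#' The site universe is every reference-T site covered in both the merged
#' cellular and merged IVT libraries; each is evaluated against the eight
#' criteria (see [mrna_config()]). The replicate t-test compares
#' per-replicate tc ratios; every other criterion uses count-merged
#' ratios.
#'
#' @param cell,ivt count-table data.frames with a replicate structure
#'   (the `replicate` column distinguishes libraries).
#' @param input2 optional count-table for the Input2 control; when
#'   `NULL`, the Input2 half of the fold criterion is skipped and flagged.
#' @param reference reference sequences (see [as_reference()]).
#' @param background background table from [build_background()].
#' @param trna_regions `GRanges` (or BED-convention data.frame accepted by
#'   [region_set()]) of tRNA intervals to exclude; `NULL` for none.
#' @param curves optional calibration table for stoichiometry.
#' @param config a [mrna_config()].
#' @return data.frame of site calls with per-condition ratios/depths,
#'   `p_ttest`, `p_binom` (BH-adjusted when configured), fold changes,
#'   criterion flags, `d_fraction`, `provisional` (single-replicate runs:
#'   the t-test cannot be evaluated, the site can never be `called`), and
#'   `called`.
#' @export
call_sites_mrna <- function(cell, ivt, input2 = NULL, reference,
                            background, trna_regions = NULL, curves = NULL,
                            config = mrna_config()) {
  cfg <- config
  cm <- .t_site_table(cell, cfg)
  vm <- .t_site_table(ivt, cfg)
  shared <- intersect(cm$key, vm$key)
  cm <- cm[match(shared, cm$key), , drop = FALSE]
  vm <- vm[match(shared, vm$key), , drop = FALSE]
  if (length(shared) == 0L) return(.empty_mrna_calls())

  out <- cm[, c("ref_id", "pos", "strand")]
  out$motif <- .motifs_for_sites(reference, cm$ref_id, cm$pos)
  out$depth_treated <- cm$depth
  out$ratio_treated <- cm$ratio
  out$mis_count_treated <- cm$mis_count
  out$depth_ivt <- vm$depth
  out$ratio_ivt <- vm$ratio

  if (!is.null(input2)) {
    i2 <- .t_site_table(input2, cfg)
    j2 <- match(cm$key, i2$key)
    out$ratio_input2 <- i2$ratio[j2]
    out$depth_input2 <- i2$depth[j2]
  } else {
    out$ratio_input2 <- NA_real_
    out$depth_input2 <- NA_real_
  }

  bg <- .bg_lookup(background, out$motif)
  out$bg_ratio <- bg$rate
  out$bg_fallback <- bg$fallback
  out$fold_background <- out$ratio_treated / pmax(out$bg_ratio, cfg$eps)
  out$fold_input2 <- out$ratio_treated / pmax(out$ratio_input2, cfg$eps)
  out$fold_ivt <- out$ratio_treated / pmax(out$ratio_ivt, cfg$eps)

  # replicate-level t-test
  cs <- .rep_ratio_stats(cell, cfg)
  vs <- .rep_ratio_stats(ivt, cfg)
  jc <- match(cm$key, cs$key)
  jv <- match(cm$key, vs$key)
  n_a <- cs$n_rep[jc]; n_b <- vs$n_rep[jv]
  testable <- !is.na(n_a) & !is.na(n_b) & n_a >= 2L & n_b >= 2L
  out$p_ttest <- NA_real_
  if (any(testable)) {
    p <- .ttest_vec(cs$mean[jc][testable], cs$var[jc][testable], n_a[testable],
                    vs$mean[jv][testable], vs$var[jv][testable], n_b[testable],
                    cfg$var_equal)
    out$p_ttest[testable] <- as.numeric(p)
  }
  out$provisional <- !testable
  if (any(out$provisional)) {
    warning(sum(out$provisional), " site(s) lack >=2 replicates per ",
            "condition; the replicate t-test cannot be evaluated and these ",
            "sites are provisional, never called")
  }

  # binomial test on merged cellular counts
  den <- if (cfg$ratio_mode == "tc") cm$n_C + cm$n_T else cm$depth
  null_rate <- if (cfg$binom_null == "background") {
    out$bg_ratio
  } else {
    pmax(out$ratio_ivt, cfg$eps)
  }
  out$p_binom <- binom_test_greater(cm$mis_count, den, null_rate)
  if (cfg$multiple_testing == "bh") {
    out$p_binom <- stats::p.adjust(out$p_binom, method = "BH")
  }

  # tRNA-region exclusion
  if (!is.null(trna_regions)) {
    if (is.data.frame(trna_regions)) trna_regions <- region_set(trna_regions)
    sites <- GenomicRanges::GRanges(out$ref_id,
                                    IRanges::IRanges(out$pos, out$pos))
    in_trna <- GenomicRanges::countOverlaps(sites, trna_regions,
                                            ignore.strand = TRUE) > 0
  } else {
    in_trna <- rep(FALSE, nrow(out))
  }
  out$in_trna <- in_trna

  c1 <- out$ratio_treated > cfg$min_ratio_cell
  c2 <- out$ratio_ivt < cfg$max_ratio_ivt
  c3 <- out$p_ttest < cfg$max_p_ttest &
    out$ratio_treated > cfg$fold_over_ivt * pmax(out$ratio_ivt, cfg$eps)
  c4 <- !in_trna
  c5_bg <- out$ratio_treated > cfg$fold_over_background * out$bg_ratio
  c5_i2 <- if (is.null(input2)) {
    rep(TRUE, nrow(out))
  } else {
    out$ratio_treated > cfg$fold_over_input2 * pmax(out$ratio_input2, cfg$eps)
  }
  c5 <- c5_bg & c5_i2
  c6 <- out$depth_treated > cfg$min_depth_cell
  c7 <- if (cfg$exclude_multi_u) {
    !is_multi_u(out$motif, cfg$multi_u_mode)
  } else {
    rep(TRUE, nrow(out))
  }
  c8 <- out$p_binom < cfg$max_p_binom

  flags <- cbind(ratio_cell = c1, ratio_ivt = c2, ttest_fold_ivt = c3,
                 not_trna = c4, fold_bg_input2 = c5, depth = c6,
                 not_multi_u = c7, binom = c8)
  out[paste0("crit_", colnames(flags))] <- as.data.frame(flags)
  out$pass <- .criteria_string(flags, colnames(flags))
  ok <- rowSums(flags, na.rm = FALSE) == ncol(flags)
  out$called <- !is.na(ok) & ok & !out$provisional

  if (!is.null(curves)) {
    est <- estimate_fraction_by_motif(out$ratio_treated, out$motif, curves)
    out$d_fraction <- est$d_fraction
    out$clamped <- est$clamped
    out$curve_fallback <- est$fallback
  } else {
    out$d_fraction <- NA_real_
    out$clamped <- NA
    out$curve_fallback <- NA
  }
  rownames(out) <- NULL
  out
}

.empty_mrna_calls <- function() {
  data.frame(ref_id = character(0), pos = integer(0), strand = character(0),
             motif = character(0), depth_treated = numeric(0),
             ratio_treated = numeric(0), mis_count_treated = numeric(0),
             depth_ivt = numeric(0), ratio_ivt = numeric(0),
             ratio_input2 = numeric(0), depth_input2 = numeric(0),
             bg_ratio = numeric(0), bg_fallback = logical(0),
             fold_background = numeric(0), fold_input2 = numeric(0),
             fold_ivt = numeric(0), p_ttest = numeric(0),
             provisional = logical(0), p_binom = numeric(0),
             in_trna = logical(0), pass = character(0), called = logical(0),
             d_fraction = numeric(0), clamped = logical(0),
             curve_fallback = logical(0), stringsAsFactors = FALSE)
}
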