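#' Configuration for the seven-criterion ncRNA D caller
#'
#' Defaults are the published cutoffs: treated mutation ratio above 20%
#' with misincorporation count above five; input ratios below 15%;
#' coverage depth above 50 in treated and both inputs; treated ratio
#' 3-fold over the motif background and 3-fold over the Input2 ratio;
#' multiple-U contexts excluded; only reference-U sites considered.
#' "Above"/"below" are read literally as strict inequalities.
#'
#' @param min_ratio_treated treated tc ratio must exceed this (0.20).
#' @param min_mis_count treated misincorporation count must exceed this (5).
#' @param max_ratio_input input1/input2 ratios must be below this (0.15).
#' @param min_depth coverage must exceed this in treated and inputs (50).
#' @param fold_over_background required treated-ratio fold over the
#'   per-motif 0%-D background (3).
#' @param fold_over_input2 required treated-ratio fold over Input2 (3).
#' @param exclude_multi_u drop sites in multiple-U contexts (TRUE).
#' @param multi_u_mode `"adjacent"` (either immediate neighbour is U) or
#'   `"any"` (any additional U in the 5-mer).
#' @param ratio_mode mutation-ratio denominator, see [mutation_ratio()].
#' @param mis_count_mode `"tc"` counts `n_C` only; `"any"` counts all
#'   non-T calls.
#' @param eps floor applied to fold-change denominators.
#' @return a list of class `craci_ncrna_config`.
#' @export
ncrna_config <- function(min_ratio_treated = 0.20,
                         min_mis_count = 5,
                         max_ratio_input = 0.15,
                         min_depth = 50,
                         fold_over_background = 3.0,
                         fold_over_input2 = 3.0,
                         exclude_multi_u = TRUE,
                         multi_u_mode = c("adjacent", "any"),
                         ratio_mode = c("tc", "any_mismatch"),
                         mis_count_mode = c("tc", "any"),
                         eps = .fold_eps) {
  cfg <- list(min_ratio_treated = min_ratio_treated,
              min_mis_count = min_mis_count,
              max_ratio_input = max_ratio_input,
              min_depth = min_depth,
              fold_over_background = fold_over_background,
              fold_over_input2 = fold_over_input2,
              exclude_multi_u = isTRUE(exclude_multi_u),
              multi_u_mode = match.arg(multi_u_mode),
              ratio_mode = match.arg(ratio_mode),
              mis_count_mode = match.arg(mis_count_mode),
              eps = eps)
  stopifnot(min_ratio_treated >= 0, min_mis_count >= 0, max_ratio_input >= 0,
            min_depth >= 0, fold_over_background >= 1, fold_over_input2 >= 1)
  class(cfg) <- "craci_ncrna_config"
  cfg
}

#' Is a uridine in a multiple-U context?
#'
#' Consecutive U stretches accumulate mutation signal during analysis and
#' are excluded from calling. The default definition flags a central U
#' whose immediate 5' or 3' neighbour is also U; the stricter `"any"`
#' mode flags any additional U anywhere in the 5-mer.
#'
#' @param motif character vector of 5-mer contexts (central base `T`).
#' @param mode `"adjacent"` or `"any"`.
#' @return logical vector.
#' @export
is_multi_u <- function(motif, mode = c("adjacent", "any")) {
  mode <- match.arg(mode)
  stopifnot(all(nchar(motif) == 5L))
  if (any(substring(motif, 3, 3) != "T")) {
    stop("multi-U check requires a central 'T' (U) base")
  }
  if (mode == "adjacent") {
    substring(motif, 2, 2) == "T" | substring(motif, 4, 4) == "T"
  } else {
    flanks <- paste0(substring(motif, 1, 2), substring(motif, 4, 5))
    grepl("T", flanks, fixed = TRUE)
  }
}

#' Merge replicate count records by count summation
#'
#' Counts (not ratios) are summed per (ref_id, pos, strand, ref_base)
#' before ratio computation, so calling is invariant to how reads were
#' split across replicate files.
#'
#' @param records count-table data.frame.
#' @return data.frame keyed by site with summed counts and `depth`.
#' @export
merge_replicates <- function(records) {
  records <- validate_count_table(records)
  if (nrow(records) == 0L) {
    return(records[, c("ref_id", "pos", "strand", "ref_base",
                       "n_A", "n_C", "n_G", "n_T", "n_del", "depth")])
  }
  g <- paste(records$ref_id, records$pos, records$strand, records$ref_base,
             sep = "\r")
  sums <- rowsum(records[, c("n_A", "n_C", "n_G", "n_T", "n_del")],
                 group = g, reorder = TRUE)
  parts <- do.call(rbind, strsplit(rownames(sums), "\r", fixed = TRUE))
  out <- data.frame(ref_id = parts[, 1], pos = as.integer(parts[, 2]),
                    strand = parts[, 3], ref_base = parts[, 4],
                    sums, stringsAsFactors = FALSE)
  out$depth <- out$n_A + out$n_C + out$n_G + out$n_T
  out <- out[order(out$ref_id, out$pos, out$strand), ]
  rownames(out) <- NULL
  out
}

# merged reference-T site table with tc ratio and mis count for one condition
.t_site_table <- function(records, cfg) {
  m <- merge_replicates(records)
  m <- m[m$ref_base == "T", , drop = FALSE]
  den <- if (cfg$ratio_mode == "tc") m$n_C + m$n_T else m$depth
  num <- if (cfg$ratio_mode == "tc") m$n_C else m$depth - m$n_T
  m$ratio <- ifelse(den > 0, num / den, NA_real_)
  m$mis_count <- if (cfg$mis_count_mode == "tc") m$n_C else m$depth - m$n_T
  m$key <- paste(m$ref_id, m$pos, m$strand, sep = "\r")
  m
}

.criteria_string <- function(flags, labels) {
  cols <- lapply(seq_along(labels), function(j) {
    r <- flags[, j]
    paste0(labels[j], ":", ifelse(is.na(r), "NA", ifelse(r, "PASS", "FAIL")))
  })
  do.call(paste, c(cols, sep = ";"))
}

#' Call D sites in tRNA / ncRNA from treated and input libraries
#'
#' Evaluates every reference-T site covered in the treated libraries
#' against the seven criteria (see [ncrna_config()]), computing per-site
#' fold changes over the motif background and the Input2 ratio, and (when
#' calibration curves are given) the D stoichiometry by inverting the
#' per-motif linear calibration.
#'
#' @param treated,input1,input2 count-table data.frames (replicates are
#'   merged by count summation).
#' @param reference reference sequences (see [as_reference()]).
#' @param background background table from [build_background()].
#' @param curves optional calibration table from [fit_calibration()];
#'   without it `d_fraction` is `NA`.
#' @param config a [ncrna_config()].
#' @return a data.frame of site calls: site key and motif, per-condition
#'   ratios and depths, fold changes, `d_fraction` (with `clamped` and
#'   `curve_fallback` flags), a semicolon-joined per-criterion `pass`
#'   string, the individual criterion flags `crit_*`, `missing_data`
#'   (site absent or uncovered in an input), and the final `called`.
#'   Sites with missing input data are reported but never called.
#' @export
call_sites_ncrna <- function(treated, input1, input2, reference,
                             background, curves = NULL,
                             config = ncrna_config()) {
  cfg <- config
  tr <- .t_site_table(treated, cfg)
  if (nrow(tr) == 0L) {
    return(.empty_ncrna_calls())
  }
  i1 <- .t_site_table(input1, cfg)
  i2 <- .t_site_table(input2, cfg)

  out <- tr[, c("ref_id", "pos", "strand")]
  out$motif <- .motifs_for_sites(reference, tr$ref_id, tr$pos)
  out$depth_treated <- tr$depth
  out$ratio_treated <- tr$ratio
  out$mis_count_treated <- tr$mis_count

  j1 <- match(tr$key, i1$key)
  j2 <- match(tr$key, i2$key)
  out$depth_input1 <- i1$depth[j1]
  out$ratio_input1 <- i1$ratio[j1]
  out$depth_input2 <- i2$depth[j2]
  out$ratio_input2 <- i2$ratio[j2]

  bg <- .bg_lookup(background, out$motif)
  out$bg_ratio <- bg$rate
  out$bg_fallback <- bg$fallback
  out$fold_background <- out$ratio_treated / pmax(out$bg_ratio, cfg$eps)
  out$fold_input2 <- out$ratio_treated / pmax(out$ratio_input2, cfg$eps)

  out$missing_data <- is.na(j1) | is.na(j2) |
    is.na(out$ratio_treated) | is.na(out$ratio_input1) | is.na(out$ratio_input2)

  c1 <- out$ratio_treated > cfg$min_ratio_treated &
    out$mis_count_treated > cfg$min_mis_count
  c2 <- out$ratio_input1 < cfg$max_ratio_input &
    out$ratio_input2 < cfg$max_ratio_input
  c3 <- out$depth_treated > cfg$min_depth &
    out$depth_input1 > cfg$min_depth & out$depth_input2 > cfg$min_depth
  c4 <- out$ratio_treated > cfg$fold_over_background * out$bg_ratio
  c5 <- out$ratio_treated >
    cfg$fold_over_input2 * pmax(out$ratio_input2, cfg$eps)
  c6 <- if (cfg$exclude_multi_u) {
    !is_multi_u(out$motif, cfg$multi_u_mode)
  } else {
    rep(TRUE, nrow(out))
  }
  c7 <- rep(TRUE, nrow(out))  # reference-T-only universe, held structurally

  flags <- cbind(ratio_treated = c1, input_ratio = c2, depth = c3,
                 fold_background = c4, fold_input2 = c5,
                 not_multi_u = c6, u_site = c7)
  out[paste0("crit_", colnames(flags))] <- as.data.frame(flags)
  out$pass <- .criteria_string(flags, colnames(flags))
  ok <- rowSums(flags, na.rm = FALSE) == ncol(flags)
  out$called <- !is.na(ok) & ok & !out$missing_data

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

.empty_ncrna_calls <- function() {
  data.frame(ref_id = character(0), pos = integer(0), strand = character(0),
             motif = character(0), depth_treated = numeric(0),
             ratio_treated = numeric(0), mis_count_treated = numeric(0),
             depth_input1 = numeric(0), ratio_input1 = numeric(0),
             depth_input2 = numeric(0), ratio_input2 = numeric(0),
             bg_ratio = numeric(0), bg_fallback = logical(0),
             fold_background = numeric(0), fold_input2 = numeric(0),
             missing_data = logical(0), pass = character(0),
             called = logical(0), d_fraction = numeric(0),
             clamped = logical(0), curve_fallback = logical(0),
             stringsAsFactors = FALSE)
}

#' Summarize called-site stoichiometry by canonical position label
#'
#' Groups calls by a user-supplied annotation mapping (ref_id, pos) to a
#' canonical tRNA position label ("16", "17", "20", "20a", "47", ...);
#' inferring such labels from structure is out of scope, so the mapping is
#' always explicit input.
#'
#' @param calls call table from [call_sites_ncrna()].
#' @param annotation data.frame with columns `ref_id`, `pos`, `label`.
#' @return data.frame per label: `label`, `n`, `mean_fraction`,
#'   `median_fraction`, plus a list-column `fractions` with the raw
#'   values. Calls without an annotation entry fall in the
#'   `"unannotated"` bucket.
#' @export
summarize_by_position <- function(calls, annotation) {
  stopifnot(all(c("ref_id", "pos", "label") %in% names(annotation)))
  if (nrow(calls) == 0L) {
    return(data.frame(label = character(0), n = integer(0),
                      mean_fraction = numeric(0), median_fraction = numeric(0)))
  }
  key <- paste(calls$ref_id, calls$pos, sep = "\r")
  akey <- paste(annotation$ref_id, annotation$pos, sep = "\r")
  label <- annotation$label[match(key, akey)]
  label[is.na(label)] <- "unannotated"
  sp <- split(calls$d_fraction, label)
  out <- data.frame(label = names(sp),
                    n = vapply(sp, length, integer(1)),
                    mean_fraction = vapply(sp, mean, numeric(1)),
                    median_fraction = vapply(sp, median, numeric(1)),
                    stringsAsFactors = FALSE)
  out$fractions <- unname(sp)
  rownames(out) <- NULL
  out
}
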