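#' Paired comparison of D stoichiometry between two conditions
#'
#' Pairs called sites on (ref_id, pos) and tests whether stoichiometry
#' shifted between conditions (e.g. siControl vs. a DUS knockdown) with a
#' two-sided paired t-test on the per-site differences.
#'
#' @param calls_a,calls_b call tables (need `ref_id`, `pos`, `d_fraction`).
#' @param restrict_to optional data.frame of `ref_id`, `pos` restricting
#'   the comparison to an explicit site list (e.g. one canonical tRNA
#'   position class).
#' @return list with `comparisons` (data.frame `ref_id, pos, fraction_a,
#'   fraction_b, delta` where `delta = fraction_b - fraction_a`),
#'   `p_value`, `n`, and `degenerate` (`TRUE` when the deltas have zero
#'   variance; then p is 1 for zero mean shift and 0 otherwise, by
#'   convention).
#' @export
paired_compare <- function(calls_a, calls_b, restrict_to = NULL) {
  ka <- paste(calls_a$ref_id, calls_a$pos, sep = "\r")
  kb <- paste(calls_b$ref_id, calls_b$pos, sep = "\r")
  shared <- intersect(ka, kb)
  if (!is.null(restrict_to)) {
    shared <- intersect(shared,
                        paste(restrict_to$ref_id, restrict_to$pos, sep = "\r"))
  }
  if (length(shared) < 2L) {
    stop("paired comparison needs at least two shared sites")
  }
  ia <- match(shared, ka); ib <- match(shared, kb)
  cmp <- data.frame(ref_id = calls_a$ref_id[ia], pos = calls_a$pos[ia],
                    fraction_a = calls_a$d_fraction[ia],
                    fraction_b = calls_b$d_fraction[ib],
                    stringsAsFactors = FALSE)
  cmp$delta <- cmp$fraction_b - cmp$fraction_a
  d <- cmp$delta
  n <- length(d)
  s <- sd(d)
  # treat numerically-zero spread (identical deltas up to floating-point
  # cancellation) as the degenerate case
  if (s < 1e-12) {
    p <- if (abs(mean(d)) < 1e-12) 1 else 0
    degenerate <- TRUE
  } else {
    t <- mean(d) * sqrt(n) / s
    p <- 2 * pt(-abs(t), df = n - 1)
    degenerate <- FALSE
  }
  list(comparisons = cmp, p_value = p, n = n, degenerate = degenerate)
}

#' Assign a writer enzyme to each D site from knockdown drops
#'
#' Each candidate writer (DUS enzyme) is knocked down in turn; the site is
#' assigned to the candidate whose depletion produces the largest drop in
#' D stoichiometry, provided that drop exceeds `drop_threshold`.
#' Sub-threshold drops and exact ties stay `"unassigned"` — knockdowns
#' show compensatory increases at other enzymes' sites, so forcing a
#' choice would over-assign.
#'
#' @param comparisons named list: writer candidate -> `comparisons`
#'   data.frame from [paired_compare()] (control as condition a, that
#'   writer's knockdown as condition b), all over the same site universe.
#' @param drop_threshold minimum absolute stoichiometry drop
#'   (control - knockdown) to assign (default 0.10).
#' @return data.frame `ref_id, pos, writer, drop, tie`; `writer` is
#'   `"unassigned"` below threshold or on a tie (then `tie = TRUE`).
#' @export
assign_writer <- function(comparisons, drop_threshold = 0.10) {
  if (length(comparisons) == 0L || is.null(names(comparisons)) ||
      any(names(comparisons) == "")) {
    stop("comparisons must be a non-empty named list (writer -> comparison)")
  }
  writers <- names(comparisons)
  base <- comparisons[[1L]]
  key <- paste(base$ref_id, base$pos, sep = "\r")
  drops <- matrix(NA_real_, nrow = length(key), ncol = length(writers),
                  dimnames = list(NULL, writers))
  for (w in writers) {
    cw <- comparisons[[w]]
    kw <- paste(cw$ref_id, cw$pos, sep = "\r")
    idx <- match(key, kw)
    if (any(is.na(idx))) {
      stop("comparison for writer '", w, "' does not cover the full site set")
    }
    drops[, w] <- -cw$delta[idx]  # drop = fraction_a - fraction_b
  }
  max_drop <- apply(drops, 1L, max)
  n_at_max <- rowSums(drops == max_drop)
  best <- writers[max.col(drops, ties.method = "first")]
  tie <- n_at_max > 1L & max_drop > drop_threshold
  assigned <- ifelse(max_drop > drop_threshold & !tie, best, "unassigned")
  data.frame(ref_id = base$ref_id, pos = base$pos, writer = assigned,
             drop = max_drop, tie = tie, stringsAsFactors = FALSE)
}
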