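#' Per-motif background misincorporation from 0%-D probes
#'
#' Unmodified uridine is not read perfectly: 0%-D probes show motif-
#' dependent T-to-C rates of roughly 4-15%. The callers compare every
#' candidate site against this background, per motif.
#'
#' @param records count-table data.frame from 0%-D probe libraries.
#' @param reference reference sequences for the probes (see
#'   [as_reference()]), used to resolve each T site's 5-mer motif.
#' @return data.frame `motif, bg_ratio, depth` — a depth-weighted mean tc
#'   ratio per motif (`depth` here is the tc denominator `n_C + n_T`
#'   summed over contributing records).
#' @details Splitting a record into two with the same ratio and summed
#'   depth leaves the table unchanged (weighted-mean invariance).
#' @export
build_background <- function(records, reference) {
  records <- validate_count_table(records)
  t_rec <- records[records$ref_base == "T", , drop = FALSE]
  if (nrow(t_rec) == 0L) stop("no reference-T sites in background records")
  motif <- .motifs_for_sites(reference, t_rec$ref_id, t_rec$pos)
  den <- t_rec$n_C + t_rec$n_T
  keep <- den > 0
  if (!any(keep)) stop("no covered reference-T sites in background records")
  g <- factor(motif[keep])
  num <- rowsum(as.numeric(t_rec$n_C[keep]), g)
  dtot <- rowsum(as.numeric(den[keep]), g)
  out <- data.frame(motif = levels(g),
                    bg_ratio = as.numeric(num / dtot),
                    depth = as.numeric(dtot), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Global mean background rate
#'
#' Unweighted mean of the per-motif rates (each motif counts once,
#' regardless of probe depth).
#'
#' @param background background table from [build_background()].
#' @return a single rate.
#' @export
global_background <- function(background) {
  mean(background$bg_ratio)
}

#' Normal-approximation confidence interval for the mean background rate
#'
#' @param background background table (needs at least two motifs).
#' @param level confidence level (default 0.95).
#' @return named numeric `c(lo, hi)`: `mean +/- z * sd / sqrt(n)` across
#'   motif-level rates.
#' @export
background_ci <- function(background, level = 0.95) {
  rates <- background$bg_ratio
  n <- length(rates)
  if (n < 2L) stop("background CI undefined with fewer than two motifs")
  m <- mean(rates)
  z <- qnorm((1 + level) / 2)
  half <- z * sd(rates) / sqrt(n)
  c(lo = m - half, hi = m + half)
}

# look up per-motif background with global-mean fallback;
# returns list(rate = numeric, fallback = logical)
.bg_lookup <- function(background, motif) {
  idx <- match(motif, background$motif)
  rate <- background$bg_ratio[idx]
  fallback <- is.na(idx)
  rate[fallback] <- global_background(background)
  list(rate = rate, fallback = fallback)
}

#' Write / read a background table
#'
#' Tab-separated `motif, bg_ratio, depth`; the two functions round-trip.
#'
#' @param background background data.frame.
#' @param path file path.
#' @export
write_background <- function(background, path) {
  stopifnot(all(c("motif", "bg_ratio") %in% names(background)))
  if (is.null(background$depth)) background$depth <- NA_real_
  write.table(background[, c("motif", "bg_ratio", "depth")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_background
#' @export
read_background <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  missing <- setdiff(c("motif", "bg_ratio"), names(df))
  if (length(missing) > 0L) {
    stop("background table missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}
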