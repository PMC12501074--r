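.calls_tsv_cols <- c("ref_id", "pos", "strand", "motif",
                     "depth_treated", "ratio_treated",
                     "ratio_input1", "ratio_input2", "ratio_ivt",
                     "fold_background", "fold_input2", "fold_ivt",
                     "p_ttest", "p_binom", "d_fraction", "pass", "called")

#' Write site calls to TSV or BED
#'
#' TSV keeps the full per-criterion detail (columns `ref_id, pos, strand,
#' motif, depth_treated, ratio_treated, ratio_input1, ratio_input2,
#' ratio_ivt, fold_background, fold_input2, fold_ivt, p_ttest, p_binom,
#' d_fraction, pass, called`) and round-trips through [read_calls()].
#' BED6 converts the 1-based site to a 0-based half-open single-base
#' interval, with `score = round(1000 * d_fraction)` and the strand
#' column.
#'
#' @param calls call table from [call_sites_ncrna()] or
#'   [call_sites_mrna()].
#' @param path output path.
#' @param format `"tsv"` or `"bed"`.
#' @param header optional character vector of `#`-prefixed header lines
#'   (e.g. the effective configuration echo) written before the table.
#' @export
write_calls <- function(calls, path, format = c("tsv", "bed"),
                        header = NULL) {
  format <- match.arg(format)
  for (col in .calls_tsv_cols) {
    if (is.null(calls[[col]])) calls[[col]] <- rep(NA, nrow(calls))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(paste0("#", sub("^#", "", header)), con)
  }
  if (format == "tsv") {
    write.table(calls[, .calls_tsv_cols], con, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    score <- ifelse(is.na(calls$d_fraction), 0L,
                    as.integer(round(1000 * calls$d_fraction)))
    bed <- data.frame(chrom = calls$ref_id,
                      start = calls$pos - 1L,
                      end = calls$pos,
                      name = paste0(calls$ref_id, ":", calls$pos, ":",
                                    calls$motif),
                      score = score,
                      strand = calls$strand,
                      stringsAsFactors = FALSE)
    write.table(bed, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a TSV call table written by [write_calls()]
#'
#' @param path path to the calls TSV (leading `#` header lines skipped).
#' @return data.frame with the call columns; `called` parsed as logical.
#' @export
read_calls <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  missing <- setdiff(c("ref_id", "pos", "d_fraction"), names(df))
  if (length(missing) > 0L) {
    stop("call table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!is.null(df$called)) df$called <- as.logical(df$called)
  df
}
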