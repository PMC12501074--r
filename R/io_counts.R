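#' @name count-tables
#' @title Per-site base-count tables
#'
#' @description
#' The unit of all D calling is a per-site, per-sample record of base-call
#' counts at a reference position. On disk these live in a tab-separated
#' table with the exact column order
#' `ref_id, pos, strand, ref_base, n_A, n_C, n_G, n_T, n_del, sample_id,
#' condition, replicate` (the layout emitted by 3-letter aligners'
#' conversion tables, plus sample bookkeeping). Positions are 1-based and
#' transcript-sense; `condition` is one of `treated`, `input1`, `input2`,
#' `ivt`.
NULL

.count_cols <- c("ref_id", "pos", "strand", "ref_base",
                 "n_A", "n_C", "n_G", "n_T", "n_del",
                 "sample_id", "condition", "replicate")

.count_int_cols <- c("pos", "n_A", "n_C", "n_G", "n_T", "n_del", "replicate")

#' Read a per-site base-count table
#'
#' @param path path to a tab-separated count table with the documented
#'   column schema (comment lines starting with `#` are skipped).
#' @return a `data.frame` with one row per (site, sample) record, integer
#'   counts, and a `depth` column (`n_A + n_C + n_G + n_T`; deletions are
#'   tallied separately and never enter depth).
#' @details Validation is strict: a missing required column is a schema
#'   error naming the column; malformed or negative counts, positions
#'   below 1, reference bases outside A/C/G/T and unknown condition
#'   labels are reported with the offending file line numbers.
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(.count_cols, names(df))
  if (length(missing) > 0L) {
    stop("count table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- df[, .count_cols, drop = FALSE]
  if (nrow(df) == 0L) {
    for (col in .count_int_cols) df[[col]] <- integer(0)
    return(validate_count_table(df))
  }
  # header is line 1; data row i sits on file line i + 1
  line_of <- function(i) i + 1L
  for (col in .count_int_cols) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0L) {
      stop("non-integer value in column '", col, "' at line(s) ",
           paste(line_of(bad), collapse = ", "), " of ", path)
    }
    df[[col]] <- v
  }
  neg <- which(df$n_A < 0 | df$n_C < 0 | df$n_G < 0 | df$n_T < 0 | df$n_del < 0)
  if (length(neg) > 0L) {
    stop("negative count at line(s) ", paste(line_of(neg), collapse = ", "),
         " of ", path)
  }
  validate_count_table(df, context = path)
}

#' Validate (and finalize) an in-memory count table
#'
#' @param records data.frame with the count-table columns.
#' @param context label used in error messages.
#' @return the validated data.frame with a recomputed `depth` column.
#' @export
validate_count_table <- function(records, context = "count table") {
  stopifnot(is.data.frame(records))
  missing <- setdiff(.count_cols, names(records))
  if (length(missing) > 0L) {
    stop(context, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(records) > 0L) {
    if (any(records$pos < 1L)) stop(context, ": positions must be >= 1")
    if (!all(records$ref_base %in% .bases))
      stop(context, ": ref_base must be one of A/C/G/T")
    if (!all(records$strand %in% c("+", "-")))
      stop(context, ": strand must be '+' or '-'")
    if (!all(records$condition %in% .conditions))
      stop(context, ": condition must be one of ",
           paste(.conditions, collapse = ", "))
    if (any(records$replicate < 1L)) stop(context, ": replicate must be >= 1")
    counts <- as.matrix(records[, c("n_A", "n_C", "n_G", "n_T", "n_del")])
    if (any(counts < 0)) stop(context, ": counts must be non-negative")
  }
  records$depth <- records$n_A + records$n_C + records$n_G + records$n_T
  records
}

#' Write a per-site base-count table
#'
#' Inverse of [read_count_table()]: writing then reading is the identity on
#' all schema fields.
#'
#' @param records validated count-table data.frame.
#' @param path output path.
#' @export
write_count_table <- function(records, path) {
  records <- validate_count_table(records)
  write.table(records[, .count_cols], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mutation (misincorporation) ratio at reference-T sites
#'
#' The D signal is a T-to-C misincorporation, so the ratio is only defined
#' at reference uridines. Two denominators are offered: `tc` (default) is
#' the conversion-ratio semantics `n_C / (n_C + n_T)` of 3-letter aligners;
#' `any_mismatch` is `(depth - n_T) / depth`. Deletions never enter either.
#'
#' @param records count-table data.frame (all rows must have `ref_base == "T"`).
#' @param mode `"tc"` or `"any_mismatch"`.
#' @return numeric vector of ratios in `[0, 1]`; `NA` where the denominator
#'   is zero (undefined, deliberately not reported as 0).
#' @export
mutation_ratio <- function(records, mode = c("tc", "any_mismatch")) {
  mode <- match.arg(mode)
  if (any(records$ref_base != "T")) {
    stop("mutation_ratio is defined only at reference 'T' (U) sites")
  }
  if (mode == "tc") {
    den <- records$n_C + records$n_T
    num <- records$n_C
  } else {
    den <- records$n_A + records$n_C + records$n_G + records$n_T
    num <- den - records$n_T
  }
  ifelse(den > 0, num / den, NA_real_)
}

#' Extract the 5-mer motif context around a position
#'
#' @param reference a single reference sequence (character string,
#'   transcript sense).
#' @param pos 1-based position(s) within the sequence.
#' @return character vector of 5-mers centered at `pos`; positions falling
#'   off either end are padded with `N`.
#' @examples
#' motif_at("AACGTAA", 4)  # "ACGTA"
#' motif_at("TACGG", 1)    # "NNTAC"
#' @export
motif_at <- function(reference, pos) {
  reference <- as.character(reference)
  stopifnot(length(reference) == 1L)
  n <- nchar(reference)
  if (any(pos < 1L | pos > n)) stop("pos outside the reference sequence")
  padded <- paste0("NN", reference, "NN")
  substring(padded, pos, pos + 4L)
}

# vectorized motif lookup across a named reference set
.motifs_for_sites <- function(reference, ref_id, pos) {
  reference <- as_reference(reference)
  unknown <- setdiff(unique(ref_id), names(reference))
  if (length(unknown) > 0L) {
    stop("site(s) reference sequence(s) absent from FASTA: ",
         paste(unknown, collapse = ", "))
  }
  padded <- paste0("NN", reference, "NN")
  substring(padded[match(ref_id, names(reference))], pos, pos + 4L)
}

#' Coerce a reference to a named character vector of sequences
#'
#' Accepts a FASTA path (read with Biostrings), a `DNAStringSet`, or an
#' already-named character vector. FASTA names are truncated at the first
#' whitespace, matching aligner conventions; `U` is rewritten to `T`.
#'
#' @param reference FASTA path, `DNAStringSet`, or named character vector.
#' @return named uppercase character vector of DNA-alphabet sequences.
#' @export
as_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      is.null(names(reference)) && file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (methods::is(reference, "XStringSet")) {
    seqs <- as.character(reference)
  } else if (is.character(reference)) {
    seqs <- reference
  } else {
    stop("reference must be a FASTA path, DNAStringSet or named character vector")
  }
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("reference sequences must be named")
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- toupper(seqs)
  chartr("U", "T", seqs)
}

#' Write reference sequences as FASTA
#'
#' @param reference named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(reference, path) {
  stopifnot(!is.null(names(reference)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(reference)) {
    writeLines(c(paste0(">", names(reference)[i]), reference[[i]]), con)
  }
  invisible(path)
}

#' Read a BED file of regions (e.g. tRNA intervals) as a GRanges
#'
#' @param path BED path (0-based half-open intervals, per the BED spec).
#' @return a `GRanges` with 1-based coordinates, suitable for
#'   [call_sites_mrna()]'s tRNA exclusion.
#' @export
read_regions_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Build a region set from a data.frame of intervals
#'
#' @param intervals data.frame with columns `ref_id`, `start`, `end`
#'   (0-based half-open, BED convention) and optionally `name`.
#' @return a `GRanges` (1-based, closed) over the same intervals.
#' @export
region_set <- function(intervals) {
  stopifnot(all(c("ref_id", "start", "end") %in% names(intervals)))
  if (any(intervals$start >= intervals$end)) {
    stop("region intervals must satisfy start < end (0-based half-open)")
  }
  GenomicRanges::GRanges(
    seqnames = intervals$ref_id,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end)
  )
}
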