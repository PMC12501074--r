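#' Per-position base counts from a text SAM alignment
#'
#' Alternative entry point to [read_count_table()]: counts read bases per
#' reference position directly from a (text) SAM file aligned to a small
#' reference, so fixtures and probe libraries need no external conversion
#' table. Only primary, mapped records are used. The CIGAR is walked with
#' the standard consumption rules: `M`/`=`/`X` consume reference and read,
#' `I` read only, `D` reference only (tallied as `n_del`), `N` reference
#' only, `S` read only, `H`/`P` neither.
#'
#' Counts are reported in transcript sense: for reverse-strand alignments
#' (FLAG 0x10) the read bases and the reference base are complemented, so
#' `ref_base` and `n_A..n_T` always describe the RNA strand. Forward and
#' reverse coverage of the same position yield separate `+` / `-` rows.
#'
#' @param sam path to a SAM file, or a character vector of SAM lines.
#' @param reference reference sequences (see [as_reference()]); every
#'   sequence a read maps to must be present.
#' @param sample_id,condition,replicate sample bookkeeping attached to the
#'   emitted records.
#' @param min_mapq minimum MAPQ to keep; defaults to 0 because
#'   multi-mapping is rampant in tRNA and discarding MAPQ-0 reads would
#'   silently drop most of the signal.
#' @return a validated count-table data.frame (one row per covered
#'   reference position and strand).
#' @export
pileup_from_sam <- function(sam, reference, sample_id, condition,
                            replicate = 1L, min_mapq = 0L) {
  if (length(sam) == 1L && !grepl("\t", sam) && file.exists(sam)) {
    lines <- readLines(sam)
  } else {
    lines <- sam
  }
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  reference <- as_reference(reference)

  acc_ref <- character(0); acc_pos <- integer(0)
  acc_base <- character(0); acc_strand <- character(0)
  del_ref <- character(0); del_pos <- integer(0); del_strand <- character(0)

  for (line in lines) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L) next                  # unmapped
    if (bitwAnd(flag, 256L) > 0L || bitwAnd(flag, 2048L) > 0L) next
    if (as.integer(f[5]) < min_mapq) next
    rname <- f[3]
    if (!rname %in% names(reference)) {
      stop("SAM record maps to '", rname, "', absent from the reference")
    }
    strand <- if (bitwAnd(flag, 16L) > 0L) "-" else "+"
    cigar <- f[6]
    seq <- toupper(f[10])
    ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
    if (length(ops) == 0L) stop("unparsable CIGAR '", cigar, "'")
    ref_pos <- as.integer(f[4])
    read_pos <- 1L
    for (op in ops) {
      len <- as.integer(sub("[A-Z=]$", "", op))
      code <- sub("^\\d+", "", op)
      if (code %in% c("M", "=", "X")) {
        idx <- seq_len(len)
        acc_ref <- c(acc_ref, rep(rname, len))
        acc_pos <- c(acc_pos, ref_pos + idx - 1L)
        acc_base <- c(acc_base,
                      substring(seq, read_pos + idx - 1L, read_pos + idx - 1L))
        acc_strand <- c(acc_strand, rep(strand, len))
        ref_pos <- ref_pos + len
        read_pos <- read_pos + len
      } else if (code == "I") {
        read_pos <- read_pos + len
      } else if (code == "D") {
        del_ref <- c(del_ref, rep(rname, len))
        del_pos <- c(del_pos, ref_pos + seq_len(len) - 1L)
        del_strand <- c(del_strand, rep(strand, len))
        ref_pos <- ref_pos + len
      } else if (code == "N") {
        ref_pos <- ref_pos + len
      } else if (code == "S") {
        read_pos <- read_pos + len
      }
      # H and P consume nothing
    }
  }

  if (length(acc_pos) == 0L && length(del_pos) == 0L) {
    empty <- data.frame(ref_id = character(0), pos = integer(0),
                        strand = character(0), ref_base = character(0),
                        n_A = integer(0), n_C = integer(0), n_G = integer(0),
                        n_T = integer(0), n_del = integer(0),
                        sample_id = character(0), condition = character(0),
                        replicate = integer(0), stringsAsFactors = FALSE)
    return(validate_count_table(empty))
  }

  # transcript-sense: complement calls on reverse-strand alignments
  rev <- acc_strand == "-"
  acc_base[rev] <- chartr("ACGT", "TGCA", acc_base[rev])

  key <- paste(acc_ref, acc_pos, acc_strand, sep = "\r")
  ukey <- sort(unique(c(key, if (length(del_pos)) {
    paste(del_ref, del_pos, del_strand, sep = "\r")
  })))
  parts <- do.call(rbind, strsplit(ukey, "\r", fixed = TRUE))
  out <- data.frame(ref_id = parts[, 1], pos = as.integer(parts[, 2]),
                    strand = parts[, 3], stringsAsFactors = FALSE)

  tab_for <- function(base) {
    cnt <- table(key[acc_base == base])
    v <- integer(length(ukey))
    v[match(names(cnt), ukey)] <- as.integer(cnt)
    v
  }
  out$n_A <- tab_for("A"); out$n_C <- tab_for("C")
  out$n_G <- tab_for("G"); out$n_T <- tab_for("T")
  dtab <- table(paste(del_ref, del_pos, del_strand, sep = "\r"))
  out$n_del <- integer(nrow(out))
  out$n_del[match(names(dtab), ukey)] <- as.integer(dtab)

  ref_chr <- substring(reference[out$ref_id], out$pos, out$pos)
  ref_chr[out$strand == "-"] <- chartr("ACGT", "TGCA", ref_chr[out$strand == "-"])
  out$ref_base <- ref_chr

  out$sample_id <- sample_id
  out$condition <- condition
  out$replicate <- as.integer(replicate)
  out <- out[order(out$ref_id, out$pos, out$strand), .count_cols]
  rownames(out) <- NULL
  validate_count_table(out, context = "pileup")
}
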