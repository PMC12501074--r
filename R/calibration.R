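#' Enumerate all 5-mer motif contexts centered on uridine
#'
#' D sits in a 5-nt sequence context (NNDNN); with four bases at each of
#' the four flanking positions there are exactly 4^4 = 256 such contexts.
#'
#' @return character vector of the 256 5-mers over A/C/G/T with central
#'   `T`, in lexicographic order.
#' @export
enumerate_motifs <- function() {
  g <- expand.grid(p1 = .bases, p2 = .bases, p4 = .bases, p5 = .bases,
                   stringsAsFactors = FALSE)
  sort(paste0(g$p1, g$p2, "T", g$p4, g$p5))
}

#' Fit per-motif linear calibration curves
#'
#' The response of the T-to-C mutation ratio y to the true D fraction x is
#' linear, `y = A x + b`; A and b are fitted per motif by least squares
#' from a mixture series of known D fractions (the 6-level probe design by
#' default).
#'
#' @param points data.frame with columns `motif`, `d_fraction_true` (x),
#'   `ratio_observed` (y) and optionally `depth`.
#' @param weighted if `TRUE`, weight points by `depth` (plain unweighted
#'   least squares is the default; probe series are sequenced to roughly
#'   uniform depth).
#' @return data.frame with one row per motif: `motif`, `slope_A`,
#'   `intercept_b`, `r2`, `n_points`. `r2` is `NA` when the response is
#'   constant (zero total sum of squares).
#' @details Fewer than two distinct x levels for a motif is a degenerate
#'   design and an error. A perfectly flat response (identical y at
#'   varying x) yields `slope_A = 0` with a warning — valid but
#'   non-invertible.
#' @export
fit_calibration <- function(points, weighted = FALSE) {
  stopifnot(all(c("motif", "d_fraction_true", "ratio_observed") %in%
                  names(points)))
  if (nrow(points) == 0L) stop("no calibration points supplied")
  x <- points$d_fraction_true
  y <- points$ratio_observed
  if (any(x < 0 | x > 1) || any(y < 0 | y > 1)) {
    stop("calibration fractions and ratios must lie in [0, 1]")
  }
  w <- if (weighted) {
    if (is.null(points$depth)) stop("weighted fit requires a 'depth' column")
    as.numeric(points$depth)
  } else {
    rep(1, nrow(points))
  }
  motif <- points$motif
  degen <- tapply(x, motif, function(v) length(unique(v)) < 2L)
  if (any(degen)) {
    stop("degenerate calibration design (fewer than two distinct D levels) ",
         "for motif(s): ", paste(names(degen)[degen], collapse = ", "))
  }
  # closed-form (weighted) least squares, grouped by motif
  g <- factor(motif)
  Sw <- rowsum(w, g); Sx <- rowsum(w * x, g); Sy <- rowsum(w * y, g)
  Sxx <- rowsum(w * x * x, g); Sxy <- rowsum(w * x * y, g)
  Syy <- rowsum(w * y * y, g)
  A <- (Sw * Sxy - Sx * Sy) / (Sw * Sxx - Sx * Sx)
  b <- (Sy - A * Sx) / Sw
  sst <- Syy - Sy * Sy / Sw
  ssr <- Syy - 2 * A * Sxy - 2 * b * Sy + A * A * Sxx + 2 * A * b * Sx +
    b * b * Sw
  r2 <- ifelse(sst > 0, pmax(0, pmin(1, 1 - ssr / sst)), NA_real_)
  n_points <- as.integer(table(g))
  out <- data.frame(motif = levels(g), slope_A = as.numeric(A),
                    intercept_b = as.numeric(b), r2 = as.numeric(r2),
                    n_points = n_points, stringsAsFactors = FALSE)
  if (any(out$slope_A == 0)) {
    warning("flat calibration (slope 0) for motif(s): ",
            paste(out$motif[out$slope_A == 0], collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Invert a calibration curve: mutation ratio to D fraction
#'
#' @param ratio_observed observed T-to-C mutation ratio(s) y.
#' @param curve a single calibration curve: a list or one-row data.frame
#'   with `slope_A` and `intercept_b`.
#' @return numeric vector `x = (y - b) / A`, clamped to `[0, 1]`; the
#'   logical attribute `"clamped"` records which values were truncated
#'   (stoichiometry is a fraction; over-/under-shoot is measurement noise,
#'   flagged rather than silently absorbed or raised).
#' @export
estimate_fraction <- function(ratio_observed, curve) {
  A <- as.numeric(curve$slope_A)
  b <- as.numeric(curve$intercept_b)
  if (length(A) != 1L || length(b) != 1L) {
    stop("estimate_fraction takes a single curve; see estimate_fraction_by_motif")
  }
  if (is.na(A) || A <= 0) {
    stop("non-invertible calibration curve (slope_A must be > 0)")
  }
  raw <- (ratio_observed - b) / A
  clamped <- !is.na(raw) & (raw < 0 | raw > 1)
  out <- pmin(pmax(raw, 0), 1)
  attr(out, "clamped") <- clamped
  out
}

#' Invert per-motif calibration curves with global fallback
#'
#' @param ratio_observed vector of observed ratios.
#' @param motif vector of 5-mer contexts, same length.
#' @param curves calibration table from [fit_calibration()].
#' @return data.frame with `d_fraction`, `clamped`, and `fallback` (`TRUE`
#'   where the motif had no usable curve and the global mean curve —
#'   mean A, mean b over invertible motifs — was used).
#' @export
estimate_fraction_by_motif <- function(ratio_observed, motif, curves) {
  stopifnot(length(ratio_observed) == length(motif))
  ok <- !is.na(curves$slope_A) & curves$slope_A > 0
  if (!any(ok)) stop("no invertible calibration curves available")
  gA <- mean(curves$slope_A[ok]); gb <- mean(curves$intercept_b[ok])
  idx <- match(motif, curves$motif)
  A <- curves$slope_A[idx]; b <- curves$intercept_b[idx]
  fallback <- is.na(idx) | is.na(A) | A <= 0
  A[fallback] <- gA; b[fallback] <- gb
  raw <- (ratio_observed - b) / A
  clamped <- !is.na(raw) & (raw < 0 | raw > 1)
  data.frame(d_fraction = pmin(pmax(raw, 0), 1),
             clamped = clamped, fallback = fallback)
}

#' Write / read a calibration table
#'
#' Tab-separated with columns `motif, slope_A, intercept_b, r2, n_points`;
#' the two functions round-trip.
#'
#' @param curves calibration data.frame.
#' @param path file path.
#' @export
write_calibration <- function(curves, path) {
  stopifnot(all(c("motif", "slope_A", "intercept_b", "r2", "n_points") %in%
                  names(curves)))
  write.table(curves[, c("motif", "slope_A", "intercept_b", "r2", "n_points")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  missing <- setdiff(c("motif", "slope_A", "intercept_b"), names(df))
  if (length(missing) > 0L) {
    stop("calibration table missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}
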