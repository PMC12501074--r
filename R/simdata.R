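#' Configuration for the synthetic count simulator
#'
#' The simulator emulates the statistical structure the caller assumes:
#' at every reference-T site the T-to-C mutation ratio responds linearly
#' to the true D fraction f through per-motif parameters,
#' `y = A_true * f + b_true` (clipped to `[0, 1]`), and read counts are
#' binomial draws at the configured depth. Treated libraries see the
#' planted fractions; input and IVT libraries are modification-free
#' (f = 0) with background `b_true * input_background_scale`.
#'
#' @param seed integer seed; a fixed seed reproduces the output exactly.
#' @param n_refs,ref_length reference layout (random A/C/G/T sequences).
#' @param depth reads per site (fixed count, or Poisson mean).
#' @param depth_model `"fixed"` or `"poisson"`.
#' @param A_true,b_true default calibration slope/intercept for motifs not
#'   listed in `motif_params`. Defaults 0.9 and 0.05: a near-complete
#'   linear response with a background in the middle of the 4-15%
#'   per-motif range observed on 0%-D probes.
#' @param motif_params optional data.frame `motif, A_true, b_true`
#'   overriding per motif.
#' @param truth optional data.frame `ref_id, pos, d_fraction_true` of
#'   planted sites; positions must be reference T.
#' @param n_sites,d_fractions when `truth` is `NULL`, plant `n_sites`
#'   modified sites at random non-multi-U T positions with these
#'   fractions (recycled; default evenly spaced on `[0.1, 0.9]`).
#' @param replicates named integer vector of replicates per condition,
#'   e.g. `c(treated = 2, input1 = 1, input2 = 1, ivt = 2)`; conditions
#'   at 0 are omitted.
#' @param input_background_scale multiplier on `b_true` for the
#'   modification-free libraries (1 = same chemistry background).
#' @param multi_u_fraction fraction of planted sites deliberately placed
#'   in adjacent-UU contexts (negative controls for the multi-U filter).
#' @param error_rate optional uniform miscall rate channelled into
#'   `n_A`/`n_G` (off by default; background flows through `b_true`).
#' @return a list of class `craci_sim_config`.
#' @export
sim_config <- function(seed = 1L, n_refs = 5L, ref_length = 400L,
                       depth = 100, depth_model = c("fixed", "poisson"),
                       A_true = 0.9, b_true = 0.05, motif_params = NULL,
                       truth = NULL, n_sites = 10L, d_fractions = NULL,
                       replicates = c(treated = 1L, input1 = 1L,
                                      input2 = 1L, ivt = 0L),
                       input_background_scale = 1,
                       multi_u_fraction = 0, error_rate = 0) {
  depth_model <- match.arg(depth_model)
  # YAML configs arrive as lists; flatten scalar-vector fields
  replicates <- unlist(replicates)
  if (is.null(names(replicates)) || any(names(replicates) == "") ||
      !all(names(replicates) %in% .conditions)) {
    stop("replicates must be a named vector over the conditions ",
         paste(.conditions, collapse = "/"))
  }
  if (!is.null(d_fractions)) d_fractions <- as.numeric(unlist(d_fractions))
  stopifnot(A_true > 0, A_true <= 1, b_true >= 0, b_true <= 0.2,
            depth > 0, multi_u_fraction >= 0, multi_u_fraction <= 1,
            error_rate >= 0, error_rate < 1,
            all(names(replicates) %in% .conditions))
  if (!is.null(d_fractions) && any(d_fractions < 0 | d_fractions > 1)) {
    stop("d_fractions must lie in [0, 1]")
  }
  cfg <- list(seed = as.integer(seed), n_refs = as.integer(n_refs),
              ref_length = as.integer(ref_length), depth = depth,
              depth_model = depth_model, A_true = A_true, b_true = b_true,
              motif_params = motif_params, truth = truth,
              n_sites = as.integer(n_sites), d_fractions = d_fractions,
              replicates = replicates,
              input_background_scale = input_background_scale,
              multi_u_fraction = multi_u_fraction, error_rate = error_rate)
  class(cfg) <- "craci_sim_config"
  cfg
}

# per-site (A, b) from motif_params with defaults
.sim_motif_ab <- function(motif, config) {
  A <- rep(config$A_true, length(motif))
  b <- rep(config$b_true, length(motif))
  mp <- config$motif_params
  if (!is.null(mp)) {
    idx <- match(motif, mp$motif)
    hit <- !is.na(idx)
    A[hit] <- mp$A_true[idx[hit]]
    b[hit] <- mp$b_true[idx[hit]]
  }
  list(A = A, b = b)
}

#' Simulate per-site count tables for all configured conditions
#'
#' @param config a [sim_config()].
#' @return list with `reference` (named character vector), `counts`
#'   (named list condition -> count-table data.frame holding all
#'   replicates), `truth` (data.frame `ref_id, pos, strand, motif,
#'   d_fraction_true, multi_u`), and the echoed `config`.
#' @details All randomness flows from `config$seed` through one
#'   generator in a fixed order (reference, site selection, then counts
#'   by condition and replicate), so a fixed configuration reproduces
#'   byte-identical tables.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "craci_sim_config"))
  set.seed(config$seed)
  reference <- vapply(seq_len(config$n_refs), function(i) {
    paste(sample(.bases, config$ref_length, replace = TRUE), collapse = "")
  }, character(1))
  names(reference) <- sprintf("ref_%02d", seq_len(config$n_refs))

  # universe of reference-T sites
  sites <- do.call(rbind, lapply(names(reference), function(r) {
    pos <- which(strsplit(reference[[r]], "")[[1]] == "T")
    if (length(pos) == 0L) return(NULL)
    data.frame(ref_id = r, pos = pos, stringsAsFactors = FALSE)
  }))
  if (is.null(sites) || nrow(sites) == 0L) {
    stop("reference contains no T sites; increase ref_length")
  }
  sites$strand <- "+"
  sites$motif <- .motifs_for_sites(reference, sites$ref_id, sites$pos)
  sites$multi_u <- is_multi_u(sites$motif)

  truth <- config$truth
  if (is.null(truth)) {
    fr <- config$d_fractions
    if (is.null(fr)) fr <- seq(0.1, 0.9, length.out = config$n_sites)
    fr <- rep_len(fr, config$n_sites)
    n_multi <- round(config$multi_u_fraction * config$n_sites)
    pick <- function(pool, n) {
      if (n > length(pool)) stop("not enough eligible T sites to plant")
      pool[sample.int(length(pool), n)]
    }
    idx_clean <- pick(which(!sites$multi_u), config$n_sites - n_multi)
    idx_multi <- if (n_multi > 0) pick(which(sites$multi_u), n_multi) else integer(0)
    idx <- c(idx_clean, idx_multi)
    truth <- data.frame(ref_id = sites$ref_id[idx], pos = sites$pos[idx],
                        d_fraction_true = fr, stringsAsFactors = FALSE)
  } else {
    tkey <- paste(truth$ref_id, truth$pos, sep = "\r")
    skey <- paste(sites$ref_id, sites$pos, sep = "\r")
    if (!all(tkey %in% skey)) {
      stop("planted site(s) fall on non-T reference positions")
    }
  }
  skey <- paste(sites$ref_id, sites$pos, sep = "\r")
  tkey <- paste(truth$ref_id, truth$pos, sep = "\r")
  ti <- match(tkey, skey)
  truth$strand <- rep("+", nrow(truth))
  truth$motif <- sites$motif[ti]
  truth$multi_u <- sites$multi_u[ti]
  if (nrow(truth) == 0L) {
    truth$motif <- character(0)
    truth$multi_u <- logical(0)
  }
  truth <- truth[, c("ref_id", "pos", "strand", "motif",
                     "d_fraction_true", "multi_u")]

  f_site <- numeric(nrow(sites))
  f_site[ti] <- truth$d_fraction_true
  ab <- .sim_motif_ab(sites$motif, config)

  reps <- config$replicates[config$replicates > 0]
  counts <- list()
  for (cond in names(reps)) {
    tabs <- vector("list", reps[[cond]])
    for (r in seq_len(reps[[cond]])) {
      tabs[[r]] <- .sim_one_library(sites, f_site, ab, config, cond, r)
    }
    counts[[cond]] <- do.call(rbind, tabs)
  }
  list(reference = reference, counts = counts, truth = truth,
       config = config)
}

.sim_one_library <- function(sites, f_site, ab, config, condition, replicate) {
  n <- nrow(sites)
  N <- if (config$depth_model == "fixed") {
    rep(as.integer(round(config$depth)), n)
  } else {
    rpois(n, config$depth)
  }
  f <- if (condition == "treated") f_site else numeric(n)
  b <- if (condition == "treated") {
    ab$b
  } else {
    ab$b * config$input_background_scale
  }
  y <- pmin(pmax(ab$A * f + b, 0), 1)
  n_C <- rbinom(n, N, y)
  n_T <- N - n_C
  n_A <- integer(n); n_G <- integer(n)
  if (config$error_rate > 0) {
    e_A <- rbinom(n, n_T, config$error_rate / 2)
    n_T <- n_T - e_A
    e_G <- rbinom(n, n_T, config$error_rate / 2)
    n_T <- n_T - e_G
    n_A <- e_A; n_G <- e_G
  }
  out <- data.frame(ref_id = sites$ref_id, pos = sites$pos,
                    strand = sites$strand, ref_base = "T",
                    n_A = n_A, n_C = n_C, n_G = n_G, n_T = n_T,
                    n_del = 0L,
                    sample_id = paste0(condition, "_rep", replicate),
                    condition = condition,
                    replicate = as.integer(replicate),
                    stringsAsFactors = FALSE)
  validate_count_table(out)
}

#' Simulate a calibration mixture series
#'
#' One observation per (motif, mixture level), binomially sampled around
#' the linear response — the in-silico analogue of sequencing the 6-level
#' D/U probe mixtures (100/80/60/40/20/0% D).
#'
#' @param motifs motif contexts to cover (default all 256).
#' @param levels known mixture D fractions (default
#'   `c(0, 0.2, 0.4, 0.6, 0.8, 1)`).
#' @param depth reads per point.
#' @param seed integer seed.
#' @param A_true,b_true,motif_params response parameters as in
#'   [sim_config()].
#' @param exact if `TRUE`, skip sampling and return the analytic
#'   expectation (points exactly on the line).
#' @return data.frame `motif, d_fraction_true, ratio_observed, depth,
#'   n_C, n_T` suitable for [fit_calibration()].
#' @export
simulate_calibration_series <- function(motifs = enumerate_motifs(),
                                        levels = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                                        depth = 2000, seed = 1L,
                                        A_true = 0.9, b_true = 0.05,
                                        motif_params = NULL,
                                        exact = FALSE) {
  if (length(levels) == 0L) stop("empty mixture level set")
  if (any(levels < 0 | levels > 1)) stop("mixture levels must lie in [0, 1]")
  set.seed(seed)
  grid <- expand.grid(motif = motifs, d_fraction_true = levels,
                      stringsAsFactors = FALSE)
  cfg <- list(A_true = A_true, b_true = b_true, motif_params = motif_params)
  ab <- .sim_motif_ab(grid$motif, cfg)
  y <- pmin(pmax(ab$A * grid$d_fraction_true + ab$b, 0), 1)
  if (exact) {
    grid$ratio_observed <- y
    grid$depth <- depth
    grid$n_C <- y * depth
    grid$n_T <- depth - grid$n_C
  } else {
    n_C <- rbinom(nrow(grid), depth, y)
    grid$ratio_observed <- n_C / depth
    grid$depth <- depth
    grid$n_C <- n_C
    grid$n_T <- depth - n_C
  }
  grid[order(grid$motif, grid$d_fraction_true), ]
}

# fixed T-free probe flanks (15 nt each side of the 5-mer)
.probe_flank_left  <- "AGCAGCGGAAGCGGA"
.probe_flank_right <- "AGGCCGAAGGCCGAA"

#' Deterministic 35-nt probe reference for a motif
#'
#' Reproduces the synthetic probe layout used for calibration: a 35-mer
#' with the 5-mer motif at positions 16-20 (central base at position 18)
#' and fixed, uridine-free flanks, so the motif's central U is the only
#' flank-independent candidate site on the probe.
#'
#' @param motif 5-mer(s) over A/C/G/T.
#' @return named character vector (names = motifs) of 35-nt sequences.
#' @export
make_probe_reference <- function(motif) {
  stopifnot(all(nchar(motif) == 5L))
  out <- paste0(.probe_flank_left, motif, .probe_flank_right)
  names(out) <- motif
  out
}

#' Simulate probe-library counts at the central motif position
#'
#' Generates count records at position 18 of each motif's 35-mer probe
#' (see [make_probe_reference()]) with a shared true D fraction — with
#' `d_fraction = 0` this is the 0%-D probe library that
#' [build_background()] consumes.
#'
#' @param motifs motifs to cover (default all 256).
#' @param d_fraction true D fraction on the probes (default 0).
#' @param depth reads per probe.
#' @param seed integer seed.
#' @param A_true,b_true,motif_params response parameters.
#' @param condition,replicate sample bookkeeping.
#' @return list with `reference` (named probes) and `counts` (count-table
#'   data.frame).
#' @export
simulate_probe_counts <- function(motifs = enumerate_motifs(),
                                  d_fraction = 0, depth = 2000, seed = 1L,
                                  A_true = 0.9, b_true = 0.05,
                                  motif_params = NULL,
                                  condition = "treated", replicate = 1L) {
  set.seed(seed)
  reference <- make_probe_reference(motifs)
  names(reference) <- paste0("probe_", motifs)
  cfg <- list(A_true = A_true, b_true = b_true, motif_params = motif_params)
  ab <- .sim_motif_ab(motifs, cfg)
  y <- pmin(pmax(ab$A * d_fraction + ab$b, 0), 1)
  n_C <- rbinom(length(motifs), depth, y)
  counts <- data.frame(ref_id = names(reference), pos = 18L, strand = "+",
                       ref_base = "T", n_A = 0L, n_C = n_C, n_G = 0L,
                       n_T = depth - n_C, n_del = 0L,
                       sample_id = paste0(condition, "_rep", replicate),
                       condition = condition,
                       replicate = as.integer(replicate),
                       stringsAsFactors = FALSE)
  list(reference = reference, counts = validate_count_table(counts))
}
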