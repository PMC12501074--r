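# builders shared across test files; all fixtures are constructed in code

# one count record; ratio is the tc ratio, depth the tc denominator unless
# extra A/G calls are given
rec <- function(ref_id, pos, n_C, n_T, condition, replicate = 1L,
                n_A = 0L, n_G = 0L, n_del = 0L, strand = "+",
                ref_base = "T", sample_id = NULL) {
  data.frame(ref_id = ref_id, pos = as.integer(pos), strand = strand,
             ref_base = ref_base, n_A = as.integer(n_A),
             n_C = as.integer(n_C), n_G = as.integer(n_G),
             n_T = as.integer(n_T), n_del = as.integer(n_del),
             sample_id = sample_id %||%
               paste0(condition, "_rep", replicate),
             condition = condition, replicate = as.integer(replicate),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# record with a target tc ratio at a given tc depth
rec_ratio <- function(ref_id, pos, ratio, depth, condition,
                      replicate = 1L, ...) {
  n_C <- as.integer(round(ratio * depth))
  rec(ref_id, pos, n_C = n_C, n_T = depth - n_C, condition = condition,
      replicate = replicate, ...)
}

# uniform background table over a motif set
flat_background <- function(rate = 0.05, motifs = enumerate_motifs()) {
  data.frame(motif = motifs, bg_ratio = rate, depth = 1000,
             stringsAsFactors = FALSE)
}

# identical linear curves for every motif
flat_curves <- function(A = 0.9, b = 0.05, motifs = enumerate_motifs()) {
  data.frame(motif = motifs, slope_A = A, intercept_b = b, r2 = 1,
             n_points = 6L, stringsAsFactors = FALSE)
}

# a 9-nt reference carrying `motif` at positions 3-7 (site at pos 5)
motif_ref <- function(motif, name = "ref1") {
  stats::setNames(paste0("CC", motif, "CC"), name)
}
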