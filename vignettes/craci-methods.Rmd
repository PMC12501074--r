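---
title: "Quantitative dihydrouridine calling from misincorporation signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative dihydrouridine calling from misincorporation signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craci)
```

## The measurement model

Dihydrouridine (D) is a reduced uridine, abundant in the tRNA D-loop and
rare in mRNA. After chemical reduction of D (KBH~4~) and reverse
transcription under a permissive condition, reduced D is read as C, so a
D site appears in sequencing data as a **T-to-C misincorporation** at a
reference uridine. Unlike truncation-based chemistries, the signal is
internal to the read, which makes it quantitative: the fraction of reads
calling C reflects the fraction of transcript copies carrying D.

Two facts shape everything downstream:

1. **The response is linear but motif-dependent.** For a uridine in a
   5-nt sequence context (an "NNUNN" motif; 4^4^ = 256 contexts exist),
   the observed mutation ratio $y$ responds to the true D fraction $x$
   as $y = A x + b$, with slope and intercept specific to the motif.
   `fit_calibration()` estimates $(A, b)$ per motif by least squares
   from a mixture series of probes with known D content (six levels:
   0/20/40/60/80/100%, on 35-nt probes carrying the motif at positions
   16–20), and `estimate_fraction()` inverts the curve,
   $x = (y - b)/A$, clamped to $[0, 1]$ with an explicit flag.
2. **Unmodified uridine is not read cleanly.** 0%-D probes show
   motif-dependent background mutation rates of roughly 4–15%
   (`build_background()` tabulates them, depth-weighted per motif).
   Every caller criterion involving "fold over background" refers to
   this per-motif table; a motif absent from the table falls back to the
   global mean rate, flagged.

The mutation ratio itself defaults to the conversion-ratio semantics of
three-letter aligners, $y = n_C / (n_C + n_T)$, since T→C is by far the
dominant signature; an any-mismatch denominator is available
(`mutation_ratio(mode = "any_mismatch")`). A zero denominator yields
`NA`, never 0 — an uncovered site is unknown, not unmodified. Deletions
are tallied but excluded from depth and ratio: the chemistry's signal is
misincorporation, not deletion.

## The callers

`call_sites_ncrna()` implements the seven-criterion caller for tRNA and
other ncRNA, evaluated at every reference-T site covered in the treated
libraries (replicates merged by count summation): treated ratio > 0.20
with misincorporation count > 5; both input ratios < 0.15; depth > 50
in treated and both inputs; treated ratio > 3× the motif background and
> 3× the Input2 ratio; no multiple-U context; U sites only. "Above" and
"below" are read as strict inequalities throughout, and every threshold
is a `ncrna_config()` field.

`call_sites_mrna()` implements the eight-criterion caller for mRNA-scale
data, where an in-vitro-transcribed (IVT), modification-free library is
the null: cellular ratio > 0.20; IVT ratio < 0.20; a two-sided
replicate t-test p < 0.05 together with a 3-fold cellular/IVT ratio;
no tRNA-region overlap (BED intervals via `GenomicRanges`); 2-fold over
motif background and over Input2; cellular depth > 30; no multiple-U
context; and an exact one-sided binomial test of the cellular
misincorporation count against the motif background rate
(Benjamini–Hochberg adjustment optional, off by default). Replicate
ratios enter only the t-test; every other criterion uses count-merged
ratios. With fewer than two replicates per condition the t-test is
impossible; such sites are reported as provisional and never called.

Design choices worth stating explicitly:

* **t-test variant.** The default is the pooled-variance Student test
  (`var_equal = TRUE`), the conventional two-sample test for duplicate
  libraries; Welch is available. With two replicates per condition
  Welch's Satterthwaite correction leaves roughly one degree of freedom
  and essentially no power (empirically ~0.6 at a 23%-vs-5% ratio
  contrast at depth 200, versus ~0.93 for the pooled test), so a Welch
  default would make the replicate criterion decorative.
* **"Multiple U" context.** Consecutive uridines accumulate signal
  during analysis, so sites whose immediate 5′ or 3′ neighbour is U are
  excluded by default (`is_multi_u(mode = "adjacent")`). A stricter
  reading — any additional U anywhere in the 5-mer — is available as
  `mode = "any"`. The adjacent definition is the default because the
  accumulation mechanism acts through directly adjacent conversions.
* **Misincorporation count.** Counted as $n_C$ (consistent with the tc
  ratio); an all-non-T variant is a flag.
* **Fold-change floors.** Denominators (background, Input2, IVT ratios)
  are floored at $\varepsilon = 10^{-4}$ so perfectly clean controls do
  not produce infinite folds; a fold criterion then degenerates to a
  plain ratio threshold, which is the conservative direction.
* **Binomial null.** The binomial criterion tests
  $k = n_C,\; n = n_C + n_T$ against the motif background rate; an
  IVT-ratio null is available by configuration.
* **Fold over IVT.** Where pipeline flowcharts circulate a 2-fold
  (log~2~FC > 1) cutoff, the stricter 3-fold is the default, with the
  2-fold variant one configuration flag away.

## Dynamics and writer assignment

`paired_compare()` pairs sites on (ref_id, pos) and applies a two-sided
paired t-test to the per-site stoichiometry differences — the statistic
used to summarise knockdown responses per canonical tRNA position
class. Zero-variance deltas get the degenerate convention p = 1 (no
shift) or p = 0 (uniform shift), flagged. `assign_writer()` assigns each
site to the knockdown with the largest stoichiometry drop, provided the
drop exceeds 0.10 absolute stoichiometry; sub-threshold drops and exact
ties stay unassigned, since depleting one synthase demonstrably
increases other D sites (compensation), and a forced argmax would
over-assign. The 0.10 default is a package choice, not a measured
constant, and is exposed as `drop_threshold`.

## What the simulator emulates — and what it does not

`simulate_counts()` generates count tables with exactly the structure
the model assumes: per T site, the treated ratio is
$\mathrm{clip}(A f + b, 0, 1)$ and counts are binomial at the configured
depth; input and IVT libraries use $f = 0$. Defaults are $A = 0.9$,
$b = 0.05$ — a near-complete linear response with a background in the
middle of the observed 4–15% per-motif range. One seed drives one
generator in a fixed order (reference, site selection, counts by
condition and replicate), so configurations reproduce byte-identically.

This is deliberately idealised. The simulator does **not** model:
motif-to-motif slope variation unless you supply `motif_params`;
sequencing miscalls into A/G unless `error_rate > 0`; coverage
heterogeneity beyond Poisson depth; alignment artefacts, multimapping,
or other uridine modifications (acp^3^U) that inflate input ratios at
specific tRNA positions. Passing the recovery suites therefore shows the
callers are correct *under the stated statistical model*, not that real
libraries are free of those confounds — that is what the input and IVT
controls are for in practice.

Two simulated regimes anchor the end-to-end suites, sized to run in
seconds:

* **ncRNA:** 20 planted sites (fractions 0.3–0.9) among ~5,000
  background T sites at depth 500, 40 seeded replicate runs. Every site
  is ≥ 5 s.d. from its nearest threshold, so recovery should be — and
  is — essentially perfect.
* **mRNA:** 8 planted sites among ~10,000 background T sites, two
  cellular and two IVT replicates at depth 200, 50 seeded runs. The
  planted panel spans the 10–40% stoichiometry regime as
  $\{0.10, 0.25, 0.275, \ldots, 0.40\}$: with $A = 0.9,\ b = 0.05$, any
  site below $f \approx 0.167$ has expected ratio under the 0.20 cutoff
  and is structurally undetectable, so the 10% site documents the
  detection floor while the remaining seven sit in the confidently
  detectable range (per-site power ≥ 0.98 from the normal approximation
  to criterion 1 and the noncentral-t power of the df-2 pooled test).
  The suite demands sensitivity ≥ 7/8 with zero false positives in
  ≥ 90% of runs.

## Numerical notes

* The calibration fit is closed-form (optionally depth-weighted) least
  squares, cross-checked against `stats::lm`; $r^2$ is `NA` for a
  constant response (zero total sum of squares), and a zero slope is
  returned with a warning — valid but non-invertible.
* Curve inversion clamps to $[0, 1]$ and records clamping; inversion
  with a missing or non-invertible motif curve uses the global mean
  curve, flagged per call.
* The paired and two-sample t-tests use explicit closed forms (hence
  exact agreement with `stats::t.test` is a test, not an assumption);
  zero-variance branches follow the degenerate conventions above with a
  `1e-12` tolerance on the delta spread to absorb floating-point
  cancellation.
* `pileup_from_sam()` walks CIGARs with the standard consumption rules
  (M/=/X both, I read-only, D reference-only into `n_del`, N
  reference-only, S read-only, H/P neither), keeps MAPQ-0 reads by
  default (multimapping is rampant in tRNA), and reports reverse-strand
  alignments complemented into transcript sense — D chemistry acts on
  the RNA strand.
* The 5-mer context at position $p$ is positions $p-2 \ldots p+2$,
  N-padded at reference ends.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
# calibrate from a simulated 6-level mixture series
curves <- fit_calibration(simulate_calibration_series(depth = 5000))
# background from 0%-D probes
probes <- simulate_probe_counts(d_fraction = 0, depth = 2000)
bg <- build_background(probes$counts, probes$reference)
# simulate a small ncRNA experiment and call
cfg <- sim_config(seed = 7, n_refs = 5, ref_length = 500, depth = 500,
                  n_sites = 10, d_fractions = seq(0.3, 0.8, length.out = 10),
                  replicates = c(treated = 2, input1 = 1, input2 = 1))
sim <- simulate_counts(cfg)
calls <- call_sites_ncrna(sim$counts$treated, sim$counts$input1,
                          sim$counts$input2, sim$reference, bg, curves)
subset(calls, called, c(ref_id, pos, motif, ratio_treated, d_fraction))
```

## Known limitations

* Calibration is linear only; saturating responses would need a model
  the package does not fit.
* Canonical tRNA position labels (16, 17, 20, 20a, 47, …) are consumed
  from a user-supplied annotation (`summarize_by_position()`), never
  inferred from structure.
* The caller cannot computationally distinguish D from acp^3^U/acp^3^D
  at shared positions beyond the input-ratio criterion; orthogonal
  evidence (input mutation signatures, mass spectrometry) is required.
* Writer assignment is a per-site argmax over knockdown drops; it does
  not model partial redundancy between synthases.
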