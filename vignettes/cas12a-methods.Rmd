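---
title: "Methods: amplicon indel quantification and PAM profiling for Cas12a"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplicon indel quantification and PAM profiling for Cas12a}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cas12atools)
```

# The problem

Cas12a (Cpf1) is a class II, type V-A CRISPR nuclease. It recognizes a
T-rich 4-nt PAM at positions −4..−1 immediately 5′ of the protospacer and
cleaves distal to the PAM, leaving staggered cuts with 5′ overhangs around
protospacer positions 18/23. Two experimental readouts dominate Cas12a
characterization:

1. **Amplicon deep sequencing.** PCR amplicons spanning the target are
   sequenced; insertions and deletions (indels) near the cut site report
   error-prone (NHEJ) repair of a nuclease cut. The quantity of interest is
   the per-sample *indel frequency*.
2. **Fluorescent reporter assays.** Loss of GFP in a GFP-integrated line
   (disruption), restoration of GFP from split fragments upon cleavage
   (GFxFP), or GFP knock-in (HDR), all measured as percentages of gated
   cells by flow cytometry.

A third, derived analysis aggregates activities across panels in which one
PAM position at a time is varied through all four bases, yielding a
position × base preference matrix and an IUPAC consensus such as `TTTV`.

This vignette documents the models, conventions and tunables behind each
stage, the design choices made where the procedure was genuinely
underdetermined, and what the synthetic-data tests do and do not establish.

# Alignment model

`semiglobal_align()` computes an optimal affine-gap semi-global alignment:
the read is aligned end to end while reference overhangs on both sides are
free, the natural model for a full-length read inside a longer amplicon
context (and the degenerate case where they are the same length). Scoring
(integers, configurable via `align_params()`):

| parameter | default | meaning |
|---|---|---|
| `match_score` | 1 | reward per identical base |
| `mismatch_penalty` | 1 | cost per substituted base; `N` never matches |
| `gap_open_penalty` | 2 | once per gap run |
| `gap_extend_penalty` | 1 | per gapped base |

A gap run of length $L$ costs $open + ext \cdot L$. No published scoring
scheme exists for this procedure; these defaults favor calling an isolated
substitution a mismatch (cost 1) rather than a 1-bp double gap (cost ≥ 6),
which is what indel counting requires.

**Determinism.** Traceback prefers, at equal score, a diagonal step over a
deletion over an insertion, and among equal-scoring end columns the
leftmost reference span wins; alignments never begin or end with a
deletion (uncovered reference is an unpenalized overhang instead). The
resulting operation list is therefore bit-reproducible. Note that indel
*placement* within a homopolymer run remains intrinsically ambiguous; the
tie rule fixes one placement, and the ±60 bp window makes the downstream
counts insensitive to it.

`orient_and_align()` aligns the read and its reverse complement and keeps
the higher score; on an exact tie the forward orientation wins. All
reported coordinates live on the forward reference axis, 0-based half-open
internally and 1-based inclusive in emitted reports.

The test suite checks the C++ core against an independent pure-R
brute-force DP that enumerates gap runs explicitly, on hundreds of random
pairs — the two implementations share only the scoring definition.

# Read filter, window, and frequency

**Anchor filter.** A read is kept when it matches at least 75% of the
first 20 bp of the reference amplicon. The rule is evaluated as
*alignment-based identity over reference positions 1–20 after orientation
selection*: anchor positions that are mismatched, deleted, or not covered
at all count as non-matches. A raw-prefix interpretation was rejected
because it fails for every reverse-orientation read and for any read with
an upstream insertion; the alignment-based reading is robust to both. The
boundary is inclusive (15/20 = 0.75 passes).

**Cut site.** The paper-facing convention places the cut after
`cut_offset = 18` protospacer bases from the PAM-proximal end on the
annotated strand — the PAM-distal midpoint of the 18/23 staggered cut.
The exact rule is not standardized; the offset is configurable, and the
±60 bp window makes the frequency insensitive to ±5 bp of convention.

**Window.** Insertions, deletions and mismatches are called within the
*closed* interval `[cut − 60, cut + 60]`. Insertions live at an inter-base
coordinate and are in-window iff that coordinate lies in the closed
interval; deletions and mismatch runs are in-window iff their interval
intersects it.

**Classification and frequency.** A read is edited iff it has ≥ 1
in-window indel; mismatches are called and reported but never counted as
edits. The frequency denominator is the number of anchor-passing reads —
counting is performed among reads that passed the filter — and the all-read
total is reported alongside so the other convention can be recomputed.
Reads failing the anchor contribute to `total_reads` only and are never
classified. Samples with fewer than 1000 total reads are flagged
`excluded` (the flag is advisory; results are still reported).

# Reporter-assay arithmetic

All inputs are already-gated percentages; FCS parsing and gating are out
of scope.

- **GFxFP**: `activity = sample GFP% − mean(negative-control GFP%)`,
  within the mCherry⁺ gate (a semantic contract of the input table).
  Negative activities are kept unclamped by default so replicate means
  stay unbiased; a clamp flag exists for display.
- **Disruption** exists in two legend variants and both are exposed as
  named functions rather than silently merged:
  `gfp_disruption_ratio() = 1 − sample/control̄` (a fraction) and
  `gfp_disruption_subtractive() = control̄ − sample` (percentage points,
  signed). Both are strictly decreasing in sample GFP, so rankings agree.
- **HDR**: `(day14 sample − day14 matched control) × (day2 reference /
  day2 condition)`. The day-2 reference point is not specified by the
  source procedure; the plate-wide day-2 mean is used, which leaves a
  plate with uniform transfection unchanged (factor 1 everywhere).
- **`boxplot_stats()`**: box limits are the medians of the lower/upper
  halves of the sorted data with the overall median excluded when n is odd
  (so `1:7` gives hinges 2 and 6 — the convention of the stated worked
  example, which differs from `fivenum()`'s inclusive Tukey hinges at odd
  n); whiskers extend to the most extreme points within 1.5 IQR of the
  hinges; notches are `median ± 1.58·IQR/√n`, the standard approximate 95%
  CI for the median.

# PAM preference and consensus

Within each target contributing a complete quartet (all four base variants
measured at the varied position), activities are normalized to sum to 1;
the per-base ratios are then averaged over targets *unweighted*. Averaging
raw activities instead would let intrinsically hot targets dominate —
absolute activity varies strongly between targets — so per-target
normalization is applied first and recorded in output metadata
(`normalization: "sum"`). Sum-normalization (rather than max- or
T-normalization, neither of which the source defines) was chosen because
it makes rows of the preference matrix true ratios that sum to 1.
All-zero quartets carry no preference information and are dropped with a
count.

`consensus_from_matrix()` includes, per position, every base with ratio ≥
`include_threshold` (default 0.15) and writes the allowed set as its
minimal IUPAC symbol. The default reproduces the canonical calls on
simulated panels — a T-dominant position collapses to `T`, an
"all but T" position becomes `V`, an A/T split becomes `W`, a C/T split
`Y` — and is a reported tunable, not a biological claim: whether a weak
fourth base belongs in the consensus is exactly what the threshold encodes.

`enumerate_target_sites()` scans both strands for PAM matches followed by
a full protospacer (default 23 nt) 3′ of the PAM on the same strand,
reporting forward-axis half-open coordinates with strand flags in
deterministic ascending order; windows containing `N` never match. The
implementation (vectorized per-position set membership) is tested against
a naive window-by-window scanner.

# Synthetic data: the stated world

The simulators exist so that every downstream stage has known ground
truth; their defaults describe a deliberately simple world.

**Reads** (`simulate_amplicon_reads`): every read spans the full amplicon
— amplicon sequencing of short PCR products justifies omitting any
fragmentation or trimming model. An edited read carries exactly *one*
indel (multi-edit reads are never described for this assay and would make
truth ambiguous), placed at the cut site plus a uniform offset within
±`position_jitter` (default 5 bp; real repair outcomes concentrate within
a few bp of the cut). The default indel-length distribution is
geometric-like over 1–20 bp — a placeholder shaped like typical NHEJ
spectra, not an empirical claim. Insertion bases are drawn from the RNG
(avoiding hidden correlation with the reference); a deletion is fully
determined by its position and length. Substitution noise (default 0.001
per base, typical of Illumina after quality trimming) is applied after the
edit; qualities are a constant symbol because the analysis is
quality-unaware. Configurations whose jitter or indel sizes could run off
the amplicon are rejected outright rather than clipped.

**Plates** (`simulate_assay_plate`): control wells are
Normal(95.72, 1.13) truncated to [0,100] — the canonical negative-control
GFP summary for a disruption line — and sample wells share the sd with
mean scaled by (1 − true_disruption).

**Panels** (`simulate_pam_panel`): activity = per-target log-normal scale
(sd 0.5, modeling observed target dependence) × base weight ×
multiplicative log-normal noise (sd 0.1). Each target emits 4 records per
varied position.

**What a green test does not establish.** The simulators omit PCR
duplicates and chimeras, paired-end structure, quality-dependent errors,
microhomology-biased deletion spectra, and multi-edit alleles. Recovery of
an injected indel rate therefore validates the *counting pipeline* —
alignment, filtering, windowing, classification, arithmetic — not the
biological fidelity of any real library. Conversely, the property-based
acceptance tests (oracle equivalence, boundary tables, determinism) hold
independent of these simplifications.

# Numerical and degenerate-input choices

- Identity thresholds and the window are compared inclusively (≥, closed
  interval), following "at least" / "±" wording.
- Zero filtered reads makes the frequency undefined: reported as `NA`
  with an explicit reason, never as 0.
- `position_preference()` errors when no complete quartet exists, and
  `consensus_from_matrix()` errors when a position has an empty allowed
  set — silent fallbacks would fabricate a consensus.
- Seeded simulators save and restore the caller's RNG state, so no hidden
  randomness crosses function boundaries; the pipeline requires an
  explicit seed for every stochastic stage and rejects unknown config
  keys by name.
- All integer scores overflow-safe for realistic read lengths (C++ `int`,
  sequences ≪ 10⁷ bp).

# Known limitations

- The aligner is quadratic time per read; it is intended for amplicon
  lengths (hundreds of bp), not genome-scale mapping.
- HDR normalization assumes day-2 GFP is strictly positive and that
  condition labels match across tables; it errors otherwise rather than
  imputing.
- The consensus caller reduces a quantitative preference matrix to a hard
  IUPAC set; borderline bases near the threshold are a reporting choice,
  and the matrix itself should accompany any consensus string.
- Reverse-strand site coordinates are reported on the forward axis; tools
  expecting strand-local coordinates must convert.
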