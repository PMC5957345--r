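---
title: "Binary QRS template matching for identity verification: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binary QRS template matching for identity verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

A resting 12-lead ECG carries a stable, subject-specific signature in the
shape of the QRS complex — the ~100 ms deflection of ventricular
depolarization. `qrsmatch` implements a 1:1 *verification* task: given two
recordings made on different occasions (a reference session S1 and a remote
session S2, possibly years apart), decide whether they come from the same
person. The method deliberately uses only two scalar features per lead,
derived from a binary approximation of the QRS shape, and a linear
discriminant on top; there is no template gallery, no deep representation,
and no dependence on absolute voltages.

## The pipeline

1. **Resampling.** Average beats (500 ms per lead) arrive at 500 Hz and are
   upsampled to 1000 Hz so one sample equals one 1 ms time-grid column. The
   upsampler is a factor-2 zero-stuffing interpolator with a Kaiser-windowed
   sinc anti-aliasing filter (`resample_to_1ms()`). The window shape
   (`beta = 5`) and half-length (10 ms) are configurable because the
   resampler family, not a specific toolbox default, is what matters: each
   polyphase branch is normalized to exact unit DC gain, the signal is
   symmetrically padded, and the first/last 5 ms — where filter transients
   live — are excluded from the package's own accuracy assertions. The QRS
   window is interior, so transients never touch it.

2. **Alignment.** All beats are time-aligned to a single lead-I reference
   pattern by maximal normalized cross-correlation (`align_to_reference()`),
   searching lags within ±100 ms by default. The normalization by the
   overlapping segments' energies makes the match invariant to amplitude
   scale, and ties break toward the smallest absolute lag. Bounding the
   search matters: an unbounded scan can lock onto the T wave of a beat
   whose QRS resembles its own T in shape. The original study initialized
   its reference as a normally behaving positive-deflection lead-I average
   beat from the population; since no such beat is published, the package
   ships a canonical synthetic reference with exactly those qualitative
   properties (`default_reference()`, fixed internal seed) and accepts any
   user-supplied reference in the same CSV dialect.

3. **Windowing.** A 100 ms window — 30 ms before to 70 ms after the
   fiducial point — is cut *synchronously* in all 12 leads
   (`extract_patterns()`). Indices are 0-based and the window is half-open
   on the right: samples `fiducial - 30 .. fiducial + 69`, exactly 100
   values. Aligning once in lead I and cutting all leads at identical
   indices is one of the two measures against measurement bias; per-lead
   independent alignment is deliberately not offered.

4. **Pair normalization.** For each pair of sessions and each lead, both
   patterns are shifted so their QRS-onset level sits at 0 V and divided by
   one *shared* scale factor — the maximal absolute amplitude over both
   sessions and all 100 samples (`normalize_pair()`). Sharing the scale is
   essential: it removes inter-subject and inter-lead voltage spans while
   preserving the relative amplitude difference between the two recordings,
   which is signal, not nuisance. When the QRS onset is not annotated the
   amplitude at the window start (−30 ms) is used as the onset level; for
   normal beats that sample precedes the QRS and is a good baseline proxy.

5. **Binary approximation.** Each normalized pattern becomes a 100 × 80
   boolean occupancy matrix (`binarize()`): columns are 1 ms steps, rows are
   amplitude bins of width Δa = 0.025 with centers at −1 + (j + 0.5)·Δa. A
   cell is occupied when its row center lies within 2Δa (±2.5% of the full
   range) of the pattern value at that column *or at either neighboring
   column*, and each column is filled to contiguity between its band
   extremes. The band is a tolerance region: it absorbs ±1 ms of timing and
   ±2.5% of amplitude variation between sessions, which is the method's
   robustness mechanism against benign intra-subject change.

6. **Matching features.** For a pair of binary matrices,
   `compute_tequ()` counts the columns where the two bands overlap (an AND
   matrix with at least one occupied cell per column), as a percentage of
   the 100 ms length; `compute_adif()` accumulates, per column, the cells
   between the two pattern amplitudes where the bands do *not* both cover
   the cell (a NAND matrix restricted to the enclosed range), scaled so
   that full-range disagreement at every step is exactly 100%. Twelve leads
   × (tEQU, aDIF) give the 24-feature vector of a pair
   (`extract_pair_features()`).

7. **Verification.** `qrs_verifier()` trains a two-class linear discriminant
   with pooled covariance and equal priors on a balanced set of equal- and
   different-identity pairs, with greedy forward stepwise feature selection
   maximizing the training ROC AUC. The acceptance threshold is calibrated
   at the equal-error-rate point of the training ROC (TAR = TRR, found by
   linear interpolation between sweep points) and then held fixed: reported
   test TAR/TRR/TVR are therefore unbiased with respect to the test data.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `grid.dt_ms` | 1 | ms | time resolution of the binary grid (100 columns) |
| `grid.da` | 0.025 | normalized | amplitude bin width (80 rows over [−1, 1]) |
| `grid.tolerance_steps` | 2 | bins | occupancy half-band = 2Δa = ±2.5% of range |
| `max_lag_ms` | 100 | ms | alignment search half-range |
| `epsilon` | 1e-4 | AUC | stepwise stopping improvement |
| `beta`, `half_len_ms` | 5, 10 | —, ms | Kaiser resampler shape and support |

Coarsening the grid (larger Δt, Δa) shrinks the matrices at the cost of
shape detail; the defaults match the finest resolution the 1000 Hz signal
supports and a memory footprint of 8000 cells (1 kB) per lead.

## Numerical choices

* **80 rows, not 81.** The literal amplitude grid [−1, −1+Δa, …, 1] has 81
  points, but the stated matrix size and memory budget imply 80; the
  package uses 80 bin *centers* at −1 + (j + 0.5)·Δa, which tile [−1, 1]
  exactly.
* **aDIF scaling.** One cell contributes Δt/100 · Δa/2 · 100 percent: the
  amplitude step is expressed as a fraction of the full 2-unit range
  (1.25%), so that disagreement covering the whole range at every time step
  yields exactly 100. Scaling by raw Δa would top out at 200.
* **Neighbor-time tolerance.** The binarization condition for the
  neighboring columns carries the same ±2Δa amplitude tolerance as the
  center column; requiring exact grid-value membership of a continuous
  signal would almost never fire.
* **Contiguity fill.** Column bands are filled between their extremes so a
  steep slope cannot leave vertical gaps inside its own band; this also
  makes the interval representation (`band`) exact, which is what the
  vectorized batch path (`cohort_pair_features()`) computes. The full
  matrices and the intervals are proven equivalent in the test suite
  against a literal per-cell implementation.
* **Row mapping and boundaries.** A continuous value maps to the nearest
  bin center, ties toward the lower row; the enclosed amplitude range of
  aDIF includes both boundary rows; band-membership comparisons are
  inclusive with a 1e-9 slack applied identically in the fast and reference
  paths, so exact boundary hits are decided consistently.
* **EER interpolation.** When the TAR = TRR crossing falls between two
  sweep thresholds, the operating point interpolates linearly in both
  rates and threshold; at the crossing TAR and TRR are equal by
  construction.
* **Degenerate inputs.** A lead whose two patterns are identically at the
  onset level has no scale factor and raises a degenerate-lead error; a
  singular pooled covariance falls back to minimal diagonal shrinkage (and,
  for fully zero-variance features, to the mean-difference direction) with
  a warning rather than failing.
* **Tie-breaks.** Alignment ties prefer the smallest absolute lag; stepwise
  ties prefer the canonical feature order (lead I..V6, tEQU before aDIF),
  making selection deterministic and invariant to candidate ordering.

## The synthetic cohort generator

Real paired-session 12-lead cohorts of meaningful size are clinical,
proprietary data. The generator (`simulate_cohort()`, `generate_cohort()`)
exists so that every pipeline stage — and the full train/calibrate/test
loop — is exercisable from a seed alone.

Each subject is a set of per-wave Gaussian parameters (P, Q, R, S, T:
amplitude, center, width) for two frontal-plane dipole components and for
each chest lead. Leads I and III render the two components; II, aVR, aVL,
aVF follow by the Einthoven/Goldberger identities, which therefore hold
exactly before noise — a property the tests assert. Chest leads are drawn
independently: the method treats leads independently and chest projections
are idiosyncratic in practice. Inter-subject distinctiveness comes from the
amplitude/width draws plus per-source intrinsic-deflection offsets (sd
2–8 ms) around the shared wave centers.

The remote session S2 perturbs the parameters — a global time shift
(±10 ms, recovered by alignment), relative per-wave amplitude jitter
(sd 0.10), per-wave timing jitter (sd 1 ms, shared across leads), optional
per-lead rescaling emulating electrode misplacement (off by default) — and
both sessions carry 15 µV RMS of band-limited additive noise. These
defaults were fixed once, by calibrating the generated feature
distributions against the published per-lead medians and quartiles of a
460-subject clinical cohort (equal-identity matching time medians in the
75–99% range with lower quartiles down to ~63%, different-identity
mismatch areas of roughly 8–30%): amplitude jitter of ~10% reflects
electrode-placement and impedance change across sessions, while QRS
micro-timing is physiologically far more reproducible, hence the 1 ms
timing sd. Heart rates are emitted as covariates only (S1 uniform in
50–95 bpm, S2 delta normal with sd 8 bpm).

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: no torso volume-conductor physics (chest leads
are independent draws, not projections of one source); no heart-rate
dependence of the beat morphology (HR is a pure covariate); no arrhythmia,
ectopy or lead-quality failures (the upstream averaging module that handles
those is out of scope); no notched/fragmented QRS beyond what Gaussian sums
express; and no attempt to reproduce the clinical feature distributions
exactly, only their ordering and rough scale.

## Problem sizes

The package's own test suite and the acceptance script run the full
pipeline on a seeded 100-subject cohort (100 equal + 9900 different pairs;
50/50 balanced training pairs, 50 + 9850 test pairs), which reproduces the
qualitative results — multi-lead superiority over every single lead, EER
balance on training, same-subject feature dominance in every lead — in
about a minute on one CPU. Smaller cohorts (2–60 subjects) back the unit
tests; the brute-force per-cell oracle is checked on 100+ random pattern
pairs. These sizes are the package's chosen trade-off between statistical
resolution and test-suite turnaround.

## Known limitations

* The upstream production chain (beat detection, averaging, arrhythmia
  rejection, QRS-onset annotation from raw signal) is out of scope; inputs
  must already be average beats. Without an onset annotation the window
  start stands in as the onset level, which is slightly less accurate for
  beats with early Q onset.
* The WFDB dialect is reserved but not implemented in this build; convert
  records to the beat CSV dialect.
* With small balanced training sets (tens of pairs) the stepwise search can
  stop after very few features; training AUC saturates at 1 and the
  selection becomes conservative by design.
* `sample_size_sweep()` cannot literally enumerate all subject
  combinations for mid-range subset sizes (the counts are astronomical); it
  switches to seeded uniform subset sampling above a configurable cap and
  reports which mode was used.
* The rank test is exposed in both paired (signed-rank) and unpaired
  (rank-sum) variants; group contrasts between disjoint subject groups are
  unpaired, so the unpaired variant is the default in group comparisons.
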