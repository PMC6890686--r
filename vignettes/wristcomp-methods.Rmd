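---
title: "Methods: accelerometer metric comparability and dominant-wrist cut-point translation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accelerometer metric comparability and dominant-wrist cut-point translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristcomp)
```

# The problem

Large cohort studies measure physical behaviour with raw tri-axial
accelerometers, but they disagree on where the device is worn (right hip,
dominant wrist, non-dominant wrist) and on how the 100 Hz signal is reduced
to an epoch-level "acceleration metric". Both choices change the final
estimates of sedentary time, physical-activity (PA) intensity and sleep.
`wristcomp` implements a complete processing and analysis chain for this
problem: epoch metrics from raw signals, wear-time handling, waking/sleeping
separation, comparability statistics between sites and metrics, and — the
centrepiece — a grid-search *translation* of validated non-dominant-wrist
ENMO cut points to the dominant wrist, with cross-validation in an
independent sample.

Real multi-site recordings of this kind are rarely shareable, so the package
also contains a synthetic cohort generator with complete ground truth. Every
stage is tested against that ground truth; the published worked example (the
candidate agreement table and its 50/110/440 mg selection) is additionally
reproduced exactly from its printed inputs.

# Epoch metrics

All metrics are computed per 5-s epoch on a half-open grid `[t, t + 5)`
anchored at local midnight (partial epochs at the recording edges are
dropped; the first full epoch after the start is used). Units are mg
(1 mg = 0.001 g).

* **ENMO** — per sample, the Euclidean norm of the calibrated acceleration
  vector minus 1 g, with negative values truncated to zero *before*
  averaging over the epoch. The truncation-then-average order matters for
  signals that dip below 1 g and is fixed by the metric's definition.
* **LFENMO** — ENMO of the per-axis low-pass filtered signal (Butterworth,
  4th order, 20 Hz cutoff). The source chain does not state the phase
  convention; we default to zero-phase forward–backward filtering (which
  preserves the epoch alignment of signal features) and expose a
  single-pass option behind `metric_config(phase = "single")`. When the
  cutoff is at or above Nyquist (sampling below 40 Hz) the filter is
  skipped with a warning, making LFENMO equal to ENMO.
* **MAD** — per epoch, the mean absolute deviation of the vector norm
  around its epoch mean. For a sinusoidal norm of amplitude $A$ this is
  $(2/\pi)A$, which the tests assert.

ENMO and MAD depend only on the vector norm and are exactly rotation
invariant; LFENMO filters per axis and is rotation invariant only
approximately (within 1 mg for locomotion-band signals, asserted in tests).
Activity *counts* are a proprietary vendor metric; their band-pass
pipeline is not public, so counts are only ever ingested from exported
epoch files (`read_epoch_counts()`) and then share the wear/imputation
processing of the other metrics. They are never computed internally.

# Gravity auto-calibration

Offsets and gains per axis are estimated from still windows: consecutive
non-overlapping 10-s windows whose per-axis SD is below 13 mg on **all
three** axes (stricter than the 2-of-3 non-wear criterion, so that retained
windows are genuinely static). During stillness the window-mean vector must
lie on the unit sphere, so `estimate_calibration()` runs an
iteratively-reweighted least-squares fit pulling the window means onto the
sphere. Identifiability requires orientation diversity: each axis must
contribute window means beyond ±300 mg in both directions; otherwise the
function returns identity parameters with `sphere_coverage_ok = FALSE` and
a warning, never a silent partial fit. The calibration error (mean absolute
deviation of window-mean norms from 1 g) is non-increasing over iterations,
and parameter recovery on injected errors (|offset| ≤ 50 mg, gain within
3%) has a median error well below 3 mg / 0.003 in the test suite.
Temperature covariates, used by some calibration schemes for other devices,
are omitted: the emulated device export has no temperature channel.

# Non-wear, clipping and imputation

Each 15-min block (aligned to midnight) is classified as non-wear when, over
the 60-min window centred on the block (truncated at recording edges), at
least 2 of 3 axes have SD < 13 mg **or** at least 2 of 3 axes have a value
range < 50 mg. Ties at exactly the threshold count as wear (the criterion
is strictly "lower than"). Epochs containing any sample above 5.5 g
(strictly greater, per-axis or norm) are flagged as abnormal and routed
through the same invalidation path. Invalid epochs are imputed with the
mean of valid epochs at the *same clock time on the other recorded days*;
epochs with no valid donor stay missing and are excluded from summaries.
Days with ≥ 16 h of wear are valid; participants with ≥ 4 valid days are
included. Non-wear that is not matched across sites is deliberately *not*
deleted.

Two documented interpretation choices: the "surrounding" window is centred
on the block and truncated at the edges (edge handling is unstated in the
source), and SD/range are computed on raw samples (whether the original
chain down-sampled first is unstated).

# Waking/sleeping separation

Sleep is detected on the non-dominant wrist from the posture angle of the z
axis against the horizontal plane (`z_angle()`: per-5-s axis means, rolling
median over 5 windows, `atan2(z, sqrt(x² + y²))`). Within a diary-guided
search window (logged bed/rise times ± 2 h), runs of successive angle
changes below 5° sustained ≥ 5 min are sleep candidates; candidates closer
than 60 min merge; the longest merged block is the night's sleep period.
With no candidate the diary times are used, with a warning. The detected
segmentation is projected unchanged onto the hip and dominant-wrist series
of the same participant, so all sites share one waking/sleeping partition.
The published chain only cites its sleep detector; this implementation is a
faithful-in-spirit angle-change heuristic whose constants (5°, 5 min,
60 min, ±2 h) are all configurable arguments. On synthetic cohorts the
median onset/wake error is under 15 min.

# Agreement statistics and the cut-point translation

Waking, worn-or-imputed ENMO epochs are binned by half-open thresholds
(lower bound inclusive: an epoch at exactly 50 mg with cuts 50/110/440 is
light). Minutes per category are accumulated per participant-day and
averaged over valid days; the participant is the unit of analysis.

Agreement between the reference (non-dominant wrist, 45/100/430 mg) and a
candidate (dominant wrist) is summarised by:

* **LCCC**, Lin's concordance correlation coefficient,
  $\rho_c = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)$ with $1/n$
  moment estimators;
* the **mean difference** (dominant minus non-dominant) with a paired-t
  95% CI — the data are paired by design, so the "two-sample t-tests" of
  the source are implemented as paired t;
* **MAPE** at the group level, $100\,|\bar d|/\bar x_{\mathrm{ref}}$,
  reported to two decimals. This group-level operationalisation is the only
  one consistent with every printed worked-example cell (e.g. 25/769 →
  3.25%, 14/147 → 9.52%); a per-participant mean-of-absolute-percent-errors
  is available as `mape_individual()` but plays no role in selection.

The candidate grid increments each reference threshold by 0 / 5 / 10 mg:
sedentary candidates vary only the sedentary threshold; light candidates
the (sedentary, light-upper) pair; moderate candidates the (light-upper,
moderate-upper) pair; vigorous candidates only the moderate-upper
threshold — 3 + 9 + 9 + 3 = 24 candidates.

**Selection** proceeds vigorous → moderate → light, at each step minimising
|mean difference|, then MAPE, then maximising LCCC. The source states the
three statistics without a strict order; this ordering is our documented
choice, with the published Table-5 outcome as its regression test. A step
whose candidates all tie defers to the next step. Remaining ties are broken
by preserving the reference inter-threshold distance (430 − 100 = 330 mg
selects 110–440 over 110–430/435 exactly as published), then by staying
closest to the reference thresholds, so fully symmetric ties return the
reference set itself. Statistics are compared with a small numeric
tolerance so that printed (rounded) inputs tie exactly while computed
inputs essentially never do. Selected thresholds are cross-validated on an
independent cohort (overlapping participant ids are an error).

# Diurnal profiles, sorted curves and SPM

Diurnal profiles average epochs into 48 half-hour clock bins
(participant-day → day → participant → cohort), optionally z-scored across
bins when metrics with different units share a plot. Because daily activity
curves are highly variable in *when* activity happens, paired curve
comparison uses **sorted** daily curves: each complete day's epoch values
sorted ascending and down-averaged onto Q equal nodes (default Q = 1440,
one node per minute of the day; the source does not state its resolution,
so it is configurable and recorded in output metadata), then averaged over
days within participant. Sorted curves are non-decreasing and preserve the
day's mean.

`spm_paired_t()` compares per-participant curve pairs with one-dimensional
statistical parametric mapping: (1) a paired t statistic at every node;
(2) smoothness estimated as the FWHM implied by the mean squared temporal
gradient of the normalised residuals; (3) a two-sided family-wise critical
threshold $t^*$ from the expected Euler characteristic of an equally smooth
t random field with `resels = (Q − 1)/FWHM`; (4) cluster-level p-values for
suprathreshold regions from the standard 1-D random-field cluster-extent
approximation. Zero-variance nodes are guarded by a relative variance floor
and flagged. A sign-permutation mode (`method = "perm"`, max-t and
max-extent null distributions; all sign flips enumerated up to n = 14)
ships alongside as an exact small-sample alternative and as the oracle the
RFT threshold is validated against: on smooth synthetic fields the two
thresholds agree within 10%, and the family-wise false-positive rate over
500 null replicates lies in [0.03, 0.08] at α = 0.05. Clusters on sorted
curves are reported as percentile bands of the daily acceleration
distribution (`percentile_band_report()`).

# The synthetic cohort generator

The generator emulates the statistical structure the analysis relies on,
per participant and day:

* **Signal model** — gravity orientation unit vector, plus a sinusoidal
  dynamic component *along gravity* in the human locomotion band
  (0.6–4 Hz), plus isotropic Gaussian noise (default SD 5 mg), clipped to
  the ±6 g sensor range. The sinusoid amplitude is scaled so the noiseless
  epoch ENMO equals the bout's target amplitude — that calibration makes
  the schedule the ground-truth oracle for every downstream test.
  Frequencies whose low rectified-sinusoid harmonics alias onto DC at the
  chosen sampling rate are excluded from the menu, keeping the epoch-ENMO
  bookkeeping within 2% (typically 0.4%).
* **Schedule** — nightly sleep windows of ~7–8 h; waking time tiled with
  5–30 min everyday bouts whose amplitudes follow a decreasing continuous
  distribution (Gamma(0.9, 35 mg), capped at 245 mg) plus 1–3 exercise
  bouts of 15–40 min at 150–500 mg. These defaults put the scheduled day
  near the reported cohort profile (roughly 690/175/90/9 min of
  sedentary/light/moderate/vigorous waking time). The continuous amplitude
  density across the intensity boundaries is what makes the cut-point grid
  search identifiable.
* **Sites** — one schedule per participant drives all three sites; the
  dominant wrist multiplies dynamic amplitudes by `asymmetry_ratio`
  (default 1.1) and the hip by `hip_attenuation` (default 0.5), matching
  the observed dominant > non-dominant > hip ordering. A single
  multiplicative ratio is an assumption: the source reports only group
  means for the asymmetry.
* **Orientation** — piecewise constant with posture changes roughly every
  20 s while awake (wrists gesture constantly) and every 8–20 min during
  sleep (position shifts of 15–60°); frozen during non-wear, which also has
  no dynamic component. Sleep posture shifts are deliberate: a night with
  literally frozen orientation is indistinguishable from non-wear under
  the SD/range rule, and real sleepers do shift. Between shifts sleep
  orientation is exactly constant, which drives the angle-based sleep
  detector correctly.
* **Non-wear and diary** — optional daily non-wear episodes (default
  probability 0.2, 45–90 min) during waking hours; the diary logs bed/rise
  times with 0–20/0–25 min of reporting error, in the direction the source
  observed (bed logged earlier, rise logged later).

Identical `cohort_spec`s generate identical cohorts. What the generator
does **not** emulate: biomechanically realistic gait spectra,
device-specific noise colour, temperature drift, naps, or any counts
signal. Passing tests therefore demonstrate that the *pipeline* recovers
known structure under the stated signal model, not that the model captures
every property of real wrist data. One visible consequence: with a pure
sinusoidal dynamic component MAD ≈ 2 × ENMO per bout, whereas real data
show a smaller ratio — comparisons that depend on the ENMO/MAD ratio are
qualitative here.

# Problem sizes, numerical choices and limitations

The default "desk-scale" profile is 30 Hz sampling, 1–4 recording days and
at most a dozen participants per experiment; 50 Hz is used wherever the
20 Hz low-pass must actually act (LFENMO concordance, the cross-metric
comparability analysis), and 100 Hz is supported throughout. The shipped
experiments use: 6 × 1-day participants for ENMO–LFENMO concordance
(r² ≥ 0.95 at both epoch and participant level); 12 × 1-day participants
with forced 45–150 min non-wear episodes for non-wear recovery; 100 seeded
orientation sets for calibration recovery; 20 seeds × 6 participants for
cut-point recovery; 500 null replicates at Q = 200 for SPM calibration;
and a 6-participant × 4-day end-to-end run. Analysis scripts regenerate
their cohorts deterministically and stream participants one at a time, so
peak memory stays near a single recording's footprint.

Non-wear recovery is scored at block level with the window geometry in
mind: a block's 60-min window mixes episode and wear signal within
22.5 min of an episode boundary, so sensitivity is evaluated on blocks
whose full window lies inside an episode and specificity on blocks whose
window does not intersect one; boundary blocks are ambiguous by
construction and excluded.

Cut-point recovery under a 10% asymmetry has one structural limit: the
ideal moderate-to-vigorous boundary (1.1 × 430 = 473 mg) lies above the
candidate grid, whose maximum is 440 mg. The grid search therefore selects
the admissible candidate closest to the scaled value (440), and the
recovery experiment asserts closeness to the scaled reference *projected
onto the grid*. Sedentary (≈ 49.5 → 50) and light (= 110) boundaries are
recovered within one 5-mg grid step outright.

Known limitations: no energy-expenditure criterion is available, so the
translated cut points equalise *between-wrist estimates* rather than
validating against measured intensity; counts comparability can only be
studied with externally supplied count files; and the sleep detector is a
documented stand-in for the cited algorithm with the same inputs and
outputs but not guaranteed constant-for-constant equivalence.
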