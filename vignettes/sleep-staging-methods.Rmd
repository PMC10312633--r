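---
title: "Methods: sleep staging from multichannel fly-brain LFP"
author: "FlySleepLFP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep staging from multichannel fly-brain LFP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, conventions and numerical choices behind
FlySleepLFP. The package implements an analysis chain for long-term
multichannel local field potential (LFP) recordings from tethered
*Drosophila* walking on an air-supported ball, together with the video and
pose streams recorded alongside: behavior-based sleep labeling,
polarity-reversal re-referencing, channel-by-frequency spectral features,
cluster-based permutation statistics, classifier-probability sleep staging,
and proboscis-extension (PE) micro-behavior analysis.

## The measurement model

A linear 16-electrode probe enters through the eye, so electrode 16 sits
most peripherally (retina/optic lobe) and electrode 1 most centrally.
Visual-stimulus-evoked deflections flip sign along the probe: positive in
the eye and optic lobe, negative centrally. The channel where the flip
occurs (the *polarity reversal*, channels 11-13 in practice) is a spatial
anchor: `detectPolarityReversal()` finds it from the stimulus-locked
average, and `rereferenceReversal()` subtracts every channel from it. Two
properties matter:

* the convention is **reference minus channel** (the literal subtraction
  order); flipping it flips the sign of every difference map, so it is
  asserted by a unit test;
* any component common to all channels (heartbeat and other non-brain
  physiology) cancels exactly, and the reversal channel is consumed, leaving
  15 channels.

`rereferenceBipolar()` (neighbor differences) is the variant used for
recordings referenced differentially; it also maps 16 channels to 15.

## Sleep labeling

Movement is quantified per video frame (30 frames/s) by frame differencing:
crop, grayscale, absolute difference, binarize, dilate (3x3 box, twice),
connected components; a frame is "moved" iff a contour reaches the area
threshold. Brief noise is pruned (movement runs < 1 s, then stillness runs
< 1 s — both exposed). Sleep is the standard fly criterion: complete
stillness for strictly more than 5 minutes (a tie at exactly 300 s stays
awake). Each bout is partitioned into:

| label | interval |
|---|---|
| presleep | 2 min before bout start |
| earlysleep | first 2 min of the bout |
| midsleep | interior |
| latesleep | last 2 min |
| pre2 / post2 | [-4, -2) min before, and [0, +2) min after the bout — evaluation-only |

pre2 and post2 never enter any training set; the probe audit
(`assertNoEvalRows`) enforces this on every fit. When two bouts are closer
than the flanking bins require, bins are clipped at the gap midpoint and
presleep (sleep-adjacent) wins over the evaluation bins; this keeps all
intervals disjoint and is exercised by hand-computed cases. All durations
are computed from frame timestamps, not indices, so dropped frames cannot
stretch a bout.

## Spectral features

Preprocessing resamples to 250 samples/s (zero-phase FIR anti-aliasing and
interpolation), band-passes 0.5-40 Hz with a Hamming windowed-sinc FIR
applied with exact group-delay compensation (zero net phase), and notches
50 Hz. Hourly acquisition segments are stitched with a 1-s linear bridge so
no boundary step survives.

Per 60-s epoch and channel, power is estimated by a Welch average: 1024-
sample Hamming windows, 50% overlap, reported as 10·log10(uV²/Hz). On the
1024-point grid at 250 samples/s the 5-40 Hz band corresponds to bins
20-164 — exactly **145 bins** (4.88-40.04 Hz, 0.2441 Hz spacing) — so an
epoch contributes a 15 x 145 channel-by-frequency feature grid. This grid
size is a structural invariant of the pipeline and is asserted in the
acceptance suite. The estimator parameters are fixed because the grid
dimension depends on them; any change alters the feature space.

## Cluster-based permutation inference

Group-level contrasts are per-fly mean spectral differences (condition A -
condition B, dB), gated at a minimum trial count per condition (10 for the
60-s sleep/wake analysis, 50 for 1-s PE epochs). `clusterPermutationTest()`
computes cell-wise one-sample t statistics across flies, thresholds at the
two-tailed t quantile (alpha 0.05, df n-1), groups same-signed
supra-threshold cells under 4-connectivity (consecutive frequency bins;
channels adjacent only when their original electrode indices are
consecutive, so the dropped reversal channel does not bridge channels 10
and 12), and calibrates the maximum |sum of t| against **all 2^n sign-flip
permutations** (Gray-code enumeration in compiled code; each permutation
costs O(cells)). For n > 20 flies a seeded random subset of 2^16 flips is
used. Exhaustive p-values are exactly reproducible and are verified
cluster-by-cluster against an independent reference implementation (MNE's
one-sample spatio-spectral cluster permutation test, run through the system
python) on random small instances.

Effect sizes are one-sample Cohen's d per cell (mean of per-fly differences
/ their SD); zero-variance cells are reported as 0 when the mean is 0 and
capped with a warning otherwise. Within-cluster post-hoc summaries report
the per-fly in-cluster mean and the direction of the contrast.

## Classifier staging

The *probability probe* trains a linear-kernel SVM on awake vs midsleep
epochs only (balanced by random undersampling; SMOTE is reserved for the
multiclass analysis), with z-score standardization fit on the training 80%
of a stratified split, and sigmoid-calibrated class probabilities. The probe
is then read out on every epoch — including presleep, early/late sleep and
the never-trained pre2/post2 bins — and its awake-class probability is
summarized per relative-time bin over 5 independent splits (two in the
desk-scale acceptance runs; the split count only narrows the summary's
dispersion). The package's qualitative target, stated as an ordering rather
than as printed values: midsleep lowest, early/late sleep intermediate,
awake highest, and post-waking bins indistinguishable from awake. Because
calibrated probabilities saturate on well-separated classes, the
"indistinguishable" clause is operationalized on the probe's dynamic range:
the post-waking mean must sit within 10% of (awake - midsleep) of the awake
mean.

The five-class analysis balances with SMOTE (synthetic rows uniform on
segments between a minority row and one of its 5 nearest minority
neighbors), splits 80/20 stratified, scales, and fits a random forest tuned
by a seeded two-stage search (random screen by out-of-bag error, then a
local grid) within a fit budget. Splits are epoch-level, matching the
analysis this package re-implements; note SMOTE-before-split means
synthetic rows derived from test-side originals can inform training — we
keep that ordering deliberately for fidelity, and the never-train audit
still guarantees the evaluation-only bins stay unseen.

Permutation feature importance shuffles one feature column at a time on the
held-out rows (5 repeats, averaged over split iterations) and records the
drop in the model score, reshaped to the channel x frequency grid. The
default score is the **mean probability assigned to the true class**: with
desk-scale held-out sets (~100 epochs) an accuracy drop is quantized at
about one percentage point and cannot rank 2175 features; the probability
score is continuous and ranks them reliably. `score = "accuracy"` restores
the conventional choice.

## The synthetic-session generator

`simulateSession()` emulates the statistical structure the analysis
assumes; its defaults are the study conditions under which the acceptance
suite runs.

* **Background**: per-channel 1/f noise (exponent 1, sd 10 uV) plus a
  shared broadband component whose channel weights form a signed linear
  ramp crossing zero at the reversal channel (peripheral positive, central
  negative) — the simplest geometry reproducing the evoked-deflection
  pattern. The state power gain multiplies both components, so the
  configured awake/midsleep band-power ratio is exactly recoverable from
  the generated data (asserted at ±10%).
* **States**: sleep bouts ~N(10, 2.5²) min (night bouts, beyond 6 h into
  the session, longer by 1.6x — matching the reported night/day median
  ratio of roughly 22/14), inter-bout gaps ~N(6, 1.5²) min, all on a whole-
  second grid. Power gains relative to midsleep = 1: awake 2.0, presleep
  1.7, early/late 1.45. The presleep gain is not in the original condition
  list; it was added because presleep LFP is already sleep-like while the
  fly still moves, and five-class separability requires presleep to have
  its own level.
* **Stage signature**: an extra 5-10 Hz component on channels 1-3 during
  sleep, with per-stage power factors (early 2.0, mid 6.0, late 3.2).
  These are chosen so that the in-box class levels in dB
  (10·log10(gain x boost): 4.6 / 7.8 / 6.7 vs awake 3.0) spread wider than
  the broadband levels (0-3 dB) — i.e. so the box is, by construction, the
  dominant stage discriminant that the importance analysis should find.
  The band-variance calibration uses the analytic spectral shape of the
  generated noise, so injected boosts are exact, not approximate.
* **PE events**: burst-initiation rates 0.3/min awake and 1.5/min midsleep
  (midsleep onsets fall at least 2.5 min into the interval with probability
  0.9); a burst is a single event with probability 0.33, otherwise
  2 + Poisson(1.5) events at N(1.5, 0.1²) s spacing; bursts are at least
  10 s apart. Sleep PEs add a 32-40 Hz component on channels 1-5 (factor
  1.5) for the PE-contrast analyses.
* **Pose**: PE displacement is a raised-cosine pulse of 0.5 s and ~20 px;
  proboscis likelihood dips to ~0.75 during extensions (exercising the
  likelihood-augmentation path) and below 0.4 in occlusion windows
  (disabled by default); antennal tips oscillate at 1 Hz, ±10°, during
  sleep only; eye and abdomen are quasi-static.
* **Calibration**: 20 presentations of a 3-s, 1 Hz square wave; each
  leading edge evokes an 80-ms half-sine whose channel amplitudes follow
  the signed ramp (60 uV at the outermost channel).

Everything is seeded; identical config + seed reproduces a session
bit-for-bit, and the component generators re-seed from fixed offsets of the
config seed so they are reproducible standalone as well.

What the generator does **not** emulate: realistic spatial correlation
structure beyond the single shared ramp component, movement artifacts,
electrode drift, grooming and leg kinematics, non-stationarity within a
state, and circadian modulation beyond the day/night bout-length factor.
Passing tests therefore demonstrate that the pipeline recovers the effects
it is designed to measure when those effects are present as modeled — not
that real recordings satisfy the model.

## Micro-behavior analysis

Pose features: per body part, raw coordinates, a zero-phase 0.1 Hz
Butterworth low-pass (order 2, with mean restoration to avoid the
zero-initial-state transient), and a 5-sample centered moving average of
the filtered series; `dist_eyeprob` is the raw proboscis-eye distance times
the proboscis likelihood. Two PE detectors are provided, mirroring the two
rigs the analysis chain serves: (i) an RBF-kernel SVM frame classifier
(70/30 split) whose positive segments — augmented by frames where the
proboscis likelihood falls below 0.9 — are reduced to one event per
extension at the maximum displacement frame; and (ii) a peak-picker on the
distance to the per-recording median (resting) position with three
exclusions applied in order: amplitude cap, single-frame spikes, and rises
faster than 0.1 s. Their agreement on synthetic tracks is measured, not
assumed (both reach precision/recall ≥ 0.9 against ground truth at default
SNR, matched within ±0.25 s).

Events within 10 s chain into bursts (single-linkage); burst grouping is
idempotent, order-independent and conserves events. Antennal angles are the
tip-base direction relative to the head axis (perpendicular of the
base-joining line), in degrees — a convention that makes rotation
invariance exactly testable. Antennal periodicity uses 30-s windows (50%
overlap), flagging a window when the 0.1-5 Hz spectral peak exceeds 6x the
median in-band level; proboscis periodicity uses the rule that an event is
periodic iff its predecessor is less than 6 s earlier.

## Problem sizes and runtime

The acceptance suite and `scripts/acceptance.R` run at desk scale: 1-h
sessions (20 seeds for the staging ordering; 3 sessions for the five-class
forest), 0.5-h pose-only sessions (20 seeds for the PE pipeline), 200 null
simulations on a 15 x 40 grid for the permutation-test calibration and 50
full-grid (15 x 145) simulations for effect recovery, all with exhaustive
2^16 sign flips at n = 16 flies. These sizes are the package's choice of
test conditions; the statistical structure, not the scale, carries the
conclusions.

## Known limitations

* Epoch-level (not fly-grouped) splits can leak within-fly structure into
  held-out metrics; a fly-grouped mode would be the conservative variant
  for real multi-fly data.
* SMOTE before splitting (kept for procedural fidelity) slightly inflates
  held-out multiclass metrics.
* The bridge interpolation in `stitchHours()` removes boundary steps but
  not slow drifts between hours; the 0.5 Hz high-pass handles those.
* The HDF5 container described for raw-data interchange is replaced by a
  plain-text session directory (CSV tables + JSON sidecar).
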