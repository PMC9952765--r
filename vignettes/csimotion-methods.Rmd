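---
title: "Quantifying subtle hand motion from WiFi CSI: model, parameters and design choices"
author: "csimotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying subtle hand motion from WiFi CSI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csimotion)
```

## 1. The sensing model

A WiFi link reports, per packet, a complex channel estimate for each of
30 OFDM subcarriers on each transmit–receive antenna pair (up to 6
streams, 180 subcarriers, here at 5 GHz / 20 MHz bandwidth, sampled at
1000 Hz).  In the frequency domain `Y = H X + N`; the channel entry of
subcarrier *i* is `H(i) = |H(i)| e^{j ∠H(i)}`.  The environment
contributes a quasi-static multipath background; a hand moving near the
link perturbs one reflected path.  Writing the reflected path length as
`d(t) = |tx − p(t)| + |p(t) − rx|` for hand position `p(t)`, the channel
of subcarrier *i* (wavelength `λᵢ`) is modelled as

`H(t, i) = H_static(i) + g · exp(−j 2π d(t) / λᵢ)`.

Because `λ ≈ 6 cm` at 5 GHz, centimetre-scale motion sweeps the
reflected phase through full rotations and the *amplitude* `|H(t, i)|`
oscillates ("fringes").  Only displacement along the gradient of
`d(·)` — the normal of the Fresnel ellipse through the hand — changes
the path length to first order; motion tangential to the ellipse is
second-order and nearly invisible.  This directional effect is a
sub-wavelength property: at multi-wavelength displacement amplitudes
even the second-order tangential path change accumulates a fringe
fraction.  The package's directional tests therefore use a 2 cm
displacement, where the tangential/perpendicular variance ratio is
far below 1 %; at the 8–10 cm amplitudes typical of a tremor surrogate
the contrast is weaker (a few percent) though still large.

## 2. The pipeline, stage by stage

Given a basic signal matrix `P` (T × S, one column per subcarrier):

**Normalization.** `P′ = (P − mean)/sd` per column, population
(divide-by-T) convention.  At T = 20 000 the sample/population
distinction is immaterial, but one convention must be fixed for exact
tests.  A constant column is an error, not a silent NaN.

**Bandpass.** A third-order digital Butterworth bandpass, designed by
bilinear transform with frequency prewarping and normalized to
`a₀ = 1`.  Band presets: `[3, 6]` Hz for resting tremor (its
physiological band), `[1, 10]` Hz for finger tapping and the
ruler-vibration calibration motion.  The printed `b, a` coefficients
come straight from the design; *filtering*, however, runs as a cascade
of analytically derived second-order sections.  The reason is
numerical: these narrow bands put all six poles at `|z| ≈ 0.99–0.997`,
where a single sixth-order recursion loses about six significant
digits (linearity holds only to ~10⁻⁶).  Factoring the designed
polynomial is no better — clustered roots are hypersensitive — so the
biquads are built from the Butterworth prototype poles via the analog
band transform and bilinear map, which involves no root finding.  The
cascade is linear to ~10⁻¹³ and its gain independently reproduces the
design's leading numerator coefficient.

**Component selection.**  The filtered matrix is centred by column
(that is what "PCA" means; the stage is equivalently an SVD of the
centred matrix) and the projection scores `A vₖ` are the candidate
motion series.  The score with maximal variance — the leading
component, variance `σ₁²/T` — is selected, sign-flipped so its sample
skewness is nonnegative (crests point up; an SVD sign is arbitrary),
and z-score renormalized to give `V*′`.  Zero-variance columns are
dropped with a warning.  Multi-link captures are handled by simply
concatenating all links' subcarrier columns before the decomposition;
a per-link subcarrier pre-selection hook exists (off by default) for
experimenting with subcarrier screening.

**Segmentation.**  Short-time energy over a trailing window of
`N = 51` samples (rectangular by default, Hamming optional; the prefix
uses truncated windows rather than fabricated padding).  The active
bout is everything above `0.1 · max(E)`, with above-threshold runs
merged across short gaps and the longest merged run returned (one
active bout per trial).  The merge gap deserves a note: the energy of
an oscillation dips at every zero crossing, and at the 3 Hz lower band
edge those dips can stay below threshold for up to half a period
(~167 samples) — far longer than the energy window.  `segment_active`
therefore accepts a `merge_gap`; the pipeline passes one period of the
filter band's lower edge (`fs / f_l`), which cannot bridge the gap
between genuinely separate bouts of in-band motion but always bridges
intra-bout dips.  The default for direct calls remains `N`.

**Quantification.**  The segmented series is smoothed by a third-order
Savitzky–Golay filter, window 101 samples (0.1 s at 1000 Hz) — wide
enough to flatten noise ripple, narrow enough to preserve crests up to
~10 Hz; edge frames use the truncated-window polynomial fit, so cubics
are reproduced exactly everywhere.  Peaks must satisfy three criteria:

* separation ≥ `⌊fs / f_max⌋` samples (100 for tapping's 10 Hz cap,
  166 for tremor's 6 Hz cap at 1000 Hz);
* height ≥ `0.2 · max(Q)`;
* topographic prominence ≥ `0.3 · max(Q)` (height above the higher of
  the two flanking minima, walking out to the nearest higher sample or
  the series end).

When two candidates are closer than the separation, the higher one
wins (tie → earlier index), implemented greedily from the highest peak
down — and verified against an exhaustive oracle in the tests.

The **count** is the number of accepted peaks.  The **duration** is the
segment length.  The **mean frequency** is `(count − 1)` divided by the
time span between first and last peak: a fencepost convention that is
insensitive to slack in the segment boundaries, which is exactly where
threshold segmentation is least precise.  (`count / duration` is
available as an alternative convention.)  The ruler preset reports
frequency only: a ring-down decays below the detectable range, so an
end-of-motion time — hence a duration — is not meaningful.

## 3. The synthetic data generator

The simulator emulates the reference study conditions: 20 s recordings
at 1000 Hz × 180 subcarriers; the target stationary for the first 5 s,
moving from the 6th second for 10 s; motion 1 m from the midpoint of
the line of sight of a 2 m link in a 4.2 m × 7.9 m room.  Motion types
and defaults:

| motion | displacement | frequency | shape |
|---|---|---|---|
| ruler vibration | 10 cm initial | 3.46 Hz | damped sinusoid (damping 0.35 s⁻¹) |
| finger tapping | 8 cm | 1 Hz | raised-cosine pulse per tap |
| resting tremor | 9 cm | per-cycle U[3, 6] Hz | concatenated sine cycles |

The tremor surrogate draws a fresh frequency for every full cycle, so
its ground truth (`cycle_times`, per-cycle frequencies, count, active
duration, and the mean frequency under the same fencepost convention
the estimator uses) is known exactly.

Two fidelity modes:

* **geometric** (default): the Fresnel path-length model above, with
  per-subcarrier wavelengths spread over the 20 MHz band.  At 8–10 cm
  displacement it produces several amplitude fringes per motion cycle,
  as real captures do — realistic, but without a closed-form cycle ↔
  peak correspondence.
* **direct**: subcarrier amplitude follows the displacement directly
  (`baseline + depthᵢ · disp(t)/amp`, depths drawn once per subcarrier
  with random sign from U[0.3, 1] of the configured gain).  One crest
  per cycle, so count recovery has an exact expected answer.  With the
  default background gain 20 and complex noise sd 0.05, the weakest
  subcarrier's amplitude SNR is ≈ 12 dB.

Artifacts mirror the known field error modes: `inject_packet_loss`
replaces samples with the previously logged row (flat runs, detectable
as identical-row runs, which `detect_packet_loss` flags);
`inject_slow_response` ramps the motion component in and out at the
bout boundaries (the "two smaller waves" effect that can cost boundary
cycles).  `generate_reference_trace` produces the 200 Hz
accelerometer-style reference: the *analytic* per-cycle acceleration
plus absolute Gaussian sensor noise (default 0.05 m/s²).  A numeric
second difference is deliberately avoided: the surrogate displacement
has velocity jumps at cycle/bout boundaries, and differencing across
them manufactures delta spikes no physical accelerometer would record.

What the simulator does **not** model: furniture/wall ray tracing,
interfering people walking near the link, receiver gain drift, and any
absolute channel gains (the study's hardware gains are unknown free
parameters).  Consequently the package's end-to-end tests validate
*structural* claims — parameter recovery under known conditions,
artifact round trips, directional contrast — not the absolute room
accuracies of a physical deployment, which depend on the real channel.

## 4. Evaluation utilities

Accuracy is `100 − e` percent with
`e = (1/N) Σ |qᵢ − gᵢ| / gᵢ × 100 %` over repetitions (absolute values:
over- and under-counting must not cancel).  `quantify_reference` runs
the same smoothing and peak criteria on the reference trace at its own
rate (separation `⌊200/6⌋ = 33` samples; smoothing window scaled to the
same 0.1 s span, 21 samples).  `fit_accuracy_vs_distance` is ordinary
least squares with R² computed from residuals (defined as 0 for a
constant response).  `build_accuracy_contour` interpolates a gridded
room survey bilinearly, reflects it across the Fresnel symmetry axis
(the centreline of the line of sight), reports validation-point
discrepancies against the mirrored prediction, and refuses to
extrapolate outside the measured rectangle (missing, not guessed).

## 5. Numerical conventions and degenerate inputs

* Phase wrapping: `(−π, π]`; the boundary maps to `+π`.
* Phase sanitization: per time step and antenna stream, the
  least-squares linear trend of unwrapped phase across subcarrier index
  plus the mean offset is removed — the standard cleanup for carrier
  and sampling frequency offset.  Raw phase is available.
* CSI-ratio denominators below `10⁻⁶ ×` the median denominator
  amplitude are imputed from the nearest valid time step of the same
  subcarrier and counted in a message.
* Zero-magnitude samples get phase 0 (reported, not fatal).
* Segment indices are 1-based inclusive; durations are
  `(end − start + 1)/fs`.
* All simulator randomness is governed by the scene seed; a fixed seed
  reproduces recordings bit for bit.

## 6. Problem sizes used by the test suite

The suite exercises full-size single recordings (20 s × 1000 Hz × 180
subcarriers) where the claim concerns the study conditions — notably a
20-seed tremor parameter-recovery sweep in the acceptance tests — and
reduced sizes (30–60 subcarriers, 2–10 s) for structural unit checks,
which keeps the default run around a minute while covering every
operation against an independent oracle.

## 7. Known limitations

* No parser for vendor capture formats (e.g. the Intel 5300 tool's
  `.dat`); captures must be converted to the documented CSV/JSON or
  binary container first.
* Single active bout per recording by default (the multi-bout flag
  returns all merged runs but downstream quantification is per-bout).
* Tremor *amplitude* in centimetres is not estimated — multipath gain
  ambiguity makes displacement magnitude unidentifiable from a single
  link's amplitude — and no clinical severity score is produced.
* Streaming/online operation is out of scope; recordings are processed
  as blocks.
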