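# csimotion

Contactless quantification of subtle hand motion from WiFi channel state
information (CSI).

Movement disorders such as Parkinson's disease show themselves in subtle,
fluctuating motor signs — a 3–6 Hz resting tremor of the hand, slowed
~1 Hz finger tapping — that a short clinical visit can easily miss.
Commodity WiFi hardware exposes, for every OFDM subcarrier of every
transmit–receive antenna pair, a complex channel estimate `H(i)`; a hand
oscillating near the link perturbs the reflected propagation path and
modulates those estimates.  `csimotion` turns a 20 s CSI capture (time ×
subcarrier complex matrix) into the **count**, **mean frequency** (Hz)
and **duration** (s) of the motion, with no wearable and no camera.  It
is aimed at researchers in wireless sensing and tele-health who want a
complete, testable implementation of the method plus a simulator to
exercise it without radio hardware.

## The method

With `Y = H X + N` (received signal, channel matrix, transmitted signal,
additive white Gaussian noise), each subcarrier contributes
`H(i) = |H(i)| e^{j∠H(i)}`.  From a basic signal `P` (per-subcarrier
amplitude by default; sanitized phase, inter-antenna phase difference
and amplitude ratio are also supported) the pipeline runs:

1. **Z-score normalization** — `P′ = (P − mean(P)) / sd(P)` per
   subcarrier column;
2. **Butterworth bandpass** — third-order digital design `G(z) = Σ bᵢ z⁻ⁱ / Σ aᵢ z⁻ⁱ`
   via the bilinear transform; `[3, 6]` Hz for resting tremor,
   `[1, 10]` Hz for tapping and ruler vibration; `A(z) = P′(z) G(z)`;
3. **Component selection** — SVD `A = U Σ Vᵀ` of the centred matrix;
   the projection score with the largest variance becomes the single
   motion series `V*′` (renormalized);
4. **Segmentation** — short-time energy
   `Eₙ = Σ_{m=n−N+1}^{n} [V*′(m) w(n−m)]²` with `N = 51`, thresholded at
   10 % of its maximum, isolates the active bout `V_W`;
5. **Quantification** — Savitzky–Golay smoothing (order 3, window 101)
   gives `Q`; peaks are counted under three criteria: minimum separation
   `⌊fs/f_max⌋` samples, minimum height `0.2 max(Q)`, minimum prominence
   `0.3 max(Q)`.  Count, mean frequency `(count − 1)/(peak span)` and
   bout duration follow.

A Fresnel-zone channel simulator (`scene_config()`, `motion_profile()`,
`synthesize_csi()`) generates recordings with known ground truth —
including packet-loss runs and slow-response artifacts — and a 200 Hz
accelerometer-style reference trace.  Evaluation helpers implement the
mean absolute relative error `e = (1/N) Σ |qᵢ − gᵢ|/gᵢ × 100 %`
(accuracy `100 − e`), an OLS accuracy-vs-distance fit, and interpolated
accuracy contours mirrored across the Fresnel-zone symmetry axis.

## Worked example

```r
library(csimotion)

prof <- motion_profile("resting_tremor")            # 3-6 Hz, 5-15 s active
scn  <- scene_config(noise_sd = 0.05, seed = 42)    # 20 s, 1000 Hz, 180 subcarriers
rec  <- synthesize_csi(scn, prof, mode = "direct")
rec$meta$ground_truth[c("true_count", "true_mean_frequency", "true_duration")]
#> $true_count          [1] 45
#> $true_mean_frequency [1] 4.529029
#> $true_duration       [1] 10

res <- quantify_recording(rec, "resting_tremor")
res
#> <pipeline_result> resting_tremor / amplitude
#> <motion_quantification> count = 44, mean frequency = 4.502 Hz, duration = 9.912 s
#> <motion_segment> [5252, 15163] (9.912 s @ 1000 Hz)
```

The pipeline recovers 44 of the 45 simulated tremor cycles, the mean
tremor frequency within 0.03 Hz, and the 10 s active bout within 0.1 s.
Comparing against the simulated wearable reference, as the method's
accuracy metric prescribes:

```r
ref <- generate_reference_trace(prof, duration = 20, seed = 42)
qr  <- quantify_reference(ref, f_max = 6)
error_percentage(res$quantification$mean_frequency, qr$mean_frequency)
#> <accuracy_report> n = 1, error = 0.29%, accuracy = 99.71%
```

A thin command-line front end (`inst/cli/csimotion.R`) wraps the same
functions as `simulate`, `design-filter`, `quantify`, `evaluate` and
`contour` subcommands.

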