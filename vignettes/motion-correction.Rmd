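---
title: "Wavelet-domain motion correction of fNIRS with thermal video tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-domain motion correction of fNIRS with thermal video tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(nirsmotion)
```

## The problem

An fNIRS channel measures light attenuation between a source and a
detector optode resting on the scalp. When the head moves, the optode
couples differently to the skin and the signal acquires two kinds of
artifact: brief high-amplitude spikes while the optode is in motion, and
persistent baseline shifts when it settles at a new position. Both
overlap spectrally with the haemodynamic response, so plain band-pass
filtering cannot separate them. `nirsmotion` removes them using an
*independent, contactless* measurement of optode motion obtained from a
thermal-infrared video of the participant's face.

## Tracking the optodes in thermal video

The tracker follows a fixed template — the rectangular master ROI (mROI)
cropped from the first frame over a detector — through the video:

1. **Skin segmentation.** Each frame is thresholded by Otsu's method on a
   256-bin histogram; facial skin is several degrees warmer than the
   background, so the upper class is the face. The correlation search is
   restricted to placements centred on skin, which both speeds the search
   and suppresses spurious background matches.
2. **Pyramid decimation.** Frame and template are decimated through a
   Gaussian pyramid (5-tap binomial filter, factor-2 subsampling per
   level). At the default level 1 a 240×320 frame becomes 120×160.
   Matching happens at the decimated resolution and centres are rescaled
   by 2^level, so positional accuracy is inherently quantized to
   2^level px; no sub-pixel refinement is attempted.
3. **Frequency-domain NCC.** The normalized cross-correlation of the
   template against every placement is computed with FFTs for the
   numerator and running (integral-image) sums for the local
   normalization. The maximum γ over admissible placements is the match
   quality.
4. **The γ gate.** Frames with γ ≤ γ_th are discarded and reported as
   NaN; tracking resumes when γ exceeds the threshold again. The default
   γ_th = 0.995 is deliberately strict — occlusions and out-of-plane
   rotations must not contaminate the motion estimate — and is exposed as
   a parameter because it was calibrated for a particular camera class.
   The template is never updated: re-finding the frame-0 crop avoids the
   cumulative drift of adaptive templates.

Slave ROIs (the sources) translate rigidly with the mROI. The resultant
motion is the Euclidean norm of the centre displacement relative to the
first retained frame; NaN gaps are linearly interpolated (and flagged),
because the wavelet transform downstream requires gap-free input.

Two tracker properties worth knowing. Otsu segmentation is applied to the
*decimated* frame, consistent with the speed motivation for decimating in
the first place. And the search is global over the skin region rather
than restricted to a neighbourhood of the last position: a strict γ gate
makes false distant matches unlikely, and a global search recovers
immediately after long occlusions.

## The time–frequency exclusion procedure

Let `x(t)` be a channel and `m(t)` the resultant motion of its detector,
at the same rate. Three objects are computed:

* the CWT of `x` with the analytic generalized Morse wavelet with
  symmetry γ_m = 3 and time–bandwidth product P² = β_m·γ_m = 60
  (so β_m = 20) — a narrowband, highly frequency-selective analytic
  wavelet suited to isolating transients;
* the CWT of `m`, with magnitude normalized by its global maximum so it
  is commensurate with coherence;
* the Morlet (ω₀ = 6) magnitude-squared wavelet coherence `C(s,t)`
  between `x` and `m`, smoothed by a Gaussian in time (SD equal to the
  scale) and a ~0.6-octave boxcar across scales.

A cell `(s,t)` is attributed to motion when **both** the normalized
motion magnitude and the coherence exceed the threshold `T` (default
0.6). The intersection rule is a deliberate design choice where the
natural-language description ("a threshold of the CWT and WCOH") is
ambiguous: requiring *both* motion energy and signal–motion coherence is
the more specific rule and protects the haemodynamic band; the union rule
is available via `correction_config(combine_rule = "union")`, and in our
simulations masks 3–10× more cells for a modest additional MSE gain.

The corrected signal subtracts the inverse CWT of the *flagged cells
only*:

    x_corrected(t) = x(t) − ICWT[ W_x · mask ](t)

rather than being the inverse transform of the retained cells. The two
differ by the transform's null space: a finite logarithmic scale grid
spanning [2/T_rec, fs/2] Hz cannot represent drift slower than its lowest
scale, the broadband noise floor, or boundary residue, and a literal
retained-cell reconstruction would silently discard them (~40% relative
RMSE on realistic resting signals). With the subtraction form an empty
mask is an exact identity, which is the behaviour the specificity
requirement demands: channels with no motion must pass through unchanged.

### Numerical choices

* **Scale grid**: logarithmic from fs/2 down to 2 cycles per record, 12
  voices/octave. Twelve voices suffice here: reconstruction amplitude
  ripple across grid phases is below 1%.
* **Padding**: zero-padding to the next power of two at least twice the
  signal length. Reflection padding was measured *worse* on band-limited
  signals (boundary phase mismatch), so plain zero-padding after mean
  removal is used.
* **Inverse transform**: single-integral (Morlet-style) reconstruction;
  the admissibility constant has the closed form a·Γ(β_m/γ_m)/γ_m for
  the Morse window with peak amplitude a, so no per-call calibration is
  needed. A unit sinusoid round-trips within 1% amplitude.
* **Grid congruence**: the coherence is computed with Morlet scales
  chosen so its centre frequencies coincide exactly with the Morse grid —
  masks compose cell-by-cell with no resampling.
* **Cone of influence** is recorded (frequency below which a coefficient
  is edge-affected, using the Gaussian-equivalent time spread
  √(β_m·γ_m)/ω_peak) but masked and unmasked cells are treated the same
  inside and outside it.
* **Degenerate inputs**: an all-zero motion trace yields an empty mask by
  definition (nothing to exclude); constant motion has undefined
  coherence and is likewise treated as no evidence of artifact; NaN in
  any CWT input is rejected — gap-filling is the tracker's job, and
  interpolated spans are flagged for audit.

## The simulation benchmark

Real validation recordings for this class of method are not publicly
deposited, so the package ships a ground-truthed generator that emulates
the validation design: simulated activations added to motion-corrupted
resting-state signals.

* **Resting physiology**: per channel, sinusoids at the cardiac
  (~1.1 Hz), respiratory (~0.25 Hz) and Mayer (~0.1 Hz) bands with random
  phases, a slow drift (0.008 Hz), and white noise — amplitudes 0.3, 0.2,
  0.4, 0.3, 0.1 signal units. These are plausible relative magnitudes for
  ΔOD-scale data; the absolute scale is irrelevant because SNR is
  scale-invariant.
* **Paradigm**: 20 s task / 20 s rest over 5 minutes at 10 Hz, the
  standard block design at these recording lengths.
* **HRF**: SPM-style double gamma (peak ≈ 5–6 s, undershoot ≈ 16 s,
  ratio 1/6), peak-normalized. The convolved regressor is normalized to
  unit peak so the injected amplitude *is* the GLM β in signal units.
  The injected amplitude (default 0.5) is exposed as a parameter: the
  realistic activation-to-noise ratio is genuinely study-dependent.
* **Motion**: 8 spike events (Gaussian displacement pulses, SD 0.5 s) and
  2 shift events (sigmoidal steps) at random times, 2–8 px each —
  displacement scales consistent with small head movements at typical
  camera geometry. Artifacts are linear in the displacement at the event
  time with independent per-channel gains (0.4–1.6, random event sign),
  so some channels are barely corrupted and others heavily — movements
  need not corrupt all channels equally.
* **Subjects** are independent seeded replicates (default 16, the usual
  cohort size for such validations) of 8 channels over 2 detectors.

What the generator does *not* emulate: serial correlation of real
physiological noise beyond the sinusoid-plus-noise structure, nonlinear
coupling between motion and optics, out-of-plane rotation (which in
reality depresses γ; occlusion frames emulate the γ-drop instead), and
source-only movement — which the method cannot correct by construction,
since motion is tracked at the detectors.

Consequently, passing benchmarks demonstrate that the machinery removes
motion-coupled content it was designed for and leaves clean signal alone;
they do not establish performance margins on human data.

### Scoring

Each channel is fitted by OLS on `[HRF⊗boxcar, intercept]`; SNR is
β/σ_rest with σ_rest the SD over rest samples; MSE is against the clean
ground truth over the whole series (activation-epoch-only MSE is a
config option). Method comparisons average replicates within channel and
then run paired t tests across the 8 channels (df = 7) — paired over
channels, never pooled.

One caveat is documented rather than hidden: with the full generator the
slow drift component partially correlates with the block regressor, so
OLS confidence intervals under-cover (β within ±3 SE in ~80% rather than
95% of replicates). This is the textbook behaviour of single-regressor
GLMs on autocorrelated noise, not an artifact of the implementation; the
coverage property is therefore verified under white noise, where OLS
standard errors are exact.

### Threshold choice

Sweeping T over {0.4, 0.5, 0.6, 0.7, 0.8} on the default benchmark:
lower thresholds mask more cells and minimize MSE; SNR peaks in the
0.6–0.7 region (the maximizer moves between adjacent grid points with
the replicate set). The package default stays at 0.6 — the value chosen
in the validation study this design follows — and both the threshold and
per-map thresholds are exposed in `correction_config()`.

## Known limitations

* Detector-side tracking only: if a source moves while its detector is
  still, the artifact is invisible to the motion trace.
* Translation-only template matching: rotation and scale changes lower γ
  and discard frames rather than being tracked.
* Displacement accuracy is ±2^level px; at level 1, sub-2 px motion is
  invisible to the tracker (though the correction accepts any externally
  supplied trace at full resolution).
* The γ_th = 0.995 gate is camera-calibrated; for noisier sensors it will
  discard aggressively and should be lowered deliberately.

## Problem sizes used in the shipped tests

Module tests run on 60–300-sample-per-second-scale signals (1–5 minutes)
and 120×160 to 240×320 frames; the end-to-end checks use 56–128
simulated channels (7–16 replicates of 8 channels) and the full
300-frame tracking sequence — sizes at which every property asserted is
stable across seeds while the whole suite stays fast.
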