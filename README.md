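# nirsmotion

Motion artifacts are the dominant nuisance in functional near-infrared
spectroscopy (fNIRS): head movements displace the optodes, injecting
high-frequency spikes and persistent baseline shifts into the optical
signal that masquerade as, or bury, the haemodynamic response.
`nirsmotion` implements a *contactless* correction pipeline for
researchers running fNIRS experiments alongside a thermal-infrared camera:
the optode displacement is measured from the thermal video itself — no
accelerometer, no short-separation channel — and used to excise
motion-related time–frequency content from the fNIRS series.

## Method

**Tracking.** A rectangular master ROI (mROI) is selected over a detector
on the first thermal frame. Every frame is segmented into skin/background
by Otsu's method, decimated through a level-1 Gaussian pyramid
(240×320 → 120×160), and the template is located by normalized
cross-correlation computed in the frequency domain, searching only
placements centred on skin. The per-frame correlation maximum γ is a
goodness index: frames with γ ≤ γ_th (default 0.995) are discarded (NaN)
and linearly interpolated afterwards. Elliptical slave ROIs (the sources)
translate rigidly with the mROI. The (row, col) displacement relative to
the first retained frame is reduced to the resultant motion
*m(t) = ‖(Δrow, Δcol)‖* in pixels.

**Correction.** With `x(t)` a channel and `m(t)` its detector's motion:

- `W_x(s,t)` — continuous wavelet transform of `x` with the analytic
  generalized Morse wavelet (symmetry γ_m = 3, time–bandwidth product
  β_m·γ_m = 60), 12 voices/octave;
- `W_m(s,t)` — same transform of the motion vector, magnitude normalized
  to its global maximum;
- `C(s,t)` — Morlet (ω₀ = 6) wavelet coherence between `x` and `m`,
  smoothed per the usual time–scale convention, in [0, 1].

A time–frequency cell is flagged when `|W_m|/max|W_m| > T` **and**
`C > T` (default `T = 0.6`, swept over {0.4, …, 0.8}); the inverse CWT of
the flagged cells — the motion-attributable content — is subtracted from
the signal. Cells failing either condition, and content outside the
transform's band, pass through untouched.

**Validation.** Following the simulation design used to validate such
correctors: canonical double-gamma HRFs convolved with a 20 s on / 20 s
off boxcar are added to (synthetic) resting-state recordings corrupted by
motion-coupled spike and shift artifacts; each channel is scored by a GLM
with the HRF⊗boxcar regressor, `SNR = β/σ_rest` (σ_rest = SD over rest
samples) and MSE against the clean ground truth; methods are compared by
paired t tests across channels after averaging replicates. Four reference
correctors are included: wavelet-IQR, PCA, spline (MARA-style) and CBSI.

## Worked example

```r
library(nirsmotion)

# synthetic thermal video with a known trajectory and 5 occluded frames
set.seed(1)
traj <- cbind(c(0, cumsum(2 * sample(-1:1, 299, TRUE))), 0)
traj <- pmax(pmin(traj, 20), -20)
sv  <- synth_thermal_video(300, c(240, 320), traj,
                           occlusion_frames = c(50, 51, 120, 200, 260))
roi <- roi_spec(sv$truth$optode_centers[[1]][1, ], 30, 40)
tr  <- track_mroi(sv$video, roi)
tr
#> Track result: 300 frames, 5 discarded (gamma_th = 0.995)
#>   gamma: min 0.9891, median 1.0000, max 1.0000

# benchmark: 7 subjects x 8 channels, spike+shift artifacts, HRF blocks
cfg <- benchmark_config(n_replicates = 7, seed = 501)
b0  <- run_benchmark(cfg, "none")
b1  <- run_benchmark(cfg, "proposed", threshold = 0.6)
mean(b1$mse < b0$mse)        # fraction of channels closer to ground truth
#> [1] 0.9821429
c(mean(b0$snr), mean(b1$snr))  # SNR = beta / sigma_rest, before / after
#> [1] 0.5126 0.5288
```

The five discarded frames are exactly the occluded ones — the γ gate
rejects frames where the template is not visible, and the trace is
interpolated across them. On this benchmark 98% of channels move closer
to the clean ground truth and the mean GLM-based SNR increases (the
margin varies with the replicate set; the full 16-replicate run in
`scripts/acceptance.R` shows the stable picture).

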