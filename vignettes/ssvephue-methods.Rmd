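---
title: "Hue tuning of SSVEPs: models, extraction and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hue tuning of SSVEPs: models, extraction and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvephue)
```

## The measurement

A flickering isoluminant checkerboard drives a steady-state visual evoked
potential (SSVEP) at the 5 Hz flicker rate. While the pattern flickers, its
hue sweeps smoothly around a hue circle defined in a cone-contrast color
space: axes are the L–M opponent contrast ΔL/L and the S-opponent contrast
ΔS/S, scaled 1:10 (full-contrast maxima 8% and 80%), so that hue angle θ is
the azimuth in the axis-normalized plane with 0° = +L ("red") and
90° = +S ("lavender"). One hue cycle takes 24 s (15°/s); hue advances 3° at
each 100 ms "on" phase and holds during the 100 ms "off" phase, so each of
the 24 fifteen-degree hue sectors receives exactly 5 on-phases per cycle. A
trial lasts 25 s and always starts with an on phase; trials run clockwise or
counterclockwise from counterbalanced start sectors so that slow adaptation
and response lag cancel in the average.

The scientific question is whether the amplitude of the 5 Hz response, as a
function of hue, is line-symmetric about the cardinal (cone-opponent) axes —
as it must be if the cortical response is just a combination of the two
cone-opponent channel outputs — or whether it is tilted into the
intermediate ("lime–magenta") directions, implying hue representations that
are not inherited unchanged from the cone-opponent input.

## Extraction pipeline

Per participant and condition the pipeline is:

1. **Epoching.** Each 25 s trial is cut on 1 s boundaries into 25 epochs of
   250 samples (250 Hz); the first epoch is discarded so the SSVEP can
   stabilize, and the remaining 24 cover each hue sector exactly once. Each
   epoch is labeled with its sector via the trial's start sector and sweep
   direction.
2. **Detrending.** A linear trend is removed per channel and epoch. The
   trend is estimated on the five 200 ms flicker-cycle means of the epoch
   rather than on raw samples: this makes the removed line exactly
   orthogonal to the 5 Hz component and its harmonics. (A naive per-sample
   least-squares line absorbs up to ~2.4% of a 5 Hz sinusoid, with the loss
   depending on the response phase — a bias that would survive averaging.)
3. **Artifact rejection.** An epoch is flagged when any channel's
   peak-to-peak amplitude exceeds 100 µV (automated counterpart of manual
   blink/saccade rejection). The synthetic generator's default blink rate is
   calibrated so about 9% of epochs are rejected.
4. **Re-referencing and channel selection.** The mean across EEG channels is
   subtracted (average reference) and the occipital channel Iz — where the
   SSVEP is maximal — is analysed. The channel with the largest mean 5 Hz
   amplitude is reported as a diagnostic.
5. **Sector averaging and reconstruction.** Retained epochs of the same
   sector are averaged and the 24 sector means concatenated in sweep order
   into one 24 s, 6000-sample signal. Because 5 Hz completes an integer
   number of cycles per second, the carrier is continuous across the seams.
   Each sample is assigned a continuously advancing hue (15°/s), shifted by
   −1.5° (half the 3° on-phase step) so the labels are centered on the hue
   staircase actually displayed; without this both directions share a +1.5°
   hue bias that appears as a ~1.4° orientation bias in fitted ellipses.
6. **Gabor transform.** The reconstruction is circularly convolved with a
   complex Gabor of center frequency 5 Hz and frequency-domain SD
   σ_f = 0.25 Hz, unit gain at 5 Hz (time-envelope SD 1/(2πσ_f) ≈ 637 ms).
   Circular convolution is appropriate because hue is periodic, so the
   reconstruction has no edges. At the 15°/s sweep rate the filter's
   half-width at half maximum corresponds to ≈11° of hue.
7. **Amplitude and latency.** The amplitude profile is the modulus of the
   Gabor output. The phase φ, measured against the stimulation cycle
   (carrier demodulated), converts to latency by L = −(φ − π/2)/(2πf): one
   2π cycle spans 200 ms at 5 Hz, and latencies are unwrapped into
   [0, 200) ms — observed values near 88–130 ms fit comfortably in one
   cycle. The π/2 offset accounts for the phase of stimulation.
8. **Normalization and averaging.** Each participant's amplitudes are
   divided by one scalar — the mean over all samples of all three contrast
   conditions and both directions — so overall gain differences between
   participants cancel; directions are averaged on the shared hue grid and
   the grand mean across participants is formed.

### Gaussian convention for the Gabor envelope

With σ_f = 0.25 Hz the standard reciprocal convention gives a time-envelope
SD of 1/(2πσ_f) ≈ 636.6 ms and a half-FWHM of ≈ 749.6 ms. The package
adopts this standard convention throughout. The commonly quoted half-width
±735.5 ms corresponds to a slightly different windowing convention; the
hue-resolution arithmetic (±735.5 ms × 15°/s ≈ ±11°) is reproduced from
that printed value as an input, not from the filter implementation.

## The synthetic EEG generator

`simulate_trial()` embeds at every scalp channel a 5 Hz sinusoid

  gain_c · A(θ(t)) · cos(2π·5·t + φ(t)),  φ(t) = π/2 − 2π·5·Lat(θ(t))/1000,

where θ(t) is the schedule's current (per-on-phase) hue and A and Lat are
elliptical tuning profiles (`make_tuning_profile()`). The phase convention
is fixed so that the extraction's latency formula returns the generating
latency exactly — the stimulation-phase offset is absorbed into the
generator. The response is a continuous sinusoid for the whole trial: the
100 ms on/off flicker is the *cause* of the 5 Hz response, not an amplitude
gate on it (gating the carrier with its own square envelope would rescale
and phase-shift the 5 Hz component). The carrier is a pure sinusoid without
harmonics because the analysis only reads the 5 Hz component and observed
harmonics are minor.

On top of the signal the generator adds per-channel 1/f (pink) background
noise (default SD 8 µV) and blink-like half-sine deflections (default
300 µV, 350 ms) on the EOG and frontopolar channels in randomly chosen
1 s epochs. The default blink probability of 0.09 per epoch, with the
100 µV rejection threshold, produces rejection rates close to the 9% the
recording conditions are meant to emulate. The default per-contrast source
gains are spaced so that 5 Hz amplitude is linear in log contrast, and the
default amplitude/latency ellipses follow the grand-mean study values
(amplitude orientations 15.6/18.8/28.3° with modest aspect ratios; latency
ellipses near 82° with radii (129, 109), (113, 99), (103, 88) ms).

What the generator does **not** emulate: volume conduction and realistic
channel covariance, eye-movement dynamics, pattern-reversal harmonics,
task-related 1 Hz transients (off by default), non-stationary alpha, or
hue-correlated noise. Passing round-trip tests therefore demonstrates the
correctness of the signal-processing chain, not robustness to every
property of real recordings.

## Ellipse fitting and bootstrap

Amplitude and latency profiles are summarized by ellipses in polar form,
r(θ) = ab / √((b cos(θ−ψ))² + (a sin(θ−ψ))²), with axial orientation ψ
(mod 180°) and semi-axes a ≥ b. Fitting uses the numerically stable direct
least-squares conic algorithm (scatter-matrix block elimination with the
4AC − B² = 1 ellipse constraint). Two variants are provided: the full
6-parameter conic (center reported as a diagnostic) and a 4-parameter
origin-centered fit. Profile fits default to the centered variant — polar
tuning profiles are origin-centered by construction, and with a free center
low-order noise harmonics masquerade as large center offsets, destabilizing
near-circular fits. A perfect circle reports ψ = 0 by convention. The fit
is verified in the tests against a brute-force geometric grid search over
(ψ, aspect) with closed-form optimal scale.

Confidence intervals resample **participants** with replacement (B = 2000),
refitting the ellipse to each resampled grand mean; ψ is axial, so means
and percentile intervals are computed on the doubled-angle circle.

When recovering *generator ground truth* (round-trip suites), the extracted
profile is first corrected for the filter's known hue smoothing:
`deconvolve_profile()` divides hue harmonic k by exp(−(k/24)²/(2σ_f²)) (the
elliptical second harmonic is attenuated by ~5%, which would bias a
generating aspect ratio of 2.0 down to ~1.91). Harmonics whose gain falls
below 5% are left untouched to avoid noise amplification. The correction is
**not** applied when reporting profiles on the measurement's own terms,
which is how the study-style outputs are produced.

## The five hue-tuning models

The model comparison explains the "purely chromatic" response — the
pointwise difference between the full- and quarter-contrast amplitude
profiles — with five candidates:

| model | prediction | free parameters | k |
|---|---|---|---|
| M1 cardinal vector-sum | √((aL cos θ)² + (aS sin θ)²) | aL, aS | 2 |
| M2 cardinal scalar-sum | \|aL cos θ\| + \|aS sin θ\| | aL, aS | 2 |
| M3 perceptual | gain × fixed Munsell iso-Chroma ellipse (ψ = 61.03°, aspect 2.05), unit mean | gain | 1 |
| M4 mixed | gain × (ω·Pn + (1−ω)·C1n(aspect)) | gain, ω, aspect | 4 |
| M5 mixed | gain × (ω·Pn + (1−ω)·C2n(aspect)) | gain, ω, aspect | 4 |

The scalar-sum uses rectified cosines so predictions are nonnegative in all
quadrants and symmetric about both cardinal axes — by construction M1 and
M2 are line-symmetric about the cardinal axes for any parameters, which is
exactly the property an obliquely tilted profile violates. In the mixed
models both components are normalized to unit mean over the hue circle
before mixing, which makes the perceptual weight ω identifiable against the
overall gain; the cardinal component's rotation is fixed at 0 (its axes
*are* the cardinal axes), and the parameter count k = 4 follows the
published model table's convention for these models even though three
parameters are numerically free. The perceptual shape's constants
(61.03°, 2.05) are built in; `munsell_ellipse()` recomputes them from
reflectance spectra and cone fundamentals when such data are supplied.

Fitting is bounded Levenberg–Marquardt least squares with ≥8 multi-starts
(deterministic jitter from a seed; ω starts uniform in [0, 1]); the
perceptual model's single gain has a closed form. Goodness of fit is
100·(1 − RSS/TSS) with TSS about the profile mean. Models are ranked by
AIC = n·ln(RSS/n) + 2k with n the number of profile samples (6000 for the
full grid); ties break toward lower RSS, then lower k. A zero RSS yields
−∞ with a warning rather than an error, so noiseless self-recovery tests
can still rank models.

### Identifiability checks

The model-recovery suite generates profiles from each model at parameters
like the published fits, perturbed by iid Gaussian noise scaled so the
generating model's goodness of fit is ≈94%, and requires the generating
model to win the AIC comparison in ≥90% of 100 seeded runs. The iid
assumption matches AIC's likelihood approximation at n = 6000; residuals of
real grand-mean profiles are hue-correlated (the Gabor filter smooths over
≈11°), for which n = 6000 overstates the effective sample size — a known
limitation of the AIC convention adopted here, shared by the procedure it
reimplements.

## Problem sizes and numerical choices

- Cohort sizes: the full published design is 16 participants × 4 sessions ×
  36 trials. The analysis drivers default to 6 × 2 × 36 and the test suite
  to 2 × 1 × 36 — sizes chosen so a complete run stays in the minutes range
  while every sector still receives several retained epochs per condition.
  An empty sector (all epochs rejected) raises an error naming the sector.
- Noiseless round trips use single trials per direction; pointwise recovery
  of A(θ) is within 2% and of Lat(θ) within 2 ms, and generating ellipse
  parameters are recovered within 2°/2% across orientations 0–170° and
  aspect ratios up to 2.0 (after kernel correction, see above).
- Degenerate inputs: ellipse fits require ≥6 distinct non-collinear points;
  collinear input and non-elliptical eigen-solutions raise errors; hue of
  the achromatic origin is an error; `normalize_and_average()` refuses a
  zero overall mean.
- Determinism: every stochastic step (trial noise, blink placement, design
  shuffles, bootstrap draws, multi-start jitter) derives from an explicit
  seed; rerunning the pipeline with the same configuration is byte-identical.

## Known limitations

- The generator's channel model is a gain vector, not a head model; scalp
  topography is only qualitatively occipital.
- Latency is defined modulo the 200 ms stimulation cycle; absolute latencies
  differing by full cycles are indistinguishable, as in any steady-state
  phase measure.
- The perceptual model's shape is fixed by two constants unless reflectance
  spectra are supplied; the packaged constants are not recomputed from
  spectral data at build time.
- Bootstrap CIs treat participants as the only resampling unit; trial-level
  variability enters only through the participant means.
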