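---
title: "Multi-vital sensing from a single MWIR thermal camera: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-vital sensing from a single MWIR thermal camera: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwirvitals)
```

## The measurement problem

A mid-wave infrared (MWIR, 3–5 µm) thermal camera sees two things an
ordinary long-wave camera does not. First, the MWIR band contains the
~4.3 µm absorption band of CO₂, so the CO₂-rich plume of exhaled breath
absorbs the radiation emitted by the warm face behind it and appears as a
faint *dark* flow in front of the nostrils. Second, cooled InSb MWIR
sensors resolve milli-kelvin temperature differences (noise-equivalent
temperature difference around 18 mK), enough to see the tiny skin
temperature oscillation that pulsatile blood flow produces at the inner
canthus — the inner corner of the eye, which is also the ISO-recommended
site for screening thermometry because it tracks core temperature.

Together these make a single frontal MWIR recording sufficient for four
quantities: respiratory rate (from the visualized breath), heart rate
(from the canthus temperature oscillation), body temperature (from the
canthus mean temperature) and an estimate of exhaled airflow velocity and
CO₂ output (from the motion of the visualized plume). This package
implements that full chain plus the agreement statistics used to compare
any of these estimates against a reference method, and a synthetic
phantom generator so every stage can be validated with known ground
truth.

## Breath visualization

The plume contrast is small against the static facial background, so each
frame is reduced by the pixel-wise temporal mean of the stack
(`mean_subtract()`). Static structure cancels exactly; what remains is
the transient absorption. The temporal mean of the output is the zero
image up to floating-point error — a property the tests check on random
stacks. A sliding-window variant exists for drifting scenes but is off by
default; the global mean is the reference behaviour. Display scaling
(`normalize_for_display()`) uses *global* percentiles over the whole
stack: per-frame scaling would re-normalize every frame and destroy the
respiratory modulation one wants to see.

## Rate estimation

A rectangular ROI placed over the visualized exhalation (or over each
nostril in a long-wave reference recording) is averaged per frame
(`extract_roi_signal()`); the MWIR trace is negated (`invert()`) so that
exhalation, which darkens the image, can be counted with an ordinary peak
detector. The trace is band-limited with a second-order Butterworth
filter applied forward and backward (`bandpass()`): zero phase shift, at
the price of a doubled effective order and edge transients. Because the
passband excludes DC, the signal mean is removed before filtering — a
large offset would otherwise excite a long boundary transient in the
forward–backward pass. Default bands are 0.1–0.4 Hz for respiration and
0.8–1.5 Hz for the resting pulse.

Two estimators are provided:

* **Time domain** (`rate_from_intervals()`): mean peak-to-peak interval,
  converted to events per minute as 60 / mean interval. Peaks are strict
  local maxima with a topographic-prominence floor and a minimum
  separation; the first and last 2 s are excluded from peak counting
  because zero-phase filtering concentrates its artefacts there. The
  prominence floor defaults to 0.3 × the interquartile range of the
  filtered trace: scale-free, so the same setting serves milli-kelvin
  canthus signals and unit-amplitude PPG. Ties on a plateau resolve to
  the first sample; candidate acceptance under the separation constraint
  is greedy in order of decreasing height. All choices are deterministic.
* **Frequency domain** (`rate_from_spectrum()`): the magnitude-spectrum
  peak over the band, using raw FFT bins with no zero padding or
  interpolation, so the resolution is 1/duration — 0.025 Hz (1.5
  events/min) for a 40-s record. Spectral ties resolve to the lowest
  frequency. This estimator is kept deliberately plain so its resolution
  limit is explicit; the time-domain path is the more accurate of the
  two, which the phantom recovery results reproduce.

Breath-by-breath morphology is supported by `segment_cycles()` (anchors
at the troughs of the exhale-positive signal, i.e. the start of
expiration) and `normalize_cycles()`, which resamples each cycle to a
fixed length, min–max scales it, and reports the per-point mean and SD
across cycles.

## Thermometry and the pulse signal

The measurement area is found by thresholding the temporal-mean image
(`segment_hottest()`): the inner canthi nearly coincide with the hottest
regions of a frontal face image. Components are labelled with
8-connectivity, those below 4 px are dropped, and the two largest are
kept (two canthi). The threshold may be an absolute temperature — the
predetermined-threshold protocol — or, by default, the 99.5th percentile
of the mean image, which needs no per-subject tuning and is invariant to
adding a constant to the image. An empty mask is an explicit error, never
a silent fallback. Body temperature is the mean over masked pixels and
all frames; the same mask yields the per-frame canthus trace that feeds
the 0.8–1.5 Hz pulse path.

## Airflow velocimetry (STIV)

A line ROI is placed along the visualized flow direction and the stack is
resliced along it (`reslice()`, bilinear, 1-px spacing), giving a
space–time image (STI): columns are distance along the line, rows are
time. A feature advected at constant speed traces a straight streak, and
with length scale Sx (m/px) and time scale St (s/px, = 1/fps),

U = (Sx / St) · (1 / tan θ),

where θ is the streak angle measured *from the space axis*. This
convention makes θ → 90° the stationary limit (U → 0), as physics
requires. Before orientation analysis the STI is median-filtered along
the space axis (`denoise_sti()`, default 15-px window — the filter has no
σ parameter; a 15-px window is the only coherent reading of a "σ = 15"
median step in an image-processing pipeline) and contrast-enhanced with
CLAHE (`enhance_contrast()`, clip limit 0.01 as a histogram fraction,
8×8 tiles; both exposed and recorded in reports). The exhalation windows
are then cropped out and analysed.

`mean_orientation()` implements the gradient-tensor orientation
histogram: Gaussian-derivative gradients (σ = 2 px) give each pixel a
level-line direction `atan2(It, Ix) + 90°` and a vote weight `Ix² + It²`
(the trace of the local structure tensor); votes are histogrammed over
(0°, 180°), the peak bin is refined by a parabolic fit over its circular
neighbours, and the angle is folded into (0°, 90°). A border of one
kernel radius, where reflection padding distorts gradients, is excluded.
The histogram default of 90 bins (2°) matches common directionality
analyses; the velocimetry wrapper uses 720 bins because the relative
velocity error propagates as 2·dθ/sin 2θ and grows sharply at shallow
angles.

### Why a coarse-to-fine refinement is necessary

At the study geometry — 2 mm/px, 60 fps — a 1 m/s plume advances 8.3 px
per frame. Adjacent STI rows are then nearly decorrelated, and discrete
derivative filters are strongly biased for such near-horizontal streaks:
the moving texture lives at temporal frequencies where a sampled
Gaussian-derivative no longer approximates a true derivative, and most of
its energy is simply filtered away, leaving static clutter that votes
near 90°. `stiv_velocity()` therefore refines coarse-to-fine: the STI
windows are resampled along time by sinc (FFT zero-padding)
interpolation — exact for every component sampled above Nyquist — the
streak slope is estimated from the orientation histogram *pooled over all
exhalation windows*, and the resampling factor is re-chosen so the
apparent slope approaches 1 px/row (45°, where angular error propagates
least). Two to three iterations converge. The pooled histogram is the
cross-exhalation aggregate: it weights every window by its gradient
energy and is far more robust than averaging per-window angles, which are
individually fragile on short, narrow windows; per-window values are
still computed at the final scale and returned for inspection, since the
estimate is dominated by the early, high-contrast phase of each
exhalation. Orientation bins within 1° of the axes are excluded from the
peak search: they correspond to exactly stationary or instantaneous
patterns, which cannot be a physical flow angle along the sampling line.

With this refinement the phantom recovery error stays below ~8% across
0.5–1.5 m/s at the full 18 mK noise level; without it, native-resolution
gradient estimates err by 50% and more at 1.5 m/s.

Flow volume follows the idealized assumption of unidirectional,
non-diffusive flow from the release surface: V = U · A with the nostril
cross-section A supplied by the user (areas are measured externally;
image-based area estimation is out of scope), and the CO₂ output is
V_CO₂ = 0.04 · V, exhaled breath being ~4% CO₂ by volume. Both identities
are exact in `flow_estimate()`, and `per_hour()` converts to m³/h for
comparison with ventilation-standard figures.

## Agreement statistics

`bland_altman()` reports the mean bias of method − reference differences,
their sample SD (n − 1), limits of agreement at bias ± 1.96 SD (the 1.96
multiplier exactly, not a t quantile), the agreement rate — the
percentage of differences falling within the LOA, boundary points counted
as within (this choice changes small-n rates and is therefore fixed and
documented) — Pearson correlation, and RMSE. With zero variance in either
series the correlation is reported as not computable rather than 1. The
identity rmse² = bias² + (n−1)/n · sd² links the columns and is checked
numerically in the tests. `compare_groups()` implements the
normality-gated decision tree: Shapiro–Wilk on each group, Bartlett on
variances if both are normal, Student's t if homoscedastic, otherwise
Mann–Whitney U; the returned record states the route taken.

## The synthetic phantom

`phantom_config()` encodes the acquisition conditions the pipeline
targets: 40-s spontaneous-breathing recordings, 60 fps MWIR and 30 fps
LWIR, ~24 °C ambient, a 34 °C facial ellipse, 36.5 °C canthus plateaus
carrying a 30 mK cardiac sinusoid (raised to 3× the noise floor in the
pulse-recovery tests), 15 breaths/min and 72 beats/min defaults, nostril
cross-sections of 7.18×10⁻⁵ and 5.85×10⁻⁵ m², and white per-pixel noise
at the 18 mK sensor resolution. The spatial grid is a scaled-down face —
96 × 80 px at 2 mm/px — so that full-length recordings (≈150 MB of
doubles) remain comfortable for routine testing; all geometric quantities
scale accordingly and every test states its configuration.

Design choices worth knowing:

* Expiration occupies the first half of each respiratory cycle (duty
  0.5, configurable); exhalation windows therefore tile the recording at
  exactly the configured rate and serve as ground truth for the STIV
  cropping.
* The plume is an advected intensity decrement, not a gas model: emitted
  continuously during exhalation along a fixed downward axis from each
  nostril to the bottom frame edge, with a Gaussian cross-section, an
  advancing front at the configured velocity, and a sinusoidal texture
  riding on it at the same speed. The texture wavelength defaults to 3×
  the per-frame displacement so that 60-fps sampling never aliases the
  motion — an intentional sampling-theory constraint, since an aliased
  phantom would encode a *wrong* ground-truth slope. A configuration
  whose nostrils sit too close to the bottom edge (axis < 8 px) is
  rejected.
* The LWIR phantom gives the nostril discs a capnogram-like waveform —
  fast upstroke, plateau, fast downstroke, baseline — in phase opposition
  to the MWIR darkening, as a nasal-temperature reference channel.
* The PPG trace is a unit cardiac sinusoid plus a 0.3-amplitude
  respiratory modulation and noise at 409.6 Hz, so the same bandpass/peak
  operators recover both reference rates.
* All randomness flows from one integer seed; identical configs produce
  bit-identical recordings.

What the phantom does *not* emulate: head or facial motion (the target
protocol is fixed-head), radiometric physics of the CO₂ band, plume
turbulence and diffusion, emissivity variation, camera vignetting or
fixed-pattern noise, and inter-subject anatomical variability. Passing
recovery tests on the phantom therefore demonstrates the correctness and
calibration of the *analysis chain*, not field performance on real
recordings.

## Conventions and numerical choices

* Pixel coordinates are 1-based `(row, col)` with row 1 at the top;
  rectangles are inclusive on both ends — the native convention of R
  matrices, used consistently everywhere including the CLI.
* Stacks are H × W × T arrays with time last; signals carry their
  sampling rate with them.
* TIFF output is 32-bit samples, linearly mapped into [0, 1] with a
  power-of-two gain and offset recorded in the JSON sidecar; the mapping
  itself is exact in binary floating point, so the round-trip error is
  bounded by the 32-bit sample quantization, `gain · 2⁻³²` in stack units
  (~10⁻⁸ °C for face-scale data). Integer (8/16-bit) TIFFs are read back
  to raw counts and calibrated as `raw · gain + offset`.
* Spectral argmax ties resolve to the lowest frequency; plateau peaks to
  the first index; both are asserted in tests.
* The respiration band follows the printed 0.1–0.4 Hz convention even
  though rates up to 25 breaths/min (0.417 Hz) slightly exceed it; the
  time-domain path is insensitive to the mild attenuation, and the
  frequency-domain path reports the nearest in-band bin, which stays
  within its one-bin tolerance.

## Known limitations

The velocimetry assumes a single dominant flow direction along the
sampling line and a streak-forming plume; it will not diagnose
recirculating or highly diffusive flow. The flow-volume figure inherits
the idealized unidirectional assumption and the externally supplied
nostril area, and is exploratory by construction. The frequency-domain
rate estimator is resolution-limited by the record length, which is why
the time-domain estimator is the default throughout the pipeline.
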