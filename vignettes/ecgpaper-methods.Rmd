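---
title: "Methods: synthesizing and digitizing paper-style ECG images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthesizing and digitizing paper-style ECG images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`ecgpaper` closes a loop: it renders multi-lead ECG time-series onto
standard ECG paper rasters with realistic document degradations, and it
digitizes such images back into calibrated millivolt series, quantifying
round-trip fidelity with SNR-style metrics. The synthesis side exists so
that digitization algorithms can be developed and validated against
pixel-exact ground truth; the digitization side is a classical pipeline
(rotation compensation, text inpainting, grid removal, strip segmentation,
column-wise trace extraction, unit conversion) with a small residual-learning
convolutional denoiser as the learned grid-removal option.

# Paper geometry and resolution

Standard ECG paper runs at 25 mm/s with 10 mm/mV gain, a fine 1 mm grid
(0.1 mV / 40 ms) and a coarse 5 mm grid (0.5 mV / 0.2 s). A page scanned at
`D` dots per inch maps 1 inch to `D` pixels, so one pixel spans
`dv = 2.54/D` mV vertically and `dt = 1.016/D` s horizontally; the trace
sampled one value per pixel column therefore has an image-implied sampling
frequency `fs_img = D/1.016` Hz (`resolutionParams()`). At the default
200 DPI a US-letter landscape page is 2200 x 1700 px, the coarse grid is
39.37 px, and `fs_img` is 196.85 Hz.

Grid pitch is generally non-integer in pixels; line positions accumulate in
floating point and are rounded per line so the mean pitch is preserved
without cumulative drift.

## Coordinates and trace rasterization

The raster convention is origin top-left, `x` = column (time), `y` = row,
1-based in R; amplitude increases upward (decreasing row index), so a
ground-truth polyline obeys `row = baseline - round(mV * px_per_mv)`.

The trace is drawn as a crisp 1-px polyline whose vertical jumps are filled
in the trailing column through the next column's row. Two consequences
drove this choice over an anti-aliased stroke:

* the filled curve is **4-connected**, which the 4-connectivity
  connected-component analysis of the extractor requires (an 8-connected
  staircase shatters into single-pixel components there);
* on a distortionless, grid-free render the rounded ground-truth pixel is
  the unique darkest candidate of its column, so column-wise extraction
  recovers the polyline exactly — the identity oracle the test suite uses
  for the whole pipeline.

# The synthetic ECG generator

`synthesizeECG()` is a stand-in for clinical time-series archives: a
sum-of-Gaussian-kernels beat template (P, Q, R, S, T waves with fixed
latencies and widths) placed at beat times from an RR process with a 3%
coefficient of variation, with per-lead amplitude multipliers (dominant
positive R wave of roughly 0.8-1.7 mV, jittered secondary waves) and a
mildly RR-stretched T latency. Defaults: 12 leads, 250 Hz, 10 s, 60 bpm.

What it emulates: quasi-periodic P-QRS-T morphology, plausible amplitudes,
distinct leads, controllable rate and duration — enough to exercise
rendering, extraction and interval metrics. What it does not emulate:
genuine inter-lead projection physics (all leads carry a positive R),
pathology-specific morphology, beat-to-beat morphology variation, or
realistic spectra. Passing round-trip tests therefore demonstrates the
fidelity of the imaging/digitization loop, not performance on clinical
recordings.

`addPhysiologicalNoise()` mixes baseline wander (sub-0.5 Hz sinusoids),
powerline interference, band-limited muscle noise and white device noise.
Each component is normalized to unit power, the mixture is scaled so that
the whole-record, all-leads-pooled `10*log10(sum(x^2)/sum(n^2))` hits the
requested SNR exactly. Pooling per record (rather than per lead) was an
open choice; the noise realization depends only on the seed, the input
signal only sets the global scale.

# Degradation models

* **Creases** — `n` parallel lines at a given inclination, placed at the
  `n` quantile translations of the line family across the page, darkened
  by `intensity` and blurred with a (possibly off-center) normalized
  Gaussian kernel; the off-center kernel gives the asymmetric shadow of
  light hitting a fold at an angle. Only the blurred line neighborhoods
  change.
* **Wrinkles** — image quilting: random patches of a seed texture placed
  in raster-scan order (default 48 px patches, patch/6 = 8 px overlap, the
  classic choice), joined along the minimum-error boundary cut of the
  squared-difference error surface, with both cuts combined on L-shaped
  corner overlaps. The DP recurrence treats out-of-range predecessors as
  `+Inf` and breaks ties toward the leftmost minimal predecessor so the
  path is deterministic. The bundled seed texture is procedural (a
  smoothed, directionally streaked random field, `wrinkleSeedTexture()`),
  i.e. synthetic rather than a scanned wrinkle photograph. Blending is
  multiplicative in luminance (`1 - a + a * texture/mean`), chosen because
  wrinkle shading modulates reflected light; the blend mode was not
  otherwise constrained.
* **Perspective** — full 3x3 homographies on homogeneous pixel
  coordinates, inverse-warped with bilinear sampling; ground-truth
  polylines map through the forward matrix with division by `w'`. The
  affine special case (`g = h = 0`) preserves parallel lines.
* **Imaging noise** — additive Gaussian (std `eta`), additive Poisson
  (rate `lambda`, applied literally as a draw added to intensity and
  clipped to [0, 255]), and salt-and-pepper that saturates a pixel jointly
  across channels to 0 or 255 with probability `p/2` each. Color
  temperature scales channels by a blackbody approximation normalized to
  identity at 6600 K, so 1000 K is orange and 40000 K blue. The full
  stack is applied creases, wrinkles, perspective, color temperature,
  Gaussian, Poisson, salt-and-pepper — salt-and-pepper last so its
  extremes survive; the provenance log records the realized order.
* **Text** — printed lead names/metadata and seven "handwriting" styles
  (slant, per-character rotation jitter, baseline sinusoid, stroke
  thickness, blue/black ink) rendered from an in-package vector stroke
  font. A stroke font keeps rendering deterministic across platforms and
  makes the warps natural; it replaces any pretrained handwriting model,
  which is out of scope. Keywords come from a bundled plain-text
  ECG/cardiology lexicon rather than NLP keyword mining.

# Digitization pipeline

**Rotation.** The skew angle is the maximizer of the variance (over the
offset axis) of the Radon projection profile. Two implementation details
matter: the projection of the page *support* is divided out, because the
raw projections of a roughly uniform rectangle peak spuriously near 45
degrees from the envelope alone; and the search is two-stage — a 0.25
degree coarse grid on a block-mean-downsampled page (longest side about
360 px), then a 0.05 degree refinement around the optimum at about 1100 px.
The variance criterion itself is the standard document-skew choice; the
sinogram-based criterion was otherwise unspecified.

**Text removal.** Overlay ink masks (synthetic mode) or a pluggable
detector's boxes, dilated by 2 px, are inpainted in increasing
distance-map order by the distance-weighted first-order approximation
`I_q(p) = I(q) + grad I(q) . (p - q)` over already-known 8-neighbors
(weights `1/d^2`, central-difference gradients over known pixels). The
scheme is exact on linear ramps and deterministic, hence idempotent for a
fixed mask.

**Grid removal.** The classical route suppresses pixels whose color
matches the reddish grid (red excess over max(G, B) above a threshold) and
fills them with the background. The learned route is a residual
convolutional denoiser: first layer conv+ReLU, middle layers
conv+batchnorm+ReLU, last a single-filter conv predicting the grid
component `v` of `y = x + v`, trained with the residual Frobenius loss and
Adam, early-stopped on a validation split. Images are processed per RGB
channel in 30 x 30 patches with 5 px overlap (edge tiles re-anchored flush
with the border so coverage is complete), and re-stitched with exponential
distance weights `exp(-d/tau)`, `tau = 5` px (the overlap width; the
cited stitching constant was not given). The full architecture preset is
17 layers of 64 7x7 filters; the desk preset used by the test suite is 4
layers of 12 5x5 filters trained on 2000 synthetic grid patches for at
most 5 epochs (batch 8, lr 1e-2), with the final layer zero-initialized
so the network starts at the identity — this is what makes the trained
model near-identity on grid-free patches at desk scale. Training pairs
come from `makeGridPatchPairs()`: light backgrounds with dark trace-like
curves, about 90% of them overlaid with periodic grid lines of random
pitch, phase and intensity.

**Strips and traces.** The row-mean intensity profile, smoothed with an
order-11 non-causal moving average (edges replicated — the filter needs
values beyond both ends), has significant minima at trace baselines;
minima below the midpoint of the profile's range, merged when closer than
5 mm, split the page at the intervening maxima into strip ROIs. Each
strip is binarized by a 3x3 local-mean threshold (offset 10) plus an
absolute darkness test, labeled with 4-connectivity, filtered (defaults at
200 DPI: min height/width 3 px jointly, min area 10 px, upper area bound
for background blobs), and fragments whose outer-boundary pixels come
within 10 px of each other are fused. (A strict symmetric Hausdorff
distance between two long adjacent fragments is of the order of their
length, so thresholding it could never re-join a broken trace; the fusion
distance is therefore the separation of the outer boundary pixel sets.) The trace is then one
row per column: the darkest below-threshold pixel of the column after a
1x3 horizontal mean blur. Ties are broken toward the row closest to the
previous column's choice (continuity), then the smallest row; pure
smallest-row tie-breaking mis-picks by one pixel on unit-slope staircases
and by the run length on steep strokes, which is visible as spike noise in
the recovered series. Columns with no ink are flagged and linearly
interpolated. The baseline of a strip is the mode of the rounded trace
rows, since flat segments dominate.

**Units.** Amplitude uses the scaling factor `0.5 mV / coarse grid px`;
the coarse pitch is estimated before grid removal from the autocorrelation
of the row/column mean-intensity profiles. The fundamental lag is refined
by climbing its harmonics — re-locating the peak near each successive
multiple and dividing — with parabolic interpolation at the final peak;
integer-lag estimates alone (e.g. 40 px instead of 39.37 px at 200 DPI)
would already consume a tolerance of one `dv` in amplitude. Timing comes
from `fs_img = D/1.016` when the DPI is trusted, else from the grid
(`coarse_px * paper_speed / 5`). Recovered series are spline-resampled to
the reference rate and aligned at the integer-lag cross-correlation
maximum within half a second.

# Metrics

Per record, `snr` is `10 log10(mean(x^2)/mean((x - xhat)^2))`; `snrMed`
replaces the mean noise power with the median, which is insensitive to the
occasional spike from a mis-picked column. A zero denominator reports a
200 dB cap sentinel. MSE is reported in mV^2 with its RMS. Cohort tables
report 2.5th/97.5th percentile endpoints (linear interpolation) and the
mean +- SD inside that range. R peaks are local maxima above half the
99th amplitude percentile with a 200 ms refractory period; RR error is
the mean absolute difference of consecutive matched intervals, invariant
to a uniform delay. QRS/QT comparison accepts any pluggable delineator;
none is built in beyond R peaks.

# Problem sizes and test design

The test suite works at desk scale, chosen as the smallest sizes that
exercise every code path meaningfully: 10 s, 12-lead records at 150-200
DPI; 20 seeded records for the clean round trip (SNR at least 20 dB and
RR error at most 10 ms per record — the package's own bar for a
distortion-free loop); 20 seeded page rotations in [-15, 15] degrees
recovered within 0.5 degrees; 100 random surfaces up to 6x5 for the
exhaustive boundary-cut oracle; 50 random 20x20 masks for the flood-fill
labeling oracle; 2000 patches / 5 epochs for the denoiser. The full-scale
denoiser preset (about 100k patches, 30 epochs, 17 layers) is configured
but not exercised by the tests.

# Known limitations

* Strip segmentation assumes non-overlapping rows; adjacent leads with
  large excursions into a neighboring band are not disentangled.
* Within a multi-segment row the extractor produces one trace across the
  whole row; synthetic-mode evaluation cuts it by ground-truth time
  windows, and without ground truth an equal-width quartering is the only
  built-in fallback.
* Only pure rotation is compensated; shear and perspective are simulated
  but not inverted.
* The handwriting renderer is a stylized stroke font, not a generative
  handwriting model; its masks are exact, which flatters inpainting
  relative to detector-derived masks.
* Steep QRS strokes are vertical pixel runs; even with continuity
  tie-breaking the recovered extremum can be off by a few pixels, which
  bounds clean-render SNR in the mid-20 dB range at 200 DPI rather than
  the cap.
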