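---
title: "Glottal area waveform analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glottal area waveform analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gawkit)
```

## The problem

High-speed videoendoscopy of the larynx records the vocal folds at several
hundred to several thousand frames per second while a subject phonates. The
folds oscillate at roughly 80–260 Hz, opening and closing a dark,
spindle-shaped gap — the glottis — between two bright tissue edges. The
clinically useful signal is not the raw video but the *glottal area
waveform* (GAW): the per-frame area of the gap, optionally split at the
anatomical midline into an image-left and image-right share. From the GAW
one reads the fundamental frequency of vibration, left/right amplitude
asymmetry (unilateral paralysis), the residual area at maximal closure
(incomplete closure in laryngitis or with a polyp), and the timing offset
between the two folds.

`gawkit` implements that pipeline for frame stacks from any source, plus
two support components that make it verifiable without clinical material: a
ground-truthed synthetic glottis video generator and a chopper-wheel
procedure for measuring a camera's true frame rate. Consumer cameras that
advertise "960 fps" capture modes do not necessarily deliver them; all
temporal quantities downstream (f0 above all) scale linearly with the frame
rate, so the calibration step matters.

## Conventions

Pixel coordinates are 0-based `(row, col)` with row 0 at the top; frame
indices are 0-based with frame `k` at time `k/fps`. Intensities are 8-bit.
"Left" and "right" always mean *image* left/right (smaller/larger column);
endoscopic images mirror the anatomical sides, and rather than guess the
orientation of a given recording the package labels everything
image-left/image-right.

## Pipeline stages

### Preprocessing

RGB frames are reduced to grayscale by a rounded weighted channel sum
(default Rec.601 weights 0.299/0.587/0.114), then contrast-stretched by a
*global* percentile map: the 1st and 99th percentiles of the whole clip's
intensities map linearly onto 0 and 255. One map per clip, not per frame —
per-frame stretching would re-scale equal glottal intensities differently
in different frames and inject flicker into the area waveform. The map is
monotone, so within-frame ordering (and hence any threshold-based
segmentation) is unaffected.

### Segmentation: seeded region growing

The glottal gap is the darkest coherent structure in a correctly exposed
laryngeal frame, so each frame is segmented by region growing from a dark
seed. Two criteria are provided:

* **region-mean** (default): repeatedly admit the boundary pixel whose
  intensity is closest to the current region mean, while that difference
  stays within a tolerance `tau`; ties break by insertion order. This is
  the classic seeded-region-growing scheme and adapts to illumination
  level (its result is invariant to adding a constant to the frame).
* **fixed-threshold**: the connected component of `{I <= threshold}`
  containing the seed. Exactly a flood fill, hence trivially checkable
  against a brute-force oracle — the test suite verifies bit-identity on
  hundreds of random grids at both connectivities.

Unset `tau`/`threshold` are derived once per clip from Otsu's threshold
(computed on the frame with the widest intensity spread, the one most
likely to show an open glottis): `threshold = otsu`,
`tau = otsu - min(frame)`. Connectivity defaults to 4. A region that
exceeds `max_area_frac` (default 0.25) of the frame is treated as leakage
and raises an error naming the frame — silent truncation would produce a
plausible-looking but meaningless waveform.

Seeding is manual (a given pixel), darkest-in-ROI (argmin intensity, ties
to smallest row then column), or propagated (darkest pixel inside the
previous nonempty mask's bounding box, falling back to the ROI rule).
`segment_stack()` seeds frame 0 explicitly and propagates thereafter.

**Closed frames.** In healthy phonation the glottis closes completely, so
some frames contain no glottal pixels at all, and any seed found there
would sit on fold tissue. A resolved seed is therefore rejected — and the
frame recorded as closed, area 0 — unless it is convincingly dark: below
`threshold` in fixed mode, below `median(frame) - tau` in region-mean mode
(the median is a robust background estimate because the gap never
dominates the frame).

### Midline and side waveforms

`fit_midline()` takes the principal axis (largest-variance eigenvector of
the pixel-coordinate covariance) of the union of all masks, anchored at the
union centroid, with the sign fixed to `d_row >= 0`. One line per clip,
matching the single drawn line of clinical practice. The fit assumes the
gap is roughly symmetric about the true midline: a strongly one-sided
pathology (paralysis, large polyp) pulls the union centroid toward the
mobile side and the fitted line with it, which dilutes the measured
asymmetry. That is precisely why clinicians draw the midline manually —
for such clips, pass a manual `midline_model()` (on the command line,
`midline: "r1,c1:r2,c2"` in the config).

Each mask pixel is assigned by the sign of the cross product
`direction x (pixel - point)`: negative left, zero or positive right.
Sending on-line pixels right is arbitrary but deterministic, and
conservation (`left + right = total`, exactly, every frame, any midline) is
a tested invariant. Edge lengths per side are unit-edge perimeter counts
(edges between a mask pixel and a non-mask or out-of-image 4-neighbor) —
an exact integer, verified against a brute-force enumeration, rather than
a sub-pixel contour length whose value depends on smoothing choices.

### Diagnostic parameters

* **f0** — the area series is mean-subtracted and linearly detrended,
  zero-padded 16x, and the FFT magnitude peak at or above `f_min = 70` Hz
  is refined by 3-point parabolic interpolation and rounded to 0.1 Hz.
  Detrending plus the `f_min` floor is the "motion error" rejection:
  endoscope and laryngeal drift concentrate below ~10 Hz, well under the
  phonation band, and must not win the peak search. A 0.4 s clip has a
  native resolution of only 2.5 Hz; padding plus interpolation brings
  recovery to within 1 Hz across 100–260 Hz (tested), and to 0.1 Hz-level
  at the 224 Hz operating point.
* **Asymmetry index** — `AI = (A_L - A_R)/(A_L + A_R)` with `A_s` the
  peak-to-peak amplitude of side `s`'s area series, both sides normalized
  by the *total* series maximum so the ratio compares like with like.
  `-1 <= AI <= 1`; negative means the image-left fold moves less. A robust
  2nd/98th-percentile amplitude is selectable for noisy series.
* **Closure deficit** — mean per-cycle minimum of the normalized total
  series, cycles being consecutive `round(fps/f0)`-frame windows (trailing
  partial window dropped). At this package's operating point a cycle spans
  only ~4 frames, and the *sampled* minimum of a waveform that truly
  touches zero lands up to three-quarters of a radian from the trough: on
  a pure sinusoid the raw estimator reports ~0.05 where the truth is 0.
  Each window minimum is therefore refined by the same 3-point parabolic
  interpolation used for spectral and calibration peaks, clamped to
  `[0, sampled minimum]`; this brings the healthy value to ~0.02 while
  moving a genuine 0.2 residual gap by under 0.02. `refine = FALSE`
  restores the plain sampled minimum.
* **Lateral phase lag** — the lag maximizing the normalized
  cross-correlation of the mean-subtracted left/right edge-length series,
  searched over one period and parabolically refined to fractional frames.
  Positive means image-right lags image-left. Antiphase series correlate
  equally at both ends of the search range; the tie resolves to the
  negative lag (`-P/2`), which is documented rather than meaningful.
* **Frames per cycle** — `floor(fps/f0)`; at 940 fps the 115–260 Hz band
  yields 3–8 frames per cycle, against 15–34 for a conventional 4000 fps
  system. The package operates deliberately in that undersampled regime,
  which is what motivates every sub-sample refinement above.

`build_report()` aggregates these with full settings provenance; optional
threshold flags ("paralysis-like", "incomplete-closure-like") annotate
synthetic phenotypes and are not a diagnosis of anything.

## Frame-rate calibration

A 4-quadrant chopper wheel with 2 opposite quadrants blacked out, spinning
at a known `chopper_hz` in front of the endoscope, modulates the recorded
brightness with period `1/(2 * chopper_hz)` seconds. The frame-mean
intensity trace is computed per frame; local maxima above the trace
midrange, at least `min_separation` frames apart and refined parabolically,
give fractional peak positions; the mean consecutive interval `T` frames
converts to `fps = T * blocked_quadrants * chopper_hz`. All consecutive
peak pairs are averaged (a single interval would waste the clip). The
generator models the modulation as a raised cosine of the transparent-area
fraction; the round trip recovers the generator's rate to 0.5% noise-free
and 1% at noise sigma 5 (tested at 240–960 fps). One practical caveat: an
8-bit-quantized trace flattens the cosine peaks, so sub-frame refinement
degrades toward integer positions — a file-based round trip at 939.44 fps
reads 940 fps (0.06% error), while the in-memory trace resolves 46.972
frames.

## The synthetic generator

The generator exists to give every stage an exact oracle, not to imitate
tissue. Side `s`'s half-width at row `y`, time `t` is

    w_s(y, t) = m(y) * [closure_s + amp_s * (1 + sin(2 pi f0 t + phase_s)) / 2]

with spindle profile `m(y) = sin(pi (y - row_top)/(row_bottom - row_top))`.
The midline sits on the boundary between columns `midline_col - 1` and
`midline_col` (continuous coordinate `c = midline_col - 0.5`), and a pixel
is glottal iff its center column lies strictly inside `(c - w_L, c + w_R)`
at its row, outside any polyp disc. Placing the midline between pixel
columns and keeping the interval open makes zero width an exactly empty
gap, leaves no pixel centers on the midline (so left/right attribution is
never a tie), and makes a horizontal mirror with swapped side parameters
reproduce the stack pixel for pixel — all tested invariants. Ground-truth
areas are counted from the same widths *before* Gaussian noise is added,
so on noise-free stacks segmentation must match the truth exactly, and
does (a tested equality, not an approximation). `simulate_gaw()` skips
rasterization and samples the continuous-column areas directly, for
testing the waveform analysis in isolation.

Study conditions (the defaults, chosen once): 160x120 px frames, glottal
spindle on rows 20–100 about column 80, amplitude 18 px per side, complete
closure, f0 224 Hz (a typical young-adult female voice and this package's
reference operating point), 939.44 fps, 0.4 s (375 frames), tissue at
intensity 180 over a gap at 40, preset noise sigma 2. Frame size is a
desk-scale stand-in for 1280x720 clinical frames — no reported quantity
depends on resolution. Pathology presets: `paralysis-left` sets
`amp_left = 1` (analytic AI of -17/19 ≈ -0.89); `laryngitis` sets 4 px
closure offsets with 14 px amplitudes (analytic deficit ≈ 0.22);
`polyp-right` halves the right amplitude, adds 3 px offsets and a 5 px
occluding disc at (60, 86).

What the generator does *not* emulate — and what passing tests therefore
do not show about clinical data: mucosal-wave texture, specular highlights
and color, irregular (aperiodic or diplophonic) vibration, moving
anatomy/camera beyond a linear trend, interlacing or rolling-shutter
artifacts, and any biomechanics (it is a kinematic, not a flow-driven,
model). Results on real recordings depend above all on exposure and on a
sensible midline.

## Numerical choices and degenerate inputs

* Frame count is `floor(duration * fps + 1e-9)`; the epsilon keeps exact
  products (0.4 s x 940 fps = 376) from falling to 375 in floating point.
  The same guard appears in `frames_per_cycle()`.
* All parabolic refinements use the three samples around the extremum and
  are skipped at sequence ends or when the curvature has the wrong sign.
* Constant series: `estimate_f0()` and `detect_peaks()` raise errors (no
  oscillation/modulation); `asymmetry_index()` and `lateral_phase_lag()`
  return `NA` with a flag when their inputs carry no signal; a constant
  stack passes through `adjust_contrast()` unchanged with a warning.
* An all-zero total-area series (never-open glottis) stops
  `build_report()`; all-empty segmentations make `fit_midline()` ask for a
  manual midline.
* Ties: darkest-pixel searches resolve to smallest row then column;
  region-growing admission ties resolve by insertion order; on-midline
  pixels go right; the midline direction sign is fixed `d_row >= 0`.

## Problem sizes

The test suite and the acceptance script run the full rendered pipeline at
375 frames of 160x120 px (the 0.4 s clip), property tests on 16x16 random
grids (200 grids for the flood-fill identity), and shorter 0.01–0.1 s
clips for geometry and IO checks; the complete suite finishes in well
under a minute on one core.

## Known limitations

* The automatic midline fit biases toward the mobile side under one-sided
  pathology (see above); supply a drawn midline for such clips.
* MP4/AVI containers are not read; decode to PNG/TIFF sequences first.
* The segmentation tracks one connected gap; a polyp that splits the gap
  into separate islands leaves only the seeded island in the mask.
* Reports are per-clip; there is no multi-clip aggregation, kymogram
  rendering, or acoustic (jitter/shimmer) analysis.
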