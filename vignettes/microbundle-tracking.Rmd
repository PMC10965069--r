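---
title: "Tracking and strain analysis of beating microbundles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and strain analysis of beating microbundles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bundletrack)
```

This vignette documents the models and procedures implemented in
**bundletrack**, the assumptions behind them, the tunable parameters and
their defaults, what the synthetic generator does and does not emulate,
and the design decisions taken where the problem was genuinely open.

## Problem setting

Cardiac microbundles are engineered heart tissues that beat spontaneously
between two flexible pillars. A time-lapse movie of a beating microbundle
encodes its mechanical function: displacement amplitude, beat rate,
spatial strain patterns, synchrony, and (through pillar deflection)
contractile force. The pipeline extracts these quantities automatically
from a grayscale movie, with no manual landmarking.

Coordinates are 1-based `(row, col)` with row increasing downward,
matching R matrix indexing; sub-pixel positions are doubles on the same
axes. Intensities are on the `[0, 1]` scale delivered by TIFF input.

## Tissue masking

Three automatic variants, all built on Otsu's threshold: the first frame,
the Gaussian-smoothed Sobel gradient magnitude of the first frame (the
smoothing turns a speckle of edge responses into a solid textured
domain), or a per-pixel min/max projection over all frames. The
foreground side is then post-processed to the single largest 8-connected
component with interior holes filled, since downstream feature detection
assumes one tissue domain. The post-processing is idempotent, and the
plain-threshold method is invariant to affine intensity rescaling (an
Otsu property).

*Polarity.* Tissue may image darker or brighter than background, so the
thresholded side must be chosen. Choosing the side with the larger
component fails whenever tissue occupies less than half the frame;
instead the side whose largest component touches fewer of the four image
corners is taken (the background, not the tissue, is corner-anchored in
these movies), with ties broken toward the larger component.

*Blur screening.* A frame is flagged when its variance-of-Laplacian,
normalized by the squared mean intensity, falls below `1e-4`
(configurable). The statistic is scale-invariant; the default separates
a sharp texture from the same texture smoothed with an 8 px Gaussian by
orders of magnitude.

## Feature detection and coverage tuning

Markers are Shi–Tomasi corners: pixels whose minimum structure-tensor
eigenvalue (Sobel gradients, 3×3 block average) is a local maximum and at
least `qualityLevel` times the best masked score, thinned greedily so no
two markers are within `minDistance` pixels.

The auto-tuner starts at `qualityLevel = 0.1`, `minDistance = 3` and
iterates at most 15 times: while the coverage (mask pixels per marker)
exceeds 40, the quality level is multiplied by `10^(-1/10)` per step —
a smooth geometric descent that spans a factor ~32 over the 15-step cap;
during the first two iterations `minDistance` is additionally
incremented while the three largest local-coverage values (20×20 px
tiles anchored at the mask bounding box) are all ≤ 50. The loop sense is
"decrease while coverage > 40": lowering the quality level admits more
markers and therefore strictly lowers coverage, so this is the only
reading under which the iteration can terminate by its own condition.
Tiles containing mask pixels but no markers report their full mask-pixel
count, keeping them influential in the `minDistance` rule.

## Lucas–Kanade tracking

The tracker is a pyramidal Lucas–Kanade solver (compiled core). Per
marker and frame pair, the constant-flow least-squares problem over a
`winSize × winSize` window is solved by damped fixed-point iteration —
template gradients by central differences on a bilinearly sampled patch,
updates until below 0.01 px or 30 iterations — refined coarse-to-fine
over a 3-level binomial image pyramid. Numerical safeguards:

- *Textureless windows.* Windows whose normalized minimum gradient
  eigenvalue falls below `1e-5` (per window pixel, unit intensity scale)
  are considered textureless: they are skipped at coarse levels and
  invalidate the marker at full resolution. The threshold cleanly
  separates textured windows (typically ≥ `1e-3`) from the near-flat
  coarse-level windows whose ill-conditioned solves would otherwise
  inject large spurious guesses.
- *Flow clamping.* A window cannot validly measure motion beyond its own
  support: per-level flow exceeding `winSize` is discarded at coarse
  levels and invalidates the marker at level 0.
- Markers whose window leaves the image, or that fail either safeguard
  anywhere in the movie, are excluded from all outputs (not
  interpolated), keeping the per-beat M×N output arrays rectangular.

`winSize` is tuned by the preliminary-tracking rule: start at 5, track
the whole movie, and grow by 5 while the maximum per-frame displacement
(largest axis component between consecutive frames) exceeds the window,
up to 15 passes. The final preliminary pass is reused as the tracking
result. `pyramid_levels = 3` follows common practice; levels are dropped
once an image side falls below 16 px.

## Temporal segmentation and drift correction

Peaks of the mean absolute displacement series are found with a
re-implemented prominence-based peak finder: strict local maxima
(plateaus resolve to midpoints), topographic prominence computed by
walking to the nearest strictly-higher sample per side, minimum
prominence 0.1 px, and distance-based suppression keeping
higher-prominence peaks first. The minimum peak distance is
`round(1.5 ×)` the gap between the first two crossings of the series
with its mean — the earliest stable estimate; crossings use linear
interpolation between samples, and exact zeros are skipped so a flat
series yields a segmentation error rather than spurious crossings.

Valleys are floor-midpoints of consecutive peaks; at least 3 peaks (one
complete beat) are required. Beats span valley to valley with the shared
boundary frame kept in both neighbors, so every beat array is
self-contained. Within a beat all displacements are measured from the
beat's own first frame; this cancels slow tracking drift, and per-beat
frame-1 displacement is identically zero by construction.

*Quality checks.* Three warnings: blurred frames; sub-pixel motion,
flagged when the maximum per-marker displacement is below 1 px (the
mean-displacement series maximum alone would misclassify movies whose
motion is super-pixel at the tissue ends but averages below a pixel);
and a contracted start. A contracted-start movie is phase-shifted, so
its displacement series looks like a normal one — the discriminating
signal is time asymmetry: with a contracted reference frame the series
dwells near its maximum, so a mean above the midrange (or a first-valley
offset above half the first-beat amplitude) raises the warning. The fix
is trimming leading frames to the first relaxed frame.

## Subdomains and strain

Rotation, when requested, is applied to the *tracked coordinates*
exactly (no resampling); images are only resampled for display. The
tissue long axis is the principal eigenvector of the mask's second
central moments, with a fallback to the image horizontal for nearly
isotropic masks (relative eigenvalue gap below `1e-3`).

Subdomain extents come from the mask by a run-length rule — rows/columns
whose longest foreground run exceeds half the maximum run — which clips
the pillar-attachment regions; the exact clipping rule was an open
choice, and this one is simple, deterministic and configurable (manual
extents are accepted). Tiles are laid out row-major with remainder
pixels split as centering margins; 30–40 px sides are recommended: large
enough for a stable pairwise fit, small enough not to average away
heterogeneous deformation.

Per tile and frame, all unordered marker pairs (membership fixed by
reference-frame position within each beat, where `Λ₀` is defined) give
`F_avg = Λ Λ₀ᵀ (Λ₀ Λ₀ᵀ)⁻¹` and `E = ½(FᵀF − I)`. Unordered pairs
suffice — duplicating pairs provably leaves the least-squares solution
unchanged — and recovery is exact (machine precision) whenever the
current positions are an affine image of the reference. Tiles with fewer
than 3 markers or collinear arrangements (reciprocal condition below
`1e-12`) are excluded with a warning rather than failing the run.
Displacement interpolation to arbitrary query points is piecewise-linear
on the Delaunay triangulation of marker positions; affine fields are
reproduced exactly inside the convex hull, and outside-hull queries take
the nearest marker's value and are flagged.

## Pillar force

A pillar region is tracked with the same machinery (mask = pillar head).
Deflection converts to force via an end-loaded rectangular cantilever,
`k = 3EI/L³`, `I = w t³/12`, or a directly supplied spring constant; a
multiplicative stiffness factor (default 1) absorbs corrections such as
spherical caps or load height. Stress divides force by the tissue
cross-section; tissue depth has no default — it cannot be measured from
in-plane images and must be supplied.

## Synthetic data generator

The generator renders a textured tissue band undergoing periodic
contraction, with exact ground truth. It replaces a finite-element
simulation stage by analytic displacement fields: the purpose of the
synthetic stage is to validate *tracking*, not tissue mechanics, so the
fields only need to be known exactly.

- *Activation:* raised-cosine pulse train
  `a(t) = (½(1 − cos 2π t/P))^p`, zero at beat boundaries; sharpness
  `p = 2` gives visually plausible brief contractions with long
  diastolic dwell.
- *Field:* horizontal contraction toward the vertical midline,
  `u_col = −a A (col − mid)/half_width`, with transverse bulging
  `u_row = ν a A (row − mid)/half_height`, `ν = 0.3`. The amplitude `A`
  is the displacement of the image edge; the mean displacement in the
  central evaluation window is accordingly smaller (about 0.19 A over
  the default geometry). The inclusion variant multiplies the field by a
  cosine taper vanishing at the center of a circular passive inclusion.
- *Rendering:* the image is tiled into 16 px cells sharing corner nodes;
  each cell's projective transform is estimated exactly from its 4 node
  correspondences and inverse-warped with bilinear sampling. Shared
  nodes keep the rendering C0-continuous; for affine fields every cell
  homography equals the global affine map, so the rendering is exact up
  to interpolation. Frames are quantized to the 16-bit grid so written
  movies reload bit-for-bit.
- *Texture:* band-limited speckle (Gaussian-filtered white noise,
  σ = 2 px) on a brighter band (intensity 0.55 ± 0.18 sd) over a darker
  background (0.15 ± 0.04), so corner detection always succeeds and
  Otsu masking recovers the band.
- *Noise:* classic lattice-gradient (Perlin) noise. "Octaves" is
  interpreted as the base lattice frequency — the number of lattice
  periods across the longer image side — matching the observation that
  high values resemble speckle; classical multi-octave fractal summation
  is not layered on by default. The amplitude is scaled so the maximum
  absolute perturbation equals the magnitude ratio times the frame's
  intensity range. A movie-level noise seed produces the *same* pattern
  on every frame (a static overlay, akin to fixed-pattern sensor
  artifacts); per-frame-varying noise is available by calling
  `add_perlin_noise()` with per-frame seeds, but note that when the
  noise lattice scale matches the texture feature scale, time-varying
  noise defeats any intensity-matching tracker.

Defaults are the package's reference validation condition: 256×256
texture, 40-frame period, 5 beats (201 frames), 2.5 px amplitude, 30
fps. What the generator does *not* emulate: out-of-plane motion,
illumination drift, photobleaching, shot noise, non-rigid texture
evolution (cell remodeling), and realistic pillar imagery. Passing
validation on synthetic movies therefore demonstrates the correctness
and accuracy of the tracking and strain machinery under known motion,
not robustness to every experimental artifact.

## Validation measures and problem sizes

Tracked displacements are compared with truth over the central 90×90 px
window: per beat, marker displacements (relative to the beat's first
frame) are interpolated onto a 3 px lattice and reduced to a mean
absolute displacement series; the analytic field is evaluated on the
same lattice with the same reference. Scores are the per-beat percentage
error at peak displacement and R², and per-tile R² of `E_cc` series
(tracked via the pairwise estimator; truth via the same estimator
applied to a dense 3 px analytic lattice). The acceptance script runs
ten movie-scale analyses (one reference movie, its noisy copy, a
6-movie ensemble, two sub-pixel movies), about 200 frames each — sizes
chosen so the full study reruns in minutes on one CPU.

Under these conditions the noise-free targets are met with large margin
(peak errors well under 1% at 2.5 px amplitude; strain R² above 0.97).
The static-noise condition is the known hard case: an intensity-matching
tracker is biased toward a static overlay in proportion to the ratio of
noise to texture gradient energy, which at these texture-contrast
settings leaves a residual underestimate of a few percent of the
window-mean peak displacement, independent of window size.

## Known limitations

- Markers lost anywhere in the movie are dropped everywhere; long movies
  with transient occlusions lose markers monotonically.
- Feature re-detection mid-movie, dense optical flow, per-pixel strain,
  and arrhythmia classification are out of scope.
- The mean-displacement series used for temporal segmentation needs at
  least 3 contraction peaks and a prominence of 0.1 px; extremely weak
  (deep sub-pixel) motion can fall below it.
- Rendered "movies" are ordered PNG frame sequences; no video container
  is written.
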