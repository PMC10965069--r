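# bundletrack

Automatic deformation analysis of time-lapse movies of beating cardiac
microbundles — millimeter-scale engineered heart tissues suspended between
two flexible pillars. From a grayscale movie alone, the package segments
the tissue, tracks hundreds of fiducial markers with auto-tuned sparse
optical flow, splits the recording into individual beats, and reports
full-field displacements, subdomain-averaged Green–Lagrange strains, beat
metrics, and (optionally) pillar forces. A synthetic beating-movie
generator with exact analytic ground truth supports end-to-end validation.

## Who it is for

Labs quantifying contractility of hiPSC-CM microbundles (or any textured
tissue beating between posts) from brightfield or phase-contrast movies,
without manual landmarking: the only required input is the movie; a binary
tissue mask and acquisition metadata (frames/s, µm/pixel) are optional.

## The method

1. **Mask.** Otsu thresholding of frame 1, of its Sobel gradient
   magnitude, or of a min/max projection across frames; the tissue side is
   post-processed to a single filled connected component.
2. **Markers.** Shi–Tomasi corners (minimum structure-tensor eigenvalue)
   inside the mask. Detection parameters are auto-tuned: starting from
   `qualityLevel = 0.1`, `minDistance = 3`, the quality level is lowered
   until the *coverage* (mask pixels per marker) is ≤ 40, while
   `minDistance` may grow during the first two iterations when local
   coverage on 20×20 tiles is ≤ 50.
3. **Tracking.** Pyramidal Lucas–Kanade sparse optical flow (compiled
   core). For each marker the local constant-flow least-squares problem

   `G v = b`, with `G = Σ ∇I ∇Iᵀ`, `b = Σ (I − J) ∇I`

   is solved iteratively over a `winSize × winSize` window, coarse-to-fine
   over the image pyramid. `winSize` starts at 5 and grows by 5 until it
   exceeds the largest per-frame motion.
4. **Beats.** Peaks of the mean absolute displacement series are found
   with a prominence-based peak finder (prominence 0.1 px; the minimum
   peak distance is 1.5× the gap between the first two mean crossings).
   Valleys are peak midpoints; each beat runs valley to valley and is
   re-referenced to its own first frame (drift correction).
5. **Strain.** Within each rectangular subdomain tile, all marker pairs
   give reference and current difference-vector matrices `Λ₀`, `Λ`; the
   average deformation gradient is the normal-equation solution
   `F_avg = Λ Λ₀ᵀ (Λ₀ Λ₀ᵀ)⁻¹`, and `E_avg = ½(F_avgᵀ F_avg − I)` with
   `E_cc` the horizontal (column–column) component.
6. **Pillars.** Tracking a pillar-head region converts deflection δ to
   force `F = k δ` (`k = 3EI/L³`, `I = w t³/12`) and stress
   `σ = F / (tissue width × depth)`.

## Worked example

```r
library(bundletrack)

## a synthetic beating movie with known ground truth (2.5 px peak motion,
## 5 beats of 40 frames, 256x256 speckle texture)
mv  <- generate_movie(synthetic_config(seed = 0))
res <- run_pipeline(mv$stack, n_tiles = c(2, 2))
print(res)
#> mb_analysis: 201 frames of 256 x 256 px
#>   markers: 824 valid / 838 tracked (coverage 37.9 px/marker)
#>   beats: 3 (peaks at 21, 61, 101, 141, 181)
#>   period: 1.333 s, mean amplitude: 1.246 px

## compare tracked displacement against the analytic truth over the
## central 90 x 90 window
ev <- evaluate_displacement(res$traj, res$seg, mv$truth)
ev$comparison$per_beat
#>   beat peak_pct_error        r2
#> 1    1      0.6549357 0.9999360
#> 2    2      0.6366090 0.9999397
#> 3    3      0.6264926 0.9999417
```

The `print` shows 838 auto-detected markers (one per ~38 mask pixels), the
five detected contraction peaks delimiting three complete beats, and the
beat period in seconds (40 frames at 30 fps). The per-beat comparison
shows the tracked peak mean displacement within 0.7% of truth and
R² > 0.999 for every beat. `run_pipeline(..., output_dir = "out")` writes
the per-beat marker position arrays (`beat1_row_pos.txt`, …), subdomain
deformation gradients (`beat1_subdomain_F.txt`), `tissue_mask.txt`,
`warnings.txt` and `metrics.json`; `render_outputs()` adds per-beat
time-series figures and displacement/strain frame sequences.

A thin command-line front end is installed at `inst/cli/bundletrack.R`
(sub-commands `run`, `mask`, `synth`, `viz`).

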