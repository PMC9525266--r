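---
title: "Registration methods for overlaying static spectral maps on laparoscopic video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registration methods for overlaying static spectral maps on laparoscopic video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Quantitative perfusion imaging — for example tissue-oxygenation (StO₂) maps
derived from hyperspectral imaging (HSI) — is not available at video frame
rate. A push-broom HSI record takes seconds, after which the surgeon sees a
static false-color map that no longer lines up with the moving laparoscopic
view. `lapreg` implements the augmentation strategy built around a saved
reference frame: during the HSI record one video frame (the *start frame*) is
stored, every subsequent frame is registered to it, and the static
physiological map is warped through the estimated transformation and
alpha-blended over the live grayscale frame. Abdominal scenes make this hard:
elastic organs, breathing motion, instruments, specular glare, and non-planar
geometry all violate the assumptions of a single global transform, which is
why the package carries three transformation models and a per-pixel fusion
and masking stage to suppress unreliable overlay regions.

```{r, eval = FALSE}
library(lapreg)

scene <- generate_scene(phantom_spec(seed = 7, n_frames = 50))
state <- pipeline_init(scene$frames[[1]])
result <- process_frame(state, scene$frames[[30]])
result$diagnostics$inlier_ratio
```

## The per-frame pipeline

1. **Preprocessing.** The green channel is extracted (strongest tissue
   contrast), smoothed with a normalized 5×5 box filter, and contrast-
   equalized with CLAHE (8×8 tile grid, clip limit 2.0). In parallel a
   *glare mask* is computed on the raw green channel: only pixels strictly
   inside the intensity band (51, 204) — 20 % and 80 % of the 8-bit range —
   are usable, and the kept area is eroded with a 5×5 elliptical kernel so
   that feature detection never touches highlight or shadow boundaries.
2. **Features.** An oriented FAST-9/16 corner detector with 3×3 non-maximum
   suppression ranks corners by contrast response and keeps at most 1000.
   Each keypoint carries an intensity-centroid orientation and a rotated
   256-bit binary descriptor. Start- and current-frame descriptors are
   matched brute-force by Hamming distance with crosscheck (mutual nearest
   neighbours only); the best 20 % by distance are retained.
3. **Quality gate.** When the mean Hamming distance of the retained matches
   strictly exceeds the detector's threshold (35 for the 1000-keypoint
   detector; 55 and 65 are wired in for the A-KAZE and BRISK settings of the
   gate table), registration is abandoned for that frame and the unmodified
   current frame is shown. The thresholds correspond to robust-estimation
   inlier ratios of roughly 0.6 at the 5 px reprojection threshold.
4. **Transformations.**
   - *Single homography (SH)*: RANSAC over 4-point DLT models with a strict
     5 px transfer-error inlier rule, refit by Hartley-normalized DLT least
     squares on the consensus set. Seeded and reproducible.
   - *Hierarchical multi-affine (HMA)*: matches are clustered (k-means on
     positions and displacement vectors), each cluster is fit by a local
     RANSAC homography, incoherent clusters are bisected and refit, accepted
     clusters absorb unassigned matches that fit their model, and each
     surviving region keeps its own homography plus a convex-hull support
     polygon.
   - *Affine moving least squares (MLS)*: each vertex of a uniform 5 px
     lattice (grid density 0.2) receives a weighted least-squares affine fit
     to the control pairs with weights \(w_i = 1/\lVert p_i - v\rVert^{2\alpha}\);
     pixels between vertices are bilinearly interpolated.
5. **Fusion and display masking.** The start frame is warped by the SH and
   by every *valid* HMA region (area above 2 % of the image, entrywise
   \(\sum |H_{\mathrm{local}} - H_{\mathrm{SH}}| < 50\)). Per candidate an
   error image is built: absolute green-channel difference against the
   current frame, 255 where the warp has no source pixel, then a 35×35
   elliptical morphological closing. The candidate with the lowest error wins
   each pixel (ties go to the SH). Pixels whose combined error exceeds 10 %
   of the value range (> 25.5, i.e. ≥ 26 on integers) are suppressed after a
   35×35 binary majority median, and suppressed pixels show the original
   current frame. No frame is ever blocked: every failure path degrades to a
   passthrough of the live image.

## Evaluation protocol

`run_scene()` reproduces the ground-truth protocol: a start frame is
registered against every subsequent frame of a scene, the transform is
applied to the start-frame landmark annotations, and three measures are
recorded per frame — mean reprojection error (RE, px), mean normalized RE
(RE divided by each landmark's own moved distance, so the identity transform
scores exactly 1), and SSIM between the current frame and the warped start
frame (11×11 Gaussian window, σ = 1.5, K₁ = 0.01, K₂ = 0.03, dynamic range
255, on luma). Aggregation weights points equally within a frame, frames
equally within a scene, and scenes equally overall. The quality gate and
display masking are deliberately *not* applied during evaluation. The
`manual_sh` / `manual_mls` methods estimate the transform from the
annotations themselves and serve as the upper-bound reference rows of the
comparison table; `identity` provides the no-transformation baseline.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `glare$lower_frac`, `upper_frac` | 0.20 / 0.80 | usable intensity band as fractions of the 8-bit range |
| `box_size` | 5 px | box-filter side |
| `clahe$tiles`, `clahe$clip` | 8, 2.0 | CLAHE tile grid and clip limit |
| `max_keypoints` | 1000 | response-ranked keypoint cap |
| `fast_threshold` | 20 | FAST contrast threshold (intensity levels) |
| `match_fraction` | 0.20 | retained fraction of crosschecked matches |
| `gate_threshold` | 35/55/65 | mean-Hamming-distance gate per detector |
| `ransac$threshold` | 5 px | inlier transfer-error bound |
| `ransac$max_iter`, `confidence` | 2000, 0.995 | RANSAC iteration budget |
| `mls$grid_density`, `alpha` | 0.2, 1.0 | lattice density (spacing 5 px) and weight exponent |
| `fusion$closing_size` | 35 px | elliptical closing kernel for error images |
| `fusion$error_frac` | 0.10 | display-mask threshold fraction of range |
| `fusion$median_size` | 35 px | binary majority median window |
| `fusion$min_area_frac`, `max_h_diff` | 0.02, 50 | HMA region validity rules |
| `overlay_alpha` | 0.5 | blend weight of the color map |
| `seed` | 17 | RANSAC/k-means seed |

## Design choices made where the design was open

- **Glare band semantics.** The 20th/80th "percentile of the maximum value
  range" is read as fixed fractions of the 8-bit range (51 and 204), not as
  data quantiles: the phrase modifies the *range*, and fixed thresholds keep
  the mask stable under illumination drift. `glare$mode = "percentile"`
  preserves the data-driven alternative. Boundaries are strict (a pixel at
  exactly 51 or 204 is excluded).
- **Erosion and box-filter borders.** Erosion treats pixels outside the image
  as unusable, so the mask shrinks at the borders — features are never
  detected on unreliable border pixels. The box filter replicates borders to
  avoid darkened margins that would create false gradients.
- **CLAHE on the full image.** The mask restricts detection, not
  equalization; CLAHE runs on the whole frame. Because the tiled
  implementation requires dimensions divisible by the grid, frames are
  replicate-padded to the next multiple of the tile count and cropped back.
- **Detector.** The package ships one detector, an oriented FAST + rotated
  binary-descriptor design with a 1000-keypoint cap, registered as
  `"orb1000"`. It is single-octave: the intended deployment compensates
  breathing and small camera motion between an HSI record and the following
  seconds, where scale changes are small. The A-KAZE/BRISK/BEBLID
  configuration names are accepted (their gate thresholds are part of the
  quality-check table) but requesting them raises an error, as no
  implementation of those specific algorithms is bundled.
- **20 % retention.** Applied after crosscheck filtering, sorted by Hamming
  distance with index-order tie-breaking; the count is `ceiling(0.2 n)` so at
  least one match always survives.
- **RANSAC.** Maximum 2000 iterations with adaptive early termination at
  confidence 0.995 and a fixed default seed, so runs are bit-reproducible.
  The final model is refit on its inliers and the inlier set re-derived under
  the refit model, keeping the invariant that every inlier has transfer
  error strictly below the threshold.
- **MLS details.** The weight exponent α = 1 follows the deformation
  literature's common choice. "Grid density 20 %" becomes a lattice spacing
  of `round(1/0.2) = 5` px. A query point coinciding with a control point
  maps exactly to that control's target. For *warping* (as opposed to point
  mapping) the field must be a backward map, so `mls_backward_field()` builds
  it from reversed control pairs; point evaluation between vertices is
  bilinear, so control points not on lattice vertices are honored only up to
  interpolation error — visible in tests as sub-0.01 px residuals.
- **HMA hyperparameters.** Initial cluster count `clamp(round(n/50), 2, 10)`,
  split inlier-ratio 0.5, expansion threshold equal to the 5 px RANSAC
  threshold, minimum region size 4, maximum bisection depth 4. These are this
  package's own choices; tests pin the *behavior* (recovery of piecewise
  motions), not the constants.
- **Error images on raw green.** Candidate difference images are computed on
  raw green channels, not the CLAHE-equalized images, because local
  equalization would distort photometric error.
- **Median filter.** "35 pixels" is read as a 35×35 square window; on a
  binary mask the median is a majority vote, implemented exactly via
  integral-image window counts with the window clipped at borders (ties,
  possible only in clipped windows, resolve to "keep the overlay").
- **nRE guard.** Landmarks that moved less than 1e-6 px contribute to RE but
  are excluded from the nRE mean; an exact zero denominator must be guarded,
  and tiny motions otherwise inflate the statistic arbitrarily.
- **SSIM direction and fill.** SSIM compares the current frame against the
  warped start frame; warp pixels without a source are filled with the
  current frame's mean luma (`ssim_fill` offers `zero`/`current`
  alternatives). Filtering uses exact separable convolution with replicate
  borders, averaged over the full map.
- **Frame indices.** All coordinates are 0-based with x = column and
  y = row, matching the annotation tool; start frames 20/200/400/600 are
  0-based sequence indices, with `frame_index_base` available for 1-based
  comparison runs.

## The synthetic phantom

`generate_scene()` emulates the statistical structure the pipeline assumes,
with exact ground truth: a corner-rich base texture (thresholded band-limited
speckle for fine structure, smooth noise for illumination, dark curvilinear
vessel-like strokes) whose green histogram lies mostly inside the glare band;
smooth seeded homography motion that is the identity at frame 0 (sinusoidal
translation/rotation/zoom/perspective trajectories, peak translation 15 px —
the deployment regime of small camera drift); optional breathing-like
sinusoidal local deformation (default period 100 frames ≈ 15 cycles/min at
25 fps); specular glare disks (intensity ≥ 230) riding on the tissue; and an
optional dark instrument bar (intensity < 51, removed by the same mask that
removes real instrument shafts) that marks covered landmarks invisible.
Landmark tracks are the exactly mapped positions, exported and re-imported
through the CVAT XML dialect.

What the phantom does *not* model: photometric noise and motion blur,
rolling-shutter effects, large out-of-plane parallax, wet-surface specular
streaks, and true elastic tissue mechanics. Passing the phantom recovery
tests therefore demonstrates correctness of the estimation machinery, not
clinical-grade accuracy on real video; the deposited annotated recording
remains the benchmark for that, and the evaluation module reproduces its
published error levels when those files are supplied.

## Problem sizes and numerical tolerances in the tests

Unit tests use 240×160 scenes of 8 frames with 12 landmarks; recovery tests
use five seeded 854×480 scenes of 50 frames each; fusion oracles run
exhaustively on 64×64 crops; SSIM is verified against a direct double-loop
evaluation to 1e-9; MLS is verified to reproduce global affines at every
lattice vertex to 1e-6 px; homography recovery on contaminated data is held
to 0.5 px mean corner error, the feature-based pipeline on phantom scenes to
1 px, and the manual-annotation evaluator to 0.5 px. Degenerate inputs
(collinear point sets, empty match sets, all-invisible frames, points at
infinity under a perspective map) raise typed errors or flagged values
rather than propagating NaNs.

## Known limitations

- Frame input is a lossless PNG sequence (the canonical bit-exact test
  surface); compressed video containers must be unpacked before use.
- One detector family is bundled; descriptor-learning variants are exposed
  only as configuration names.
- The HMA region structure uses spatial and displacement clustering; no
  descriptor-space constraints are applied.
- MLS has no outlier rejection by construction, so with feature matches it
  inherits their gross errors — the reason it is an opt-in transform rather
  than the default, and the reason the default pipeline pairs SH with HMA
  region fusion.
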