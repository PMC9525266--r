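# lapreg

Feature-based registration of laparoscopic video for overlaying static
spectral image data — e.g. tissue-oxygenation (StO₂) maps from hyperspectral
imaging (HSI) — on the live view.

## The problem

Quantitative perfusion maps from HSI are not available at video frame rate:
a push-broom record takes seconds and yields one static false-color image.
`lapreg` aligns that static map with the moving laparoscopic view. During the
HSI record one video frame is saved as the **start frame**; every subsequent
frame *I_t* is registered to it, and the map — linked to the start frame by a
one-time sensor calibration homography *H_cal* — is warped through the
composed transform and alpha-blended over the grayscale live frame.

The per-frame chain is

1. green channel → 5×5 box filter → CLAHE (8×8 tiles, clip 2.0), with a glare
   mask that keeps only intensities strictly inside (51, 204) and erodes the
   kept area with a 5×5 elliptical kernel;
2. oriented FAST corners (≤ 1000, response-ranked) with rotated 256-bit
   binary descriptors, matched by Hamming distance with crosscheck, best 20 %
   retained;
3. a quality gate: if the mean matching distance exceeds the detector
   threshold (35 for the 1000-keypoint detector) the original frame is shown;
4. transformation estimation — single homography *H* via RANSAC
   (inlier rule: transfer error < 5 px) with normalized-DLT refit,
   optionally hierarchical multi-affine (HMA) region homographies and an
   affine moving-least-squares (MLS) deformation field
   (5 px lattice, weights *w_i = 1/‖p_i − v‖^{2α}*);
5. per-pixel fusion of candidate warps by lowest closed photometric error
   (35×35 elliptical closing) and a display mask that suppresses pixels with
   error above 10 % of the intensity range (35×35 majority median).

The evaluation module implements the ground-truth protocol: reprojection
error (RE) of transformed landmark annotations, RE normalized by each
landmark's own moved distance (identity transform ⇒ exactly 1), and SSIM,
aggregated frame → scene → overall. Annotations are read and written in the
CVAT "annotations 1.1" point-track XML dialect. A seeded synthetic phantom
generator supplies scenes with exact ground truth (known homography paths,
glare, occluders, landmark tracks), so everything is testable offline.

## Worked example

```r
library(lapreg)

# a seeded 30-frame phantom scene with exact ground truth
scene <- generate_scene(phantom_spec(seed = 7, n_frames = 30))

# live-augmentation pipeline against frame 24
state <- pipeline_init(scene$frames[[1]])
res <- process_frame(state, scene$frames[[25]])
str(res$diagnostics[c("gated", "mean_distance", "n_matches", "inlier_ratio")])
#> List of 4
#>  $ gated        : logi FALSE
#>  $ mean_distance: num 9.34
#>  $ n_matches    : int 148
#>  $ inlier_ratio : num 1

# ground-truth evaluation of three methods over the scene
run_scene(scene$frames, scene$annotations, "identity",   start_frame = 0,
          compute_ssim_per_frame = FALSE)
#> <registration_metrics: identity, start 0 | RE 3.85 px, nRE 1.000, SSIM NaN>
run_scene(scene$frames, scene$annotations, "feature_sh", start_frame = 0,
          compute_ssim_per_frame = FALSE)
#> <registration_metrics: feature_sh, start 0 | RE 0.07 px, nRE 0.078, SSIM NaN>
run_scene(scene$frames, scene$annotations, "manual_sh",  start_frame = 0,
          compute_ssim_per_frame = FALSE)
#> <registration_metrics: manual_sh, start 0 | RE 0.00 px, nRE 0.000, SSIM NaN>
```

Reading the numbers: the landmarks moved 3.85 px on average (the identity
row — doing nothing — has normalized RE exactly 1 by construction). The
feature-based single homography brings the mean reprojection error down to
0.07 px on this rigid-motion phantom, close to the manual-annotation upper
bound of ~0 px. SSIM is `NaN` only because its computation was switched off
here for speed.

A thin command-line front end over the same functions ships in
`inst/scripts/lapreg.R` (`simulate`, `preprocess`, `features`, `register`,
`evaluate`, `overlay`, `run` subcommands).

## Package layout

- `R/io_formats.R` — PNG frame sequences, CVAT XML, calibration CSV, YAML config
- `R/preprocess.R` — green channel, glare mask, box filter + CLAHE
- `R/features.R` — detector/descriptor, crosschecked matching, quality gate
- `R/transforms.R` — RANSAC homography, HMA regions, MLS fields, warping
- `R/fusion.R` — region validity, error images, per-pixel fusion, display mask
- `R/evaluation.R` — RE / normalized RE / SSIM, scenes, aggregation
- `R/hsi_overlay.R` — sensor calibration, false-color mapping, overlay rendering
- `R/synthetic.R` — seeded phantom scenes with exact ground truth
- `R/pipeline.R` — end-to-end per-frame loop with passthrough guarantees

The methods vignette (`vignettes/registration-methods.Rmd`) documents the
models, parameter semantics, numerical choices, and known limitations.
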