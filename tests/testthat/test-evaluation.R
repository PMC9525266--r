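simple_ann <- function() {
  # 3 landmarks over 2 frames with known motion
  tracks <- list(
    list(track_id = 0L, points = data.frame(frame = 0:1, x = c(10, 14),
                                            y = c(10, 13), visible = TRUE)),
    list(track_id = 1L, points = data.frame(frame = 0:1, x = c(50, 50),
                                            y = c(40, 56), visible = TRUE)),
    list(track_id = 2L, points = data.frame(frame = 0:1, x = c(80, 80),
                                            y = c(80, 80), visible = TRUE)))
  annotation_set(tracks, 2, c(100, 100))
}

test_that("point errors implement RE, moved distance, and normalized RE", {
  ann <- simple_ann()
  pe <- point_errors("identity", ann, 0, 1)
  expect_equal(pe$re, c(5, 16, 0)) # (4,3) -> 5; (0,16) -> 16; no motion -> 0
  expect_equal(pe$moved, c(5, 16, 0))
  # identity: nRE exactly 1 for landmarks that moved; unmoved one excluded
  expect_equal(pe$nre[1:2], c(1, 1))
  expect_true(is.na(pe$nre[3]))
  expect_equal(mean(pe$nre, na.rm = TRUE), 1)

  # a perfect transform gives RE 0 everywhere: the affine through the three
  # landmark motions
  src <- rbind(c(10, 10), c(50, 40), c(80, 80))
  dst <- rbind(c(14, 13), c(50, 56), c(80, 80))
  A <- t(solve(cbind(src, 1), dst)) # 2 x 3 affine coefficients
  pe2 <- point_errors(rbind(A, c(0, 0, 1)), ann, 0, 1)
  expect_lt(max(pe2$re), 1e-6)

  # plain ratio: RE 4 with moved 16 gives nRE 0.25
  shift4 <- matrix(c(1, 0, 0, 0, 1, 4, 0, 0, 1), 3, 3, byrow = TRUE)
  pe3 <- point_errors(shift4, ann, 0, 1)
  expect_equal(pe3$re[2], 12) # mapped 4 px short of a 16 px motion
  expect_equal(pe3$nre[2], 0.75)

  # RE is invariant to relabeling track ids
  ann2 <- ann
  ann2$tracks <- rev(ann2$tracks)
  pe4 <- point_errors("identity", ann2, 0, 1)
  expect_setequal(round(pe4$re, 9), round(pe$re, 9))
})

test_that("SSIM matches direct formula evaluation and is symmetric", {
  expect_equal(compute_ssim(matrix(100L, 16, 16), matrix(100L, 16, 16)), 1)

  set.seed(30)
  a <- matrix(sample(0:255, 64, TRUE), 8, 8)
  b <- matrix(sample(0:255, 64, TRUE), 8, 8)
  expect_lt(abs(compute_ssim(a, b) - bf_ssim(a, b)), 1e-9)
  expect_equal(compute_ssim(a, b), compute_ssim(b, a))

  a2 <- matrix(sample(0:255, 24 * 20, TRUE), 24, 20)
  b2 <- lapreg:::as_mono(a2 + matrix(rnorm(480, 0, 25), 24, 20))
  expect_lt(abs(compute_ssim(a2, b2) - bf_ssim(a2, b2)), 1e-9)
  expect_lt(compute_ssim(a2, b2), 1)
  expect_error(compute_ssim(a, a2), "shape")
})

test_that("a static scene evaluates to zero error and a moving one to nRE 1", {
  static_spec <- phantom_spec(seed = 31, size = c(160L, 120L), n_frames = 4,
                              n_landmarks = 8, max_translation = 0,
                              max_rotation = 0, max_scale = 0,
                              max_perspective = 0, n_glare = 0)
  sc <- generate_scene(static_spec)
  m <- run_scene(sc$frames, sc$annotations, "identity", start_frame = 0,
                 compute_ssim_per_frame = FALSE)
  expect_equal(m$scene_mean_re, 0)

  sc2 <- small_scene()
  m2 <- run_scene(sc2$frames, sc2$annotations, "identity", start_frame = 0,
                  compute_ssim_per_frame = FALSE)
  expect_equal(m2$scene_mean_nre, 1)
  expect_gt(m2$scene_mean_re, 0)
})

test_that("ground-truth transforms recover exact homography motion", {
  sc <- small_scene()
  # landmarks move under an exact homography, so the manual-annotation fit
  # must recover it and the MLS field must interpolate it closely
  m_sh <- run_scene(sc$frames, sc$annotations, "manual_sh", start_frame = 0,
                    compute_ssim_per_frame = FALSE)
  expect_lt(m_sh$scene_mean_re, 0.1)

  tr <- ground_truth_transform(sc$annotations, 0, 3, mode = "sh")
  expect_lt(corner_error(tr$H, sc$true_transforms[[4]],
                         c(240, 160)), 0.5)
  tr_mls <- ground_truth_transform(sc$annotations, 0, 3, mode = "mls")
  expect_s3_class(tr_mls, "deformation_field")
  pe <- point_errors(tr_mls, sc$annotations, 0, 3)
  # control points are honored up to bilinear interpolation on the 5 px lattice
  expect_lt(mean(pe$re), 1e-3)
})

test_that("scene aggregation averages scene means without weighting", {
  sc <- small_scene()
  m <- run_scene(sc$frames, sc$annotations, "identity", start_frame = 0,
                 compute_ssim_per_frame = FALSE)
  one <- aggregate_scenes(list(m))
  expect_equal(one$mean_re, m$scene_mean_re)
  expect_equal(one$n_scenes, 1)
  four <- aggregate_scenes(list(m, m, m, m))
  expect_equal(four$mean_re, m$scene_mean_re)
  expect_equal(four$mean_nre, m$scene_mean_nre)

  # permutation invariance over frames within a scene
  expect_equal(mean(rev(m$per_frame$mean_re)), mean(m$per_frame$mean_re))
})

test_that("landmark jitter keeps manual-annotation error near the noise floor", {
  # smooth homography motion plus 0.5 px Gaussian annotation jitter: the
  # manual SH evaluator should stay within 3 sigma
  sc <- small_scene()
  sigma <- 0.5
  ann <- sc$annotations
  set.seed(33)
  ann$tracks <- lapply(ann$tracks, function(t) {
    t$points$x <- lapreg:::clamp(t$points$x + rnorm(nrow(t$points), 0, sigma),
                                 0, 239)
    t$points$y <- lapreg:::clamp(t$points$y + rnorm(nrow(t$points), 0, sigma),
                                 0, 159)
    t
  })
  m <- run_scene(sc$frames, ann, "manual_sh", start_frame = 0,
                 compute_ssim_per_frame = FALSE)
  expect_lt(m$scene_mean_re, 3 * sigma)
})
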