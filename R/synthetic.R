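# Synthetic laparoscopy-like fixtures with exact ground truth: textured
# phantom frames under known homography (plus optional smooth local
# deformation), glare spots, an instrument-like occluder, CVAT-compatible
# landmark tracks, and calibration fixtures. Everything is seeded and
# bit-reproducible, so the generators double as oracles for the registration
# and evaluation modules.

#' Specification of a synthetic phantom scene
#'
#' The defaults mirror the reference recording conditions: 854 x 480 frames,
#' 28 landmarks, 750 frames per scene (tests use far fewer), smooth
#' perspective camera motion, breathing-like periodic deformation, glare
#' spots, and an optional dark instrument bar that occludes landmarks.
#'
#' @param seed Integer seed; same seed and spec give bit-identical scenes.
#' @param size `c(W, H)` in pixels (default `c(854, 480)`).
#' @param n_landmarks Number of evenly spaced landmarks (default 28).
#' @param n_frames Frames in the scene (default 750).
#' @param max_translation Peak camera translation in px (default 15).
#' @param max_rotation Peak in-plane rotation in radians (default 0.02).
#' @param max_scale Peak relative zoom (default 0.02).
#' @param max_perspective Peak projective coefficient (default 2e-6).
#' @param motion_period Frames per camera-motion cycle (default 250).
#' @param deform_amplitude Local deformation amplitude in px (0 disables;
#'   default 0).
#' @param breathing_period Frames per deformation cycle (default 100,
#'   i.e. ~15 cycles/min at 25 fps).
#' @param n_glare Number of injected specular spots (default 6).
#' @param glare_radius Glare spot radius in px (default 12).
#' @param occluder Render a moving dark instrument bar (default FALSE).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L, size = c(854L, 480L), n_landmarks = 28L,
                         n_frames = 750L, max_translation = 15,
                         max_rotation = 0.02, max_scale = 0.02,
                         max_perspective = 2e-6, motion_period = 250,
                         deform_amplitude = 0, breathing_period = 100,
                         n_glare = 6L, glare_radius = 12, occluder = FALSE) {
  structure(as.list(environment()), class = "phantom_spec")
}

# Smooth band-limited noise in [0,1], seeded by the caller.
smooth_noise <- function(H, W, sigma) {
  n <- matrix(runif(H * W), H, W)
  k <- gaussian_kernel1d(2L * ceiling(2 * sigma) + 1L, sigma)
  s <- conv_sep(n, k)
  (s - min(s)) / (max(s) - min(s) + 1e-12)
}

#' Generate the phantom base texture
#'
#' Band-limited multi-scale noise with vessel-like curvilinear structures,
#' tuned so the green channel is mid-range dominant (most of its histogram
#' inside the glare-mask band (51, 204)) and rich in corners, so the detector
#' and the glare thresholds are both exercised.
#'
#' @param spec A [phantom_spec()].
#' @return A [frame_image()].
#' @export
generate_phantom_texture <- function(spec) {
  W <- spec$size[1]; H <- spec$size[2]
  with_seed(spec$seed, {
    # hard-edged speckle blobs (thresholded band-limited noise) provide the
    # corner-rich fine structure; smooth components modulate illumination
    fine <- as.numeric(smooth_noise(H, W, 1.2) > 0.5)
    mid <- smooth_noise(H, W, 4)
    coarse <- smooth_noise(H, W, 16)
    tex <- 0.45 * fine + 0.35 * mid + 0.20 * coarse
    # vessel-like dark curvilinear structures: smooth random walks
    vessels <- matrix(0, H, W)
    for (v in seq_len(14)) {
      x <- runif(1, 0, W - 1); y <- runif(1, 0, H - 1)
      ang <- runif(1, 0, 2 * pi)
      width <- sample(1:2, 1)
      for (s in seq_len(600)) {
        ang <- ang + rnorm(1, 0, 0.15)
        x <- x + cos(ang); y <- y + sin(ang)
        if (x < width + 1 || x > W - width - 2 || y < width + 1 || y > H - width - 2) break
        xi <- round(x); yi <- round(y)
        vessels[(yi + 1 - width):(yi + 1 + width), (xi + 1 - width):(xi + 1 + width)] <- 1
      }
    }
    k <- gaussian_kernel1d(5L, 1.0)
    vessels <- conv_sep(vessels, k)
    g <- 100 + 90 * tex - 45 * vessels # mid-range dominant green
    r <- 120 + 70 * tex - 20 * vessels
    b <- 60 + 50 * tex
    px <- array(0, c(H, W, 3))
    px[, , 1] <- clamp(round(r), 0, 255)
    px[, , 2] <- clamp(round(g), 0, 255)
    px[, , 3] <- clamp(round(b), 0, 255)
    frame_image(px, 0L)
  })
}

# Smooth homography path: identity at t = 0, sinusoidal parameter
# trajectories with seed-derived phases afterwards.
phantom_homography <- function(spec, t, phases) {
  W <- spec$size[1]; H <- spec$size[2]
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  s <- sin(2 * pi * t / spec$motion_period + phases) -
    sin(phases) # zero at t = 0
  tx <- spec$max_translation * s[1]
  ty <- spec$max_translation * s[2]
  th <- spec$max_rotation * s[3]
  sc <- 1 + spec$max_scale * s[4]
  px <- spec$max_perspective * s[5]
  py <- spec$max_perspective * s[6]
  # rotate/scale about the image center, then translate, then perspective
  Tc <- matrix(c(1, 0, -cx, 0, 1, -cy, 0, 0, 1), 3, 3, byrow = TRUE)
  R <- matrix(c(sc * cos(th), -sc * sin(th), 0,
                sc * sin(th), sc * cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Tb <- matrix(c(1, 0, cx + tx, 0, 1, cy + ty, 0, 0, 1), 3, 3, byrow = TRUE)
  P <- matrix(c(1, 0, 0, 0, 1, 0, px, py, 1), 3, 3, byrow = TRUE)
  normalize_h(Tb %*% R %*% Tc %*% P)
}

# Backward deformation displacement (added to the inverse-homography source
# position), breathing-like low-frequency sinusoid; zero at t = 0.
phantom_deformation <- function(spec, t, xs, ys, phases) {
  if (spec$deform_amplitude == 0) return(cbind(0 * xs, 0 * ys))
  W <- spec$size[1]; H <- spec$size[2]
  amp <- spec$deform_amplitude * sin(2 * pi * t / spec$breathing_period)
  dx <- amp * sin(2 * pi * ys / H + phases[7]) * cos(2 * pi * xs / (2 * W))
  dy <- amp * cos(2 * pi * xs / W + phases[8]) * sin(2 * pi * ys / (2 * H))
  cbind(dx, dy)
}

occluder_polygon <- function(spec, t) {
  # instrument-like bar sweeping across the lower image half
  W <- spec$size[1]; H <- spec$size[2]
  u <- (t / max(spec$n_frames - 1, 1))
  x0 <- -0.1 * W + 1.2 * W * u
  ang <- pi / 3
  len <- 1.2 * H; wid <- max(0.05 * W, 6)
  dir <- c(cos(ang), sin(ang))
  nrm <- c(-sin(ang), cos(ang))
  base <- c(x0, H * 0.25)
  rbind(base + wid * nrm, base - wid * nrm,
        base - wid * nrm + len * dir, base + wid * nrm + len * dir)
}

point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi + 1e-30) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Generate a full synthetic scene with exact ground truth
#'
#' Frame `t` is the base texture warped by a known smooth homography `H_t`
#' (optionally plus a smooth breathing-like deformation), with bright glare
#' spots (intensity >= 230) and, optionally, a dark instrument bar
#' (intensity < 51, so the glare/dark mask removes it like a real instrument
#' shaft). Landmark tracks are the exactly mapped positions, marked invisible
#' under the occluder or outside the image. The true transforms are returned
#' so tests can use the generator as an oracle.
#'
#' @param spec A [phantom_spec()].
#' @return List with `frames` (list of [frame_image()]), `annotations`
#'   (an [annotation_set()]), `true_transforms` (list of 3 x 3 matrices,
#'   start -> frame t), `glare` (per-frame spot centers), and `spec`.
#' @export
generate_scene <- function(spec) {
  W <- spec$size[1]; H <- spec$size[2]
  base <- generate_phantom_texture(spec)
  scene_seed <- spec$seed + 1000L
  with_seed(scene_seed, {
    phases <- runif(8, 0, 2 * pi)
    # landmarks on an even grid with jitter, away from the borders
    nl <- spec$n_landmarks
    gw <- ceiling(sqrt(nl * W / H)); gh <- ceiling(nl / gw)
    gx <- seq(0.12, 0.88, length.out = gw) * (W - 1)
    gy <- seq(0.12, 0.88, length.out = gh) * (H - 1)
    lm <- cbind(rep(gx, each = gh), rep(gy, times = gw))[seq_len(nl), ]
    lm <- lm + matrix(runif(2 * nl, -8, 8), nl, 2)
    glare_pos <- cbind(runif(spec$n_glare, 0.1, 0.9) * W,
                       runif(spec$n_glare, 0.1, 0.9) * H)
  })
  xs_all <- rep(0:(W - 1), each = H)
  ys_all <- rep(0:(H - 1), times = W)
  base_chans <- lapply(1:3, function(c)
    matrix(as.numeric(base$pixels[, , c]), H, W))
  frames <- vector("list", spec$n_frames)
  transforms <- vector("list", spec$n_frames)
  track_pts <- vector("list", spec$n_frames)
  deformed <- spec$deform_amplitude > 0
  for (t in seq_len(spec$n_frames) - 1L) {
    Ht <- phantom_homography(spec, t, phases)
    transforms[[t + 1]] <- Ht
    if (t == 0) {
      px <- base$pixels
      valid <- matrix(TRUE, H, W)
    } else {
      Hinv <- solve(Ht)
      src <- apply_homography_to_points(Hinv, cbind(xs_all, ys_all))
      d <- phantom_deformation(spec, t, xs_all, ys_all, phases)
      sx <- src[, 1] + d[, 1]; sy <- src[, 2] + d[, 2]
      px <- array(0L, c(H, W, 3))
      valid <- NULL
      for (c in 1:3) {
        res <- cpp_bilinear_sample(base_chans[[c]], sx, sy)
        v <- res$values; v[!res$valid] <- 0
        px[, , c] <- as_mono(matrix(v, H, W))
        if (c == 1) valid <- matrix(res$valid, H, W)
      }
    }
    # landmark forward positions: invert the backward map per landmark
    if (t == 0) {
      pt <- lm
    } else {
      pt <- apply_homography_to_points(Ht, lm)
      if (deformed) {
        # solve H^-1(x) + d(x) = p by fixed-point iteration (d is small/smooth)
        for (it in 1:8) {
          d <- phantom_deformation(spec, t, pt[, 1], pt[, 2], phases)
          pt <- apply_homography_to_points(Ht, lm - d)
        }
      }
    }
    # glare spots ride on the tissue (mapped by the forward homography)
    gl <- apply_homography_to_points(Ht, glare_pos)
    for (g in seq_len(nrow(gl))) {
      cx <- gl[g, 1]; cy <- gl[g, 2]
      if (is.na(cx)) next
      x0 <- max(0, floor(cx - spec$glare_radius))
      x1 <- min(W - 1, ceiling(cx + spec$glare_radius))
      y0 <- max(0, floor(cy - spec$glare_radius))
      y1 <- min(H - 1, ceiling(cy + spec$glare_radius))
      if (x0 > x1 || y0 > y1) next
      xs <- x0:x1; ys <- y0:y1
      d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
      hit <- d2 <= spec$glare_radius^2
      for (c in 1:3) {
        plane <- px[ys + 1, xs + 1, c]
        plane[hit] <- pmax(plane[hit], 230L + as.integer(round(25 * (1 - sqrt(d2[hit]) / spec$glare_radius))))
        px[ys + 1, xs + 1, c] <- pmin(plane, 255L)
      }
    }
    occluded <- rep(FALSE, nrow(lm))
    if (spec$occluder) {
      poly <- occluder_polygon(spec, t)
      inside <- matrix(point_in_polygon(xs_all, ys_all, poly), H, W)
      for (c in 1:3) {
        plane <- px[, , c]
        plane[inside] <- as.integer(round(c(28, 30, 34)[c] * 0.9))
        px[, , c] <- plane
      }
      occluded <- point_in_polygon(pt[, 1], pt[, 2], poly)
    }
    visible <- !occluded & pt[, 1] >= 0 & pt[, 1] <= W - 1 &
      pt[, 2] >= 0 & pt[, 2] <= H - 1
    track_pts[[t + 1]] <- data.frame(frame = t, x = clamp(pt[, 1], 0, W - 1),
                                     y = clamp(pt[, 2], 0, H - 1),
                                     visible = visible)
    frames[[t + 1]] <- frame_image(px, t)
  }
  tracks <- lapply(seq_len(nrow(lm)), function(i) {
    d <- do.call(rbind, lapply(track_pts, function(tp) tp[i, , drop = FALSE]))
    rownames(d) <- NULL
    list(track_id = i - 1L, points = d)
  })
  ann <- annotation_set(tracks, spec$n_frames, spec$size)
  list(frames = frames, annotations = ann, true_transforms = transforms,
       glare = glare_pos, spec = spec)
}

#' Generate a sensor-calibration fixture
#'
#' A smooth synthetic physiological map, a known ground-truth calibration
#' homography, and annotated point pairs (default 25, matching the reference
#' one-time calibration), optionally perturbed by Gaussian noise.
#'
#' @param seed Integer seed.
#' @param n_pairs Number of annotated pairs (default 25).
#' @param sigma Gaussian annotation noise in px (default 0).
#' @param map_size Spectral image `c(W, H)` (default `c(180, 135)`, a scaled
#'   push-broom sensor geometry).
#' @param frame_size Color-sensor `c(W, H)` (default `c(854, 480)`).
#' @return List with `map` (a [physio_map()]), `H_true` (3 x 3), and `pairs`
#'   (data frame for [calibrate_sensors()]).
#' @export
generate_calibration_fixture <- function(seed = 1L, n_pairs = 25L, sigma = 0,
                                         map_size = c(180L, 135L),
                                         frame_size = c(854L, 480L)) {
  W <- map_size[1]; H <- map_size[2]
  with_seed(seed, {
    vals <- smooth_noise(H, W, 10)
    # map spectral coords into a central window of the color frame
    sx <- 0.8 * frame_size[1] / W
    sy <- 0.8 * frame_size[2] / H
    th <- runif(1, -0.05, 0.05)
    H_true <- normalize_h(matrix(c(sx * cos(th), -sx * sin(th), 0.08 * frame_size[1],
                                   sy * sin(th), sy * cos(th), 0.08 * frame_size[2],
                                   runif(1, -1e-5, 1e-5), runif(1, -1e-5, 1e-5), 1),
                                 3, 3, byrow = TRUE))
    src <- cbind(runif(n_pairs, 0, W - 1), runif(n_pairs, 0, H - 1))
    dst <- apply_homography_to_points(H_true, src) +
      matrix(rnorm(2 * n_pairs, 0, sigma), n_pairs, 2)
    list(map = physio_map(vals),
         H_true = H_true,
         pairs = data.frame(x_src = src[, 1], y_src = src[, 2],
                            x_dst = dst[, 1], y_dst = dst[, 2]))
  })
}
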