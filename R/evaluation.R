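# Ground-truth evaluation protocol: reprojection error (RE), normalized RE,
# SSIM, scene construction from start frames, and table-style aggregation.

map_points <- function(transform, points) {
  if (is.character(transform) && transform == "identity") return(points)
  if (inherits(transform, "deformation_field"))
    return(apply_field_to_points(transform, points))
  apply_homography_to_points(transform, points)
}

#' Per-landmark reprojection errors between two frames
#'
#' For every landmark visible in both frames the start-frame position is
#' mapped by the transform and compared with the annotated current-frame
#' position: `RE = |T(p_start) - p_current|`, `moved = |p_start - p_current|`,
#' `nRE = RE / moved`. The identity transform therefore has `nRE = 1` for
#' every landmark that moved. Landmarks whose moved distance is below
#' `min_moved` contribute to RE but are excluded from the nRE mean (their
#' normalization would be undefined or arbitrarily inflated).
#'
#' @param transform `"identity"`, a homography, or a `deformation_field`
#'   mapping start-frame to current-frame coordinates.
#' @param annotations An [annotation_set()].
#' @param start_frame,current_frame 0-based frame indices.
#' @param min_moved Moved-distance floor below which nRE is excluded
#'   (default 1e-6 px).
#' @return Data frame with `track_id`, `re`, `moved`, `nre` (NA when
#'   excluded); empty when no landmark is co-visible.
#' @export
point_errors <- function(transform, annotations, start_frame, current_frame,
                         min_moved = 1e-6) {
  cov <- covisible_points(annotations, start_frame, current_frame)
  if (nrow(cov) == 0)
    return(data.frame(track_id = integer(), re = numeric(), moved = numeric(),
                      nre = numeric()))
  p0 <- cbind(cov$xa, cov$ya)
  p1 <- cbind(cov$xb, cov$yb)
  mapped <- map_points(transform, p0)
  re <- sqrt(rowSums((mapped - p1)^2))
  moved <- sqrt(rowSums((p0 - p1)^2))
  nre <- ifelse(moved < min_moved, NA_real_, re / moved)
  data.frame(track_id = cov$track_id, re = re, moved = moved, nre = nre)
}

#' Structural similarity between two mono images
#'
#' Standard SSIM with an 11 x 11 Gaussian window (sigma 1.5), K1 = 0.01,
#' K2 = 0.03, dynamic range 255, averaged over the full map. Filtering uses
#' replicate borders and exact (non-FFT) separable convolution.
#'
#' @param reference,test H x W mono images (0-255), same shape.
#' @return SSIM value in \[-1, 1\].
#' @export
compute_ssim <- function(reference, test) {
  if (!identical(dim(reference), dim(test)))
    stop("SSIM inputs must have the same shape", call. = FALSE)
  a <- matrix(as.numeric(reference), nrow(reference))
  b <- matrix(as.numeric(test), nrow(test))
  k <- gaussian_kernel1d(11L, 1.5)
  L <- 255
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  mu_a <- conv_sep(a, k); mu_b <- conv_sep(b, k)
  var_a <- conv_sep(a * a, k) - mu_a^2
  var_b <- conv_sep(b * b, k) - mu_b^2
  cov_ab <- conv_sep(a * b, k) - mu_a * mu_b
  ssim_map <- ((2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2))
  mean(ssim_map)
}

#' Ground-truth ("manual annotation") transform between two frames
#'
#' The upper-bound reference rows of the comparison table: the transform is
#' estimated from the annotated landmarks themselves, either as a RANSAC
#' homography (threshold 5 px) or as an affine MLS deformation field with the
#' co-visible landmarks as control points.
#'
#' @param annotations An [annotation_set()].
#' @param start_frame,current_frame 0-based frame indices.
#' @param mode `"sh"` or `"mls"`.
#' @param seed RANSAC seed.
#' @param config Configuration list (RANSAC threshold, MLS density/alpha).
#' @return A `homography_transform` or `deformation_field`, or `NULL` when
#'   too few landmarks are co-visible (4 for SH, 3 for MLS).
#' @export
ground_truth_transform <- function(annotations, start_frame, current_frame,
                                   mode = c("sh", "mls"), seed = 17,
                                   config = default_config()) {
  mode <- match.arg(mode)
  cov <- covisible_points(annotations, start_frame, current_frame)
  p0 <- cbind(cov$xa, cov$ya); p1 <- cbind(cov$xb, cov$yb)
  if (mode == "sh") {
    if (nrow(cov) < 4) return(NULL)
    estimate_single_homography(list(src = p0, dst = p1),
                               threshold = config$ransac$threshold,
                               seed = seed,
                               max_iter = config$ransac$max_iter,
                               confidence = config$ransac$confidence)
  } else {
    if (nrow(cov) < 3) return(NULL)
    estimate_mls_field(list(p = p0, q = p1), annotations$image_size,
                       grid_density = config$mls$grid_density,
                       alpha = config$mls$alpha)
  }
}

# Estimate the start->current transform for one frame under a given method.
# Returns list(transform, backward) where backward warps start into current
# geometry, or NULL on failure.
estimate_frame_transform <- function(method, start_ctx, current, annotations,
                                     start_frame, current_frame, config, seed) {
  if (method == "identity") {
    H <- diag(3)
    return(list(transform = "identity", backward = H))
  }
  if (method %in% c("manual_sh", "manual_mls")) {
    mode <- sub("manual_", "", method)
    tr <- ground_truth_transform(annotations, start_frame, current_frame,
                                 mode = mode, seed = seed, config = config)
    if (is.null(tr)) return(NULL)
    backward <- if (mode == "sh") tr else {
      cov <- covisible_points(annotations, start_frame, current_frame)
      mls_backward_field(list(p = cbind(cov$xa, cov$ya),
                              q = cbind(cov$xb, cov$yb)),
                         annotations$image_size,
                         grid_density = config$mls$grid_density,
                         alpha = config$mls$alpha)
    }
    return(list(transform = tr, backward = backward))
  }
  # feature-based methods need the video frames
  pp <- preprocess_frame(current, config)
  kp <- detect_describe(pp$mono, pp$mask, detector = config$detector,
                        descriptor = config$descriptor,
                        max_keypoints = config$max_keypoints,
                        fast_threshold = config$fast_threshold)
  matches <- match_features(start_ctx$keypoints, kp,
                            retain_fraction = config$match_fraction)
  if (nrow(matches$pairs) < 4) return(NULL)
  if (method == "feature_sh") {
    tr <- tryCatch(
      estimate_single_homography(matches, threshold = config$ransac$threshold,
                                 seed = seed,
                                 max_iter = config$ransac$max_iter,
                                 confidence = config$ransac$confidence),
      error = function(e) NULL)
    if (is.null(tr)) return(NULL)
    return(list(transform = tr, backward = tr, matches = matches))
  }
  if (method == "feature_mls") {
    tr <- tryCatch(
      estimate_mls_field(matches, start_ctx$image_size,
                         grid_density = config$mls$grid_density,
                         alpha = config$mls$alpha),
      error = function(e) NULL)
    if (is.null(tr)) return(NULL)
    bw <- mls_backward_field(matches, start_ctx$image_size,
                             grid_density = config$mls$grid_density,
                             alpha = config$mls$alpha)
    return(list(transform = tr, backward = bw, matches = matches))
  }
  stop("unknown method: ", method, call. = FALSE)
}

#' Run the evaluation protocol over one scene
#'
#' A scene is a start frame registered against every subsequent frame up to
#' the last. For each frame the transform is estimated with the chosen method,
#' the per-landmark reprojection errors are computed, and SSIM is measured
#' between the current frame and the warped start frame (invalid warp pixels
#' filled with the current frame's mean luma). As in the reference protocol,
#' the quality gate and display-mask postprocessing are NOT applied here. A
#' frame on which the method fails is recorded with the identity transform and
#' flagged.
#'
#' @param frames List of [frame_image()] covering the scene (indices must
#'   include the start and all evaluated frames).
#' @param annotations An [annotation_set()] (may be `NULL` for SSIM-only runs
#'   of feature methods).
#' @param method One of `"identity"`, `"manual_sh"`, `"manual_mls"`,
#'   `"feature_sh"`, `"feature_mls"`.
#' @param start_frame 0-based start-frame index (scene defaults: 20, 200,
#'   400, 600).
#' @param last_frame 0-based last frame of the scene (default: last frame
#'   available).
#' @param config Configuration list.
#' @param compute_ssim_per_frame Set FALSE to skip SSIM (faster; RE only).
#' @return Object of class `registration_metrics` with `per_frame` (data
#'   frame: `frame`, `mean_re`, `mean_nre`, `ssim`, `n_points`, `flagged`)
#'   and scene means `scene_mean_re`, `scene_mean_nre`, `scene_mean_ssim`.
#' @export
run_scene <- function(frames, annotations, method, start_frame,
                      last_frame = NULL, config = default_config(),
                      compute_ssim_per_frame = TRUE) {
  idx <- vapply(frames, function(f) f$frame_index, integer(1))
  names(frames) <- as.character(idx)
  if (is.null(last_frame)) last_frame <- max(idx)
  stopifnot(start_frame < last_frame)
  start <- frames[[as.character(start_frame)]]
  if (is.null(start)) stop("start frame not in sequence", call. = FALSE)
  needs_frames <- startsWith(method, "feature_") || compute_ssim_per_frame
  start_ctx <- list(image_size = c(dim(start$pixels)[2], dim(start$pixels)[1]))
  if (startsWith(method, "feature_")) {
    pp <- preprocess_frame(start, config)
    start_ctx$keypoints <- detect_describe(pp$mono, pp$mask,
                                           detector = config$detector,
                                           descriptor = config$descriptor,
                                           max_keypoints = config$max_keypoints,
                                           fast_threshold = config$fast_threshold)
  }
  start_luma <- if (compute_ssim_per_frame) frame_luma(start) else NULL
  eval_frames <- idx[idx > start_frame & idx <= last_frame]
  rows <- lapply(sort(eval_frames), function(f) {
    current <- frames[[as.character(f)]]
    est <- estimate_frame_transform(method, start_ctx, current, annotations,
                                    start_frame, f, config, config$seed)
    flagged <- is.null(est)
    if (flagged) est <- list(transform = "identity", backward = diag(3))
    pe <- if (!is.null(annotations))
      point_errors(est$transform, annotations, start_frame, f,
                   min_moved = config$nre_min_moved)
    else data.frame(re = numeric(), nre = numeric())
    ssim <- NA_real_
    if (compute_ssim_per_frame) {
      wr <- warp_image(start_luma, est$backward)
      cur_luma <- frame_luma(current)
      warped <- frame_pixels(wr$image)
      fill <- switch(config$ssim_fill,
                     mean = round(mean(cur_luma)),
                     zero = 0L,
                     current = cur_luma)
      if (config$ssim_fill == "current") warped[!wr$validity] <- cur_luma[!wr$validity]
      else warped[!wr$validity] <- fill
      ssim <- compute_ssim(cur_luma, warped)
    }
    data.frame(frame = f,
               mean_re = if (nrow(pe) > 0) mean(pe$re) else NA_real_,
               mean_nre = if (any(!is.na(pe$nre))) mean(pe$nre, na.rm = TRUE)
               else NA_real_,
               ssim = ssim, n_points = nrow(pe), flagged = flagged)
  })
  per_frame <- do.call(rbind, rows)
  structure(list(per_frame = per_frame,
                 scene_mean_re = mean(per_frame$mean_re, na.rm = TRUE),
                 scene_mean_nre = mean(per_frame$mean_nre, na.rm = TRUE),
                 scene_mean_ssim = mean(per_frame$ssim, na.rm = TRUE),
                 method = method, start_frame = start_frame),
            class = "registration_metrics")
}

#' @export
print.registration_metrics <- function(x, ...) {
  cat(sprintf("<registration_metrics: %s, start %d | RE %.2f px, nRE %.3f, SSIM %.3f>\n",
              x$method, x$start_frame, x$scene_mean_re, x$scene_mean_nre,
              x$scene_mean_ssim))
  invisible(x)
}

#' Aggregate scene metrics into one comparison-table row
#'
#' Unweighted mean of scene means (points are averaged per frame, frames per
#' scene, scenes overall).
#'
#' @param metrics List of `registration_metrics`.
#' @return Data frame with `mean_re`, `mean_nre`, `mean_ssim`, `n_scenes`.
#' @export
aggregate_scenes <- function(metrics) {
  if (length(metrics) == 0) stop("no scenes to aggregate", call. = FALSE)
  data.frame(
    mean_re = mean(vapply(metrics, function(m) m$scene_mean_re, numeric(1)),
                   na.rm = TRUE),
    mean_nre = mean(vapply(metrics, function(m) m$scene_mean_nre, numeric(1)),
                    na.rm = TRUE),
    mean_ssim = mean(vapply(metrics, function(m) m$scene_mean_ssim, numeric(1)),
                     na.rm = TRUE),
    n_scenes = length(metrics))
}
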