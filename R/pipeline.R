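# End-to-end live-augmentation loop: capture start frame -> per-frame
# preprocess -> features -> quality gate -> single homography (+ optional
# multi-affine regions) -> fusion -> display mask -> compose/overlay.
# Every failure path degrades to showing the unmodified current frame, so no
# frame is ever blocked.

#' Initialize the pipeline on a start frame
#'
#' Preprocesses the start frame and computes its keypoints once; they are
#' reused unchanged for every subsequent frame.
#'
#' @param start_frame The reference [frame_image()] saved during the
#'   spectral record.
#' @param config Configuration list as from [default_config()].
#' @param overlay Optional list with `map` (a [physio_map()]) and `cal`
#'   (a `sensor_calibration`) to render the physiological overlay.
#' @return Object of class `pipeline_state`.
#' @export
pipeline_init <- function(start_frame, config = default_config(),
                          overlay = NULL) {
  pp <- preprocess_frame(start_frame, config)
  kp <- detect_describe(pp$mono, pp$mask, detector = config$detector,
                        descriptor = config$descriptor,
                        max_keypoints = config$max_keypoints,
                        fast_threshold = config$fast_threshold)
  structure(list(start_frame = start_frame, start_mono = pp$mono,
                 start_mask = pp$mask, start_keypoints = kp,
                 config = config, overlay = overlay),
            class = "pipeline_state")
}

#' Process one live frame
#'
#' Runs the full per-frame chain. If the quality gate fails (or any stage
#' errors) the original current frame is returned unmodified; otherwise the
#' start frame is warped by the single homography (fused with any valid
#' multi-affine region warps when `config$transform == "sh+hma"`), the
#' display mask suppresses high-error pixels, and the physiological overlay
#' is rendered when configured.
#'
#' @param state A `pipeline_state` from [pipeline_init()].
#' @param current The current [frame_image()].
#' @return List with `output` (a [frame_image()]) and `diagnostics` (list:
#'   `gated`, `reason`, `mean_distance`, `n_matches`, `inlier_ratio`,
#'   `n_regions`, `timing_ms` per stage).
#' @export
process_frame <- function(state, current) {
  cfg <- state$config
  diag_ <- list(gated = TRUE, reason = "", mean_distance = NA_real_,
                n_matches = 0L, inlier_ratio = NA_real_, n_regions = 0L,
                timing_ms = c())
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  pp <- preprocess_frame(current, cfg)
  kp <- detect_describe(pp$mono, pp$mask, detector = cfg$detector,
                        descriptor = cfg$descriptor,
                        max_keypoints = cfg$max_keypoints,
                        fast_threshold = cfg$fast_threshold)
  t1 <- tic()
  matches <- match_features(state$start_keypoints, kp,
                            retain_fraction = cfg$match_fraction)
  diag_$n_matches <- nrow(matches$pairs)
  diag_$mean_distance <- matches$mean_distance
  gate <- quality_gate(matches, cfg$detector, cfg$gate_threshold)
  t2 <- tic()
  if (!gate$pass) {
    diag_$reason <- gate$reason
    diag_$timing_ms <- c(detect = (t1 - t0) * 1000, match = (t2 - t1) * 1000)
    return(list(output = current, diagnostics = diag_))
  }
  result <- tryCatch({
    sh <- estimate_single_homography(matches, threshold = cfg$ransac$threshold,
                                     seed = cfg$seed,
                                     max_iter = cfg$ransac$max_iter,
                                     confidence = cfg$ransac$confidence)
    diag_$inlier_ratio <- length(sh$inlier_indices) / sh$n_pairs
    image_size <- c(dim(current$pixels)[2], dim(current$pixels)[1])
    cands <- list(list(warp = warp_image(state$start_frame, sh),
                       label = "SH"))
    if (identical(cfg$transform, "sh+hma")) {
      hma <- tryCatch(
        estimate_hma(matches, image_size,
                     split_ratio = cfg$hma$split_ratio,
                     min_region = cfg$hma$min_region,
                     expand_threshold = cfg$hma$expand_threshold,
                     k_init = cfg$hma$k_init, max_depth = cfg$hma$max_depth,
                     seed = cfg$seed,
                     ransac_threshold = cfg$ransac$threshold),
        error = function(e) NULL)
      if (!is.null(hma)) {
        valid <- Filter(function(r)
          validate_region(r, sh, image_size,
                          min_area_frac = cfg$fusion$min_area_frac,
                          max_h_diff = cfg$fusion$max_h_diff), hma$regions)
        diag_$n_regions <- length(valid)
        for (i in seq_along(valid))
          cands[[length(cands) + 1]] <- list(
            warp = warp_image(state$start_frame, valid[[i]]$H_local),
            label = sprintf("HMA-region-%d", i))
      }
    }
    for (i in seq_along(cands))
      cands[[i]]$error_image <- build_error_image(cands[[i]]$warp, current,
                                                  cfg$fusion$closing_size)
    fusion <- fuse_candidates(cands)
    suppress <- build_display_mask(fusion$combined_error,
                                   threshold_frac = cfg$fusion$error_frac,
                                   median_size = cfg$fusion$median_size)
    fusion$display_mask <- !suppress
    out <- if (!is.null(state$overlay)) {
      render_overlay(current, sh, state$overlay$map, state$overlay$cal,
                     alpha = cfg$overlay_alpha,
                     display_mask = fusion$display_mask)
    } else {
      compose_output(fusion, current)
    }
    diag_$gated <- FALSE
    diag_$reason <- "ok"
    list(output = out, diagnostics = diag_)
  }, error = function(e) {
    diag_$reason <- conditionMessage(e)
    list(output = current, diagnostics = diag_)
  })
  t3 <- tic()
  result$diagnostics$timing_ms <- c(detect = (t1 - t0) * 1000,
                                    match = (t2 - t1) * 1000,
                                    transform = (t3 - t2) * 1000)
  result
}

#' Run the pipeline over a frame sequence
#'
#' Applies [process_frame()] to every frame after the start frame and
#' collects a per-frame log. Timing is logged but never part of any
#' assertion (it is hardware-dependent).
#'
#' @param frames List of [frame_image()] objects (ascending order).
#' @param config Configuration list.
#' @param start_index 0-based index of the frame to use as reference
#'   (default: the first frame).
#' @param overlay Optional overlay spec as in [pipeline_init()].
#' @return List with `outputs` (list of frames) and `log` (data frame with
#'   one row per processed frame).
#' @export
run_video <- function(frames, config = default_config(), start_index = NULL,
                      overlay = NULL) {
  idx <- vapply(frames, function(f) f$frame_index, integer(1))
  if (is.null(start_index)) start_index <- idx[1]
  start <- frames[[match(start_index, idx)]]
  state <- pipeline_init(start, config, overlay)
  todo <- which(idx != start_index)
  outputs <- vector("list", length(todo))
  rows <- vector("list", length(todo))
  for (i in seq_along(todo)) {
    f <- frames[[todo[i]]]
    res <- process_frame(state, f)
    outputs[[i]] <- res$output
    d <- res$diagnostics
    rows[[i]] <- data.frame(
      frame = f$frame_index, gated = d$gated, reason = d$reason,
      mean_distance = d$mean_distance, n_matches = d$n_matches,
      inlier_ratio = d$inlier_ratio, n_regions = d$n_regions,
      detect_ms = unname(d$timing_ms["detect"]),
      match_ms = unname(d$timing_ms["match"]),
      transform_ms = if ("transform" %in% names(d$timing_ms))
        unname(d$timing_ms["transform"]) else NA_real_)
  }
  list(outputs = outputs, log = do.call(rbind, rows))
}
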