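# Augmentation of live video with a static physiological map: one-time
# sensor calibration from annotated point pairs, false-color mapping, and
# per-frame semitransparent overlay.

#' Construct a physiological map
#'
#' A static false-color source image, e.g. a tissue-oxygenation (StO2)
#' fraction per spectral pixel. Values are clipped to \[0, 1\]; NA/NaN marks
#' pixels with no estimate (rendered transparent).
#'
#' @param values H' x W' numeric matrix.
#' @param colormap_id Name of an `hcl.colors` palette (default `"viridis"`).
#' @param valid_mask Optional logical matrix; defaults to `!is.na(values)`.
#' @return Object of class `physio_map`.
#' @export
physio_map <- function(values, colormap_id = "viridis", valid_mask = NULL) {
  vm <- if (is.null(valid_mask)) !is.na(values) else valid_mask & !is.na(values)
  values <- clamp(values, 0, 1)
  structure(list(values = values, colormap_id = colormap_id, valid_mask = vm),
            class = "physio_map")
}

#' One-time calibration between the spectral and color sensors
#'
#' Fits the homography mapping spectral-image coordinates to color-sensor
#' coordinates by Hartley-normalized DLT least squares over ALL annotated
#' pairs - no RANSAC, since the manual annotations are trusted. The fixed
#' sensor arrangement makes this a one-time step (25 annotated pairs in the
#' reference setup). Differing sensor resolutions are absorbed by the
#' homography's scale; no separate resampling is needed.
#'
#' @param pairs Data frame with `x_src`, `y_src` (spectral) and `x_dst`,
#'   `y_dst` (color), or `list(src, dst)` of n x 2 matrices.
#' @return Object of class `sensor_calibration`: `H_cal`
#'   (a `homography_transform`), the pairs, and `rms_residual` in px.
#' @export
calibrate_sensors <- function(pairs) {
  if (is.data.frame(pairs)) {
    src <- cbind(pairs$x_src, pairs$y_src)
    dst <- cbind(pairs$x_dst, pairs$y_dst)
  } else {
    src <- rbind(pairs$src); dst <- rbind(pairs$dst)
  }
  if (nrow(src) < 4) stop("at least 4 pairs are required", call. = FALSE)
  H <- dlt_homography(src, dst)
  res <- transfer_errors(H, src, dst)
  structure(list(
    H_cal = structure(list(H = H, inlier_indices = seq_len(nrow(src)),
                           reproj_threshold = NA_real_, n_pairs = nrow(src)),
                      class = "homography_transform"),
    point_pairs = list(src = src, dst = dst),
    rms_residual = sqrt(mean(res^2))
  ), class = "sensor_calibration")
}

#' @export
print.sensor_calibration <- function(x, ...) {
  cat(sprintf("<sensor_calibration: %d pairs, RMS residual %.3f px>\n",
              x$H_cal$n_pairs, x$rms_residual))
  invisible(x)
}

#' False-color a physiological map
#'
#' Perceptually ordered colormap lookup: 0 and 1 map to the palette
#' endpoints, NA values are invalid (transparent).
#'
#' @param map A [physio_map()].
#' @param n_colors Palette resolution (default 256).
#' @return List with `pixels` (H' x W' x 3, 0-255) and `valid` mask.
#' @export
colorize <- function(map, n_colors = 256L) {
  pal <- col2rgb(hcl.colors(n_colors, map$colormap_id))
  v <- map$values
  idx <- pmin(floor(ifelse(is.na(v), 0, v) * n_colors) + 1L, n_colors)
  out <- array(0L, c(nrow(v), ncol(v), 3))
  for (c in 1:3) out[, , c] <- matrix(pal[c, idx], nrow(v), ncol(v))
  list(pixels = out, valid = map$valid_mask)
}

#' Overlay a physiological map on a registered video frame
#'
#' The map is warped into the current frame by the composed transform
#' `frame_transform o H_cal` (spectral -> start-frame color -> current
#' frame), then alpha-blended over the grayscale current frame:
#' `out = round(alpha * color + (1 - alpha) * gray)`. Pixels where the warped
#' map is invalid, or where `display_mask` is FALSE, show the untouched
#' current frame.
#'
#' @param current The current [frame_image()].
#' @param frame_transform Homography mapping start-frame to current-frame
#'   coordinates (e.g. from [estimate_single_homography()]), or `"identity"`.
#' @param map A [physio_map()].
#' @param cal A `sensor_calibration` from [calibrate_sensors()], or
#'   `"identity"` when the map is already in start-frame coordinates.
#' @param alpha Blend weight of the color map (default 0.5, semitransparent).
#' @param display_mask Optional logical matrix; FALSE suppresses the overlay.
#' @return A [frame_image()].
#' @export
render_overlay <- function(current, frame_transform, map, cal, alpha = 0.5,
                           display_mask = NULL) {
  Hf <- if (is.character(frame_transform) && frame_transform == "identity")
    diag(3) else as_h_matrix(frame_transform)
  Hc <- if (is.character(cal) && cal == "identity") diag(3)
  else as_h_matrix(cal$H_cal)
  H <- normalize_h(Hf %*% Hc)
  col <- colorize(map)
  cur_px <- frame_pixels(current)
  Hout <- dim(cur_px)[1]; Wout <- dim(cur_px)[2]
  # backward-warp the colorized map (and its validity) into the current frame
  xs <- rep(0:(Wout - 1), each = Hout)
  ys <- rep(0:(Hout - 1), times = Wout)
  src <- apply_homography_to_points(solve(H), cbind(xs, ys))
  sx <- src[, 1]; sy <- src[, 2]
  ok <- attr(src, "valid")
  sx[!ok] <- -1; sy[!ok] <- -1
  warped <- array(0, c(Hout, Wout, 3))
  valid <- NULL
  for (c in 1:3) {
    res <- cpp_bilinear_sample(matrix(as.numeric(col$pixels[, , c]),
                                      dim(col$pixels)[1]), sx, sy)
    v <- res$values; v[!res$valid] <- 0
    warped[, , c] <- matrix(v, Hout, Wout)
    if (c == 1) valid <- matrix(res$valid & ok, Hout, Wout)
  }
  vres <- cpp_bilinear_sample(matrix(as.numeric(col$valid),
                                     nrow(col$valid)), sx, sy)
  map_valid <- matrix(!is.na(vres$values) & vres$values > 0.999, Hout, Wout) &
    valid
  show <- map_valid
  if (!is.null(display_mask)) show <- show & display_mask
  gray <- frame_luma(current)
  out <- cur_px
  for (c in 1:3) {
    plane <- out[, , c]
    blended <- round(alpha * warped[, , c] + (1 - alpha) * gray)
    plane[show] <- blended[show]
    out[, , c] <- clamp(plane, 0, 255)
  }
  frame_image(out, if (inherits(current, "frame_image"))
    current$frame_index else 0L)
}
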