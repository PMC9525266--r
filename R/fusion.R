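# Per-pixel fusion of candidate warps and the display mask that suppresses
# unreliable overlay pixels (the visualization postprocessing chain).

#' Validate an HMA region for fusion
#'
#' A region's warp participates in fusion only if (a) its support polygon
#' covers more than 2\% of the image area and (b) the entrywise sum of
#' absolute differences between its local homography and the global single
#' homography is below 50. Both matrices must be normalized to `H[3,3] = 1`,
#' since raw entries are differenced.
#'
#' @param region One region from a `region_transform_set` (list with
#'   `H_local` and `support_polygon`).
#' @param H_global The global `homography_transform` (or 3 x 3 matrix).
#' @param image_size `c(W, H)` in pixels.
#' @param min_area_frac Minimum polygon area as a fraction of the image area
#'   (default 0.02).
#' @param max_h_diff Maximum sum of absolute entry differences (default 50).
#' @return TRUE if the region may be fused.
#' @export
validate_region <- function(region, H_global, image_size,
                            min_area_frac = 0.02, max_h_diff = 50) {
  Hl <- as_h_matrix(region$H_local)
  Hg <- as_h_matrix(H_global)
  if (abs(Hl[3, 3] - 1) > 1e-9 || abs(Hg[3, 3] - 1) > 1e-9)
    stop("homographies must be normalized to H[3,3] = 1", call. = FALSE)
  poly <- region$support_polygon
  if (is.null(poly) || nrow(poly) < 3) return(FALSE)
  x <- poly[, 1]; y <- poly[, 2]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  area > min_area_frac * image_size[1] * image_size[2] &&
    sum(abs(Hl - Hg)) < max_h_diff
}

#' Build the photometric error image of a candidate warp
#'
#' Absolute difference of the green channels of the warped start frame and
#' the current frame, set to 255 where the warp has no source pixel, then
#' smoothed by a morphological closing with a 35 x 35 elliptical structuring
#' element so that thin high-error structures merge into contiguous regions.
#' The difference is taken on the raw green channels (not the CLAHE-equalized
#' detection images), since local equalization would distort the photometric
#' error.
#'
#' @param warp A `warp_result` holding the warped start frame.
#' @param current The current [frame_image()].
#' @param closing_size Side of the elliptical closing kernel (default 35).
#' @return H x W numeric error image in \[0, 255\].
#' @export
build_error_image <- function(warp, current, closing_size = 35) {
  gw <- if (inherits(warp$image, "frame_image") ||
              length(dim(frame_pixels(warp$image))) == 3)
    extract_green(warp$image) else frame_pixels(warp$image)
  gc_ <- if (length(dim(frame_pixels(current))) == 3)
    extract_green(current) else frame_pixels(current)
  err <- abs(gw - gc_)
  err[!warp$validity] <- 255
  kern <- ellipse_kernel(closing_size)
  storage.mode(kern) <- "double"
  closed <- EBImage::closing(err / 255, kern) * 255
  matrix(pmin(pmax(as.numeric(closed), 0), 255), nrow(err), ncol(err))
}

#' Fuse candidate warps by per-pixel error minimization
#'
#' For each pixel the candidate with the lowest error is selected; the fused
#' image takes that candidate's pixel. Ties are broken by candidate order, so
#' the globally trusted single homography should be listed first.
#'
#' @param candidates Non-empty list of candidates, each a list with `warp`
#'   (a `warp_result`), `error_image`, and `label`.
#' @return Object of class `fusion_result`: `fused_image`, integer
#'   `source_index` map, `combined_error` (pointwise minimum), candidate
#'   `labels`, and a `display_mask` slot (`NULL` until
#'   [build_display_mask()] is applied).
#' @export
fuse_candidates <- function(candidates) {
  if (length(candidates) == 0) stop("no candidates to fuse", call. = FALSE)
  err1 <- candidates[[1]]$error_image
  H <- nrow(err1); W <- ncol(err1)
  combined <- err1
  source_index <- matrix(1L, H, W)
  if (length(candidates) > 1) {
    for (k in 2:length(candidates)) {
      ek <- candidates[[k]]$error_image
      stopifnot(identical(dim(ek), dim(err1)))
      better <- ek < combined # strict: earlier candidates win ties
      source_index[better] <- k
      combined[better] <- ek[better]
    }
  }
  first_px <- frame_pixels(candidates[[1]]$warp$image)
  is_frame <- length(dim(first_px)) == 3
  if (is_frame) {
    fused <- array(0L, dim(first_px))
    for (k in seq_along(candidates)) {
      sel <- source_index == k
      px <- frame_pixels(candidates[[k]]$warp$image)
      for (c in 1:3) {
        plane <- fused[, , c]
        plane[sel] <- px[, , c][sel]
        fused[, , c] <- plane
      }
    }
    fused <- frame_image(fused)
  } else {
    fused <- matrix(0L, H, W)
    for (k in seq_along(candidates)) {
      sel <- source_index == k
      fused[sel] <- frame_pixels(candidates[[k]]$warp$image)[sel]
    }
  }
  structure(list(fused_image = fused, source_index = source_index,
                 combined_error = combined,
                 labels = vapply(candidates, function(c) c$label, character(1)),
                 display_mask = NULL),
            class = "fusion_result")
}

#' Build the display-suppression mask from the combined error
#'
#' Pixels whose combined error exceeds 10\% of the 8-bit range (i.e. error
#' > 25.5, so 26 and above on integer data) are marked for suppression; a
#' 35 x 35 binary majority median filter then removes isolated decisions.
#'
#' @param combined_error H x W error image on the 8-bit scale.
#' @param threshold_frac Error threshold as a fraction of 255 (default 0.10).
#' @param median_size Median filter window side (default 35).
#' @return Logical matrix: TRUE = suppress the overlay at this pixel (show
#'   the original current frame).
#' @export
build_display_mask <- function(combined_error, threshold_frac = 0.10,
                               median_size = 35) {
  raw <- combined_error > threshold_frac * 255
  binary_median(raw, median_size)
}

#' Compose the final output frame
#'
#' Splices the fused image and the original current frame: where the fusion
#' result's display mask allows it the fused pixel is shown, elsewhere the
#' untouched current frame.
#'
#' @param fusion A `fusion_result` whose `display_mask` has been set (TRUE =
#'   show the fused pixel). A `NULL` mask shows the fused image everywhere.
#' @param current The current [frame_image()].
#' @return A [frame_image()].
#' @export
compose_output <- function(fusion, current) {
  cur_px <- frame_pixels(current)
  fus_px <- frame_pixels(fusion$fused_image)
  stopifnot(identical(dim(cur_px), dim(fus_px)))
  show <- fusion$display_mask
  if (is.null(show)) show <- matrix(TRUE, dim(cur_px)[1], dim(cur_px)[2])
  out <- cur_px
  for (c in 1:3) {
    plane <- out[, , c]
    fplane <- fus_px[, , c]
    plane[show] <- fplane[show]
    out[, , c] <- plane
  }
  frame_image(out, if (inherits(current, "frame_image"))
    current$frame_index else 0L)
}
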