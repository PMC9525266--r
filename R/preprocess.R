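# Frame preprocessing: green channel, glare/dark masking, smoothing, CLAHE.
# Features are detected on the equalized image but only inside the glare mask,
# which is computed on the raw green channel.

#' Extract the green channel of a frame
#'
#' Laparoscopic tissue contrast is strongest in the green channel, which is
#' used as the single-channel detection image.
#'
#' @param frame A [frame_image()].
#' @return H x W integer matrix (a mono image, values 0-255).
#' @export
extract_green <- function(frame) {
  px <- frame_pixels(frame)
  if (length(dim(px)) != 3 || dim(px)[3] != 3)
    stop("extract_green expects a 3-channel RGB frame", call. = FALSE)
  m <- px[, , 2]
  storage.mode(m) <- "integer"
  m
}

#' Compute the glare/dark mask of a mono image
#'
#' Specular highlights and dark areas (instrument shafts, vignetting) are
#' unreliable for feature detection. Pixels are kept only when their intensity
#' lies strictly inside the band `(lower_frac * 255, upper_frac * 255)` of the
#' 8-bit range (51 and 204 at the defaults), and the kept area is then eroded
#' with a 5 x 5 elliptical structuring element. Pixels outside the image count
#' as excluded, so the mask also shrinks at the borders.
#'
#' `mode = "percentile"` switches the band limits to data-driven quantiles of
#' the image instead of fixed fractions of the value range.
#'
#' @param mono H x W mono image (0-255).
#' @param lower_frac,upper_frac Band limits as fractions of the value range
#'   (defaults 0.20 and 0.80).
#' @param mode `"range"` (fixed fractions of 255, the default) or
#'   `"percentile"` (quantiles of the data).
#' @param erosion_size Side of the elliptical erosion kernel (default 5).
#' @return Object of class `glare_mask`: list with logical `mask` (TRUE =
#'   usable) plus the parameters used.
#' @export
compute_glare_mask <- function(mono, lower_frac = 0.2, upper_frac = 0.8,
                               mode = c("range", "percentile"),
                               erosion_size = 5) {
  mode <- match.arg(mode)
  stopifnot(lower_frac >= 0, lower_frac < upper_frac, upper_frac <= 1)
  if (mode == "range") {
    lo <- lower_frac * 255
    hi <- upper_frac * 255
  } else {
    qs <- quantile(mono, c(lower_frac, upper_frac), names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  keep <- mono > lo & mono < hi
  r <- (erosion_size - 1L) / 2L
  kern <- ellipse_kernel(erosion_size)
  storage.mode(kern) <- "double"
  # zero-pad so pixels outside the image count as excluded
  padded <- matrix(0, nrow(keep) + 2L * r, ncol(keep) + 2L * r)
  padded[(r + 1):(r + nrow(keep)), (r + 1):(r + ncol(keep))] <- keep
  eroded <- EBImage::erode(padded, kern)
  mask <- eroded[(r + 1):(r + nrow(keep)), (r + 1):(r + ncol(keep))] > 0.5
  structure(list(mask = mask, lower_frac = lower_frac, upper_frac = upper_frac,
                 mode = mode, erosion_size = erosion_size),
            class = "glare_mask")
}

mask_matrix <- function(mask) {
  if (inherits(mask, "glare_mask")) mask$mask else mask
}

#' Smooth and contrast-equalize a mono image
#'
#' A normalized 5 x 5 box filter (replicate borders) suppresses sensor noise,
#' then Contrast Limited Adaptive Histogram Equalization (8 x 8 tile grid,
#' clip limit 2.0) evens out illumination so feature response is comparable
#' across the image.
#'
#' @param mono H x W mono image (0-255).
#' @param box_size Box filter side (default 5).
#' @param tiles CLAHE tile-grid size per axis (default 8).
#' @param clip CLAHE clip limit (default 2.0).
#' @return Smoothed, equalized mono image (0-255 integer matrix).
#' @export
smooth_and_equalize <- function(mono, box_size = 5, tiles = 8, clip = 2.0) {
  if (nrow(mono) < tiles || ncol(mono) < tiles)
    stop("image smaller than one CLAHE tile", call. = FALSE)
  boxed <- round(conv_sep(mono, rep(1 / box_size, box_size)))
  # the tiled equalizer needs dimensions divisible by the grid; replicate-pad
  # to the next multiple and crop back
  H <- nrow(boxed); W <- ncol(boxed)
  Hp <- ceiling(H / tiles) * tiles; Wp <- ceiling(W / tiles) * tiles
  padded <- boxed[c(seq_len(H), rep(H, Hp - H)), c(seq_len(W), rep(W, Wp - W)),
                  drop = FALSE]
  eq <- EBImage::clahe(padded / 255, nx = tiles, ny = tiles, bins = 256,
                       limit = clip)
  as_mono(as.matrix(eq)[seq_len(H), seq_len(W)] * 255)
}

#' Preprocess a frame for feature detection
#'
#' Full preprocessing chain: green channel, then (a) box filter + CLAHE for
#' the detection image and (b) the glare mask computed on the raw (unequalized)
#' green channel.
#'
#' @param frame A [frame_image()].
#' @param config Configuration list as from [default_config()].
#' @return List with `mono` (equalized detection image) and `mask`
#'   (a `glare_mask`).
#' @export
preprocess_frame <- function(frame, config = default_config()) {
  g <- extract_green(frame)
  mono <- smooth_and_equalize(g, box_size = config$box_size,
                              tiles = config$clahe$tiles,
                              clip = config$clahe$clip)
  mask <- compute_glare_mask(g, lower_frac = config$glare$lower_frac,
                             upper_frac = config$glare$upper_frac,
                             mode = config$glare$mode,
                             erosion_size = config$glare$erosion_size)
  list(mono = mono, mask = mask)
}
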