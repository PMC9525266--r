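# I/O for external artifacts: PNG frame sequences, CVAT annotation XML,
# calibration point pairs, and run configuration.

#' Construct a video frame
#'
#' A frame is an 8-bit RGB image (rows = y, columns = x, third dimension =
#' R,G,B) together with its 0-based position in the sequence. Pixel centers sit
#' at integer coordinates; `x` is the column and `y` the row, both 0-based.
#'
#' @param pixels H x W x 3 array of intensities in \[0, 255\].
#' @param frame_index Non-negative integer frame position.
#' @return An object of class `frame_image`.
#' @export
frame_image <- function(pixels, frame_index = 0L) {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    stop("frame pixels must be an H x W x 3 array", call. = FALSE)
  if (dim(pixels)[1] < 8 || dim(pixels)[2] < 8)
    stop("frames must be at least 8 x 8 pixels", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("frame intensities must lie in [0, 255]", call. = FALSE)
  if (frame_index < 0) stop("frame_index must be >= 0", call. = FALSE)
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, frame_index = as.integer(frame_index)),
            class = "frame_image")
}

frame_pixels <- function(frame) {
  if (inherits(frame, "frame_image")) frame$pixels else frame
}

#' @export
print.frame_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<frame_image %d x %d, frame_index %d>\n", d[2], d[1], x$frame_index))
  invisible(x)
}

#' Read video frames from a PNG sequence
#'
#' Reads a directory of numbered PNG images (or a single PNG file) as 8-bit RGB
#' frames. The trailing integer in each file name is taken as the frame index;
#' unnumbered files are indexed by their sorted position. A lossless PNG
#' sequence is the canonical input so that test runs are bit-exact across
#' platforms.
#'
#' @param source Directory containing PNG files, or a single PNG path.
#' @param indices Optional integer vector of frame indices to read. `NULL`
#'   reads all frames; an empty vector returns an empty list.
#' @return List of [frame_image()] objects in ascending index order.
#' @export
read_frames <- function(source, indices = NULL) {
  if (!file.exists(source)) stop("source not found: ", source, call. = FALSE)
  if (dir.exists(source)) {
    files <- list.files(source, pattern = "\\.png$", full.names = TRUE)
    if (length(files) == 0) stop("no PNG files in ", source, call. = FALSE)
    nums <- suppressWarnings(as.integer(sub(".*?([0-9]+)\\.png$", "\\1", files)))
    if (anyNA(nums) || anyDuplicated(nums)) {
      files <- sort(files)
      nums <- seq_along(files) - 1L
    }
    ord <- order(nums)
    files <- files[ord]; nums <- nums[ord]
  } else {
    files <- source
    nums <- 0L
  }
  if (!is.null(indices)) {
    if (length(indices) == 0) return(list())
    missing_idx <- setdiff(indices, nums)
    if (length(missing_idx) > 0)
      stop("frame index out of range: ", paste(missing_idx, collapse = ", "),
           call. = FALSE)
    keep <- match(sort(indices), nums)
    files <- files[keep]; nums <- nums[keep]
  }
  Map(function(f, i) read_frame(f, i), files, nums, USE.NAMES = FALSE)
}

read_frame <- function(path, frame_index = 0L) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2)
    stop("grayscale image; frames must be RGB: ", path, call. = FALSE)
  if (dim(a)[3] == 4) a <- a[, , 1:3, drop = FALSE]
  frame_image(round(a * 255), frame_index)
}

#' Write a frame as PNG
#' @param frame A [frame_image()].
#' @param path Output PNG path.
#' @export
write_frame <- function(frame, path) {
  png::writePNG(frame_pixels(frame) / 255, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Annotations
# ---------------------------------------------------------------------------

#' Construct an annotation set of landmark tracks
#'
#' The ground-truth container: every track is one annotated landmark with a
#' per-frame position and visibility flag. Coordinates are 0-based pixels
#' (x = column, y = row), matching the CVAT convention.
#'
#' @param tracks List of tracks; each a list with `track_id` and `points`, a
#'   data.frame with columns `frame`, `x`, `y`, `visible`.
#' @param n_frames Number of frames in the annotated sequence.
#' @param image_size `c(W, H)` of the annotated images, or `NULL` if unknown.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(tracks, n_frames, image_size = NULL) {
  ids <- vapply(tracks, function(t) as.integer(t$track_id), integer(1))
  if (anyDuplicated(ids)) stop("track ids must be unique", call. = FALSE)
  for (t in tracks) {
    p <- t$points
    if (nrow(p) == 0) stop("track ", t$track_id, " has no points", call. = FALSE)
    if (any(p$frame < 0 | p$frame > n_frames - 1))
      stop("track ", t$track_id, " has frame indices outside [0, n_frames-1]",
           call. = FALSE)
    if (!is.null(image_size)) {
      vis <- p$visible
      if (any(p$x[vis] < 0 | p$x[vis] > image_size[1] - 1 |
                p$y[vis] < 0 | p$y[vis] > image_size[2] - 1))
        stop("track ", t$track_id, " has visible points outside image bounds",
             call. = FALSE)
    }
  }
  structure(list(tracks = tracks, n_frames = as.integer(n_frames),
                 image_size = image_size),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set: %d tracks, %d frames>\n",
              length(x$tracks), x$n_frames))
  invisible(x)
}

#' Landmarks visible in both of two frames
#'
#' @param ann An [annotation_set()].
#' @param frame_a,frame_b 0-based frame indices.
#' @return Data frame with `track_id`, `xa`, `ya`, `xb`, `yb`, one row per
#'   landmark visible in both frames.
#' @export
covisible_points <- function(ann, frame_a, frame_b) {
  rows <- lapply(ann$tracks, function(t) {
    pa <- t$points[t$points$frame == frame_a & t$points$visible, , drop = FALSE]
    pb <- t$points[t$points$frame == frame_b & t$points$visible, , drop = FALSE]
    if (nrow(pa) == 1 && nrow(pb) == 1)
      data.frame(track_id = t$track_id, xa = pa$x, ya = pa$y, xb = pb$x, yb = pb$y)
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(track_id = integer(), xa = numeric(), ya = numeric(),
                      xb = numeric(), yb = numeric())
  out
}

#' Read CVAT "annotations 1.1" point-track XML
#'
#' Every `<track>` element becomes a landmark track. A point is invisible when
#' either its `outside` or `occluded` attribute is set (the two flags are
#' OR-ed, since annotation exports differ in which one they use).
#'
#' @param path Path to the XML file.
#' @return An [annotation_set()].
#' @export
read_cvat_xml <- function(path) {
  doc <- xml2::read_xml(path)
  track_nodes <- xml2::xml_find_all(doc, ".//track")
  size_node <- xml2::xml_find_first(doc, ".//meta//size")
  w_node <- xml2::xml_find_first(doc, ".//original_size/width")
  h_node <- xml2::xml_find_first(doc, ".//original_size/height")
  image_size <- if (!inherits(w_node, "xml_missing") && !inherits(h_node, "xml_missing"))
    c(as.numeric(xml2::xml_text(w_node)), as.numeric(xml2::xml_text(h_node)))
  else NULL
  tracks <- lapply(track_nodes, function(tn) {
    pts <- xml2::xml_find_all(tn, "./points")
    if (length(pts) == 0)
      stop("track ", xml2::xml_attr(tn, "id"), " has no points", call. = FALSE)
    coords <- strsplit(xml2::xml_attr(pts, "points"), "[,;]")
    xy <- do.call(rbind, lapply(coords, function(v) as.numeric(v[1:2])))
    outside <- xml2::xml_attr(pts, "outside", default = "0") == "1"
    occluded <- xml2::xml_attr(pts, "occluded", default = "0") == "1"
    list(track_id = as.integer(xml2::xml_attr(tn, "id")),
         points = data.frame(frame = as.integer(xml2::xml_attr(pts, "frame")),
                             x = xy[, 1], y = xy[, 2],
                             visible = !(outside | occluded)))
  })
  n_frames <- if (!inherits(size_node, "xml_missing"))
    as.integer(xml2::xml_text(size_node))
  else max(vapply(tracks, function(t) max(t$points$frame), numeric(1))) + 1L
  annotation_set(tracks, n_frames, image_size)
}

#' Write an annotation set as CVAT "annotations 1.1" XML
#'
#' Inverse of [read_cvat_xml()]: coordinates are written with three decimals so
#' the round trip reproduces them within 1e-3 px. Invisible points are written
#' with `outside="1"`.
#'
#' @param annotations An [annotation_set()].
#' @param path Output path.
#' @export
write_cvat_xml <- function(annotations, path) {
  doc <- xml2::xml_new_root("annotations")
  xml2::xml_add_child(doc, "version", "1.1")
  meta <- xml2::xml_add_child(doc, "meta")
  task <- xml2::xml_add_child(meta, "task")
  xml2::xml_add_child(task, "size", as.character(annotations$n_frames))
  if (!is.null(annotations$image_size)) {
    os <- xml2::xml_add_child(task, "original_size")
    xml2::xml_add_child(os, "width", as.character(annotations$image_size[1]))
    xml2::xml_add_child(os, "height", as.character(annotations$image_size[2]))
  }
  for (t in annotations$tracks) {
    tn <- xml2::xml_add_child(doc, "track", id = as.character(t$track_id),
                              label = "landmark", source = "manual")
    p <- t$points
    for (i in seq_len(nrow(p))) {
      xml2::xml_add_child(tn, "points",
                          frame = as.character(p$frame[i]),
                          outside = if (p$visible[i]) "0" else "1",
                          occluded = "0", keyframe = "1",
                          points = sprintf("%.3f,%.3f", p$x[i], p$y[i]),
                          z_order = "0")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read calibration point pairs from CSV
#'
#' Plain-text CSV with columns `x_src`, `y_src`, `x_dst`, `y_dst`; one row per
#' annotated pair (source = spectral image, destination = color sensor).
#'
#' @param path CSV path.
#' @return Data frame with the four coordinate columns.
#' @export
read_calibration_pairs <- function(path) {
  df <- read.csv(path)
  need <- c("x_src", "y_src", "x_dst", "y_dst")
  if (!all(need %in% names(df)))
    stop("calibration CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df[, need]
}

#' Write calibration point pairs to CSV
#' @param pairs Data frame with `x_src`, `y_src`, `x_dst`, `y_dst`.
#' @param path Output CSV path.
#' @export
write_calibration_pairs <- function(pairs, path) {
  write.csv(pairs[, c("x_src", "y_src", "x_dst", "y_dst")], path,
            row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Run configuration
# ---------------------------------------------------------------------------

gate_threshold_for <- function(detector) {
  switch(detector, orb1000 = 35, akaze = 55, brisk = 65,
         stop("unknown detector: ", detector, call. = FALSE))
}

#' Default run configuration
#'
#' All tunable thresholds of the registration pipeline with their default
#' values. The quality-gate threshold follows the detector (35 for ORB1000,
#' 55 for A-KAZE, 65 for BRISK) unless set explicitly.
#'
#' @param detector Detector choice: `"orb1000"`, `"akaze"`, or `"brisk"`.
#' @return Named list of configuration values.
#' @export
default_config <- function(detector = "orb1000") {
  list(
    detector = detector,
    descriptor = "native",
    transform = "sh",
    gate_threshold = gate_threshold_for(detector),
    match_fraction = 0.2,
    fast_threshold = 20,
    max_keypoints = 1000,
    glare = list(lower_frac = 0.2, upper_frac = 0.8, mode = "range",
                 erosion_size = 5),
    box_size = 5,
    clahe = list(tiles = 8, clip = 2.0),
    ransac = list(threshold = 5, max_iter = 2000, confidence = 0.995),
    hma = list(split_ratio = 0.5, min_region = 4, expand_threshold = 5,
               k_init = NULL, max_depth = 4),
    mls = list(grid_density = 0.2, alpha = 1.0),
    fusion = list(closing_size = 35, error_frac = 0.10, median_size = 35,
                  min_area_frac = 0.02, max_h_diff = 50,
                  difference_channel = "raw_green"),
    ssim_fill = "mean",
    overlay_alpha = 0.5,
    nre_min_moved = 1e-6,
    frame_index_base = 0,
    start_frames = c(20, 200, 400, 600),
    last_frame = 749,
    seed = 17
  )
}

valid_choices <- list(detector = c("orb1000", "akaze", "brisk"),
                      descriptor = c("native", "beblid256", "beblid512"),
                      transform = c("sh", "hma", "mls", "sh+hma"))

#' Load a run configuration from a YAML file
#'
#' Keys absent from the file keep their defaults; an unknown key is an error
#' (with the key named), so typos never pass silently. Setting `detector`
#' without `gate_threshold` auto-selects the detector's gate threshold.
#'
#' @param path Path to a YAML config file. An empty file yields the defaults.
#' @return Named list as from [default_config()].
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  detector <- if (!is.null(user$detector)) tolower(user$detector) else "orb1000"
  base <- default_config(detector)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0)
    stop("unknown config key: ", paste(unknown, collapse = ", "), call. = FALSE)
  user$detector <- detector
  cfg <- modifyList(base, user)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  for (key in names(valid_choices)) {
    if (!(cfg[[key]] %in% valid_choices[[key]]))
      stop("invalid ", key, ": ", cfg[[key]], call. = FALSE)
  }
  thresholds <- c(cfg$gate_threshold, cfg$ransac$threshold, cfg$fast_threshold,
                  cfg$mls$grid_density, cfg$fusion$closing_size,
                  cfg$fusion$error_frac, cfg$fusion$median_size)
  if (any(thresholds <= 0)) stop("all thresholds must be positive", call. = FALSE)
  invisible(cfg)
}
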