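# Keypoint detection, binary description, crosschecked Hamming matching,
# and the mean-distance quality gate.

DETECTOR_CAPS <- c(orb1000 = 1000L)

#' Detect and describe keypoints
#'
#' Runs the package's oriented corner detector on the preprocessed mono image
#' within the glare mask: FAST-9/16 corners with 3x3 non-maximum suppression,
#' ranked by contrast response and capped at `max_keypoints` (1000 for
#' `"orb1000"`), each with an intensity-centroid orientation and a rotated
#' 256-bit binary descriptor.
#'
#' The `"akaze"`, `"brisk"` and BEBLID choices are part of the configuration
#' surface (their quality-gate thresholds are implemented) but no
#' implementation of those algorithms ships with this package, so requesting
#' them here is an error.
#'
#' @param mono Preprocessed H x W mono image (0-255).
#' @param mask A `glare_mask` or logical matrix of the same size (TRUE =
#'   usable pixel).
#' @param detector `"orb1000"`.
#' @param descriptor `"native"`.
#' @param max_keypoints Response-ranked cap on keypoint count (default 1000).
#' @param fast_threshold FAST contrast threshold (default 20).
#' @return Object of class `keypoint_set`: data.frame `keypoints`
#'   (`x`, `y`, `scale`, `orientation`, `response`), integer matrix
#'   `descriptors` (one row per keypoint, 32 bytes = 256 bits), and
#'   `detector_tag`.
#' @export
detect_describe <- function(mono, mask = NULL, detector = "orb1000",
                            descriptor = "native", max_keypoints = 1000L,
                            fast_threshold = 20L) {
  detector <- tolower(detector)
  if (!(detector %in% valid_choices$detector))
    stop("unknown detector: ", detector, call. = FALSE)
  if (detector != "orb1000")
    stop("detector '", detector, "' is not available in this implementation; ",
         "use 'orb1000'", call. = FALSE)
  if (!(tolower(descriptor) %in% valid_choices$descriptor))
    stop("unknown descriptor: ", descriptor, call. = FALSE)
  if (tolower(descriptor) != "native")
    stop("descriptor '", descriptor, "' is not available in this ",
         "implementation; use 'native'", call. = FALSE)
  m <- mask_matrix(mask)
  if (is.null(m)) m <- matrix(TRUE, nrow(mono), ncol(mono))
  stopifnot(identical(dim(m), dim(mono)))
  storage.mode(mono) <- "integer"
  res <- cpp_detect_orb(mono, m, as.integer(max_keypoints),
                        as.integer(fast_threshold), 20L)
  structure(list(
    keypoints = data.frame(x = res$x, y = res$y,
                           scale = rep(31, length(res$x)),
                           orientation = res$angle, response = res$response),
    descriptors = res$descriptors,
    detector_tag = detector
  ), class = "keypoint_set")
}

#' @export
print.keypoint_set <- function(x, ...) {
  cat(sprintf("<keypoint_set: %d keypoints (%s)>\n",
              nrow(x$keypoints), x$detector_tag))
  invisible(x)
}

empty_match_set <- function(reason = "empty keypoint set") {
  structure(list(
    pairs = data.frame(idx_a = integer(), idx_b = integer(),
                       distance = integer(), xa = numeric(), ya = numeric(),
                       xb = numeric(), yb = numeric()),
    crosschecked = data.frame(idx_a = integer(), idx_b = integer(),
                              distance = integer()),
    mean_distance = NA_real_, n_crosschecked = 0L,
    retained_fraction = 0.2, flagged = reason
  ), class = "match_set")
}

#' Match two keypoint sets
#'
#' Brute-force Hamming matching with crosscheck: a pair is kept only if the
#' two keypoints are mutual nearest neighbours. The crosschecked matches are
#' sorted by ascending distance (ties broken by index order for determinism)
#' and the best `ceiling(retain_fraction * n)` are retained; `mean_distance`
#' is the mean Hamming distance over the retained pairs and feeds the
#' [quality_gate()].
#'
#' @param a,b `keypoint_set` objects with equal descriptor width (start frame
#'   first, current frame second).
#' @param retain_fraction Fraction of best crosschecked matches retained
#'   (default 0.2).
#' @return Object of class `match_set` with retained `pairs` (indices,
#'   distances and the matched coordinates), all `crosschecked` matches,
#'   `mean_distance`, and `n_crosschecked`.
#' @export
match_features <- function(a, b, retain_fraction = 0.2) {
  if (nrow(a$keypoints) == 0 || nrow(b$keypoints) == 0)
    return(empty_match_set())
  if (ncol(a$descriptors) != ncol(b$descriptors))
    stop("descriptor widths differ", call. = FALSE)
  ab <- cpp_hamming_nn(a$descriptors, b$descriptors)
  ba <- cpp_hamming_nn(b$descriptors, a$descriptors)
  ia <- seq_len(nrow(a$descriptors))
  mutual <- ba$idx[ab$idx] == ia
  cc <- data.frame(idx_a = ia[mutual], idx_b = ab$idx[mutual],
                   distance = ab$dist[mutual])
  if (nrow(cc) == 0) return(empty_match_set("no mutual matches"))
  ord <- order(cc$distance, cc$idx_a, cc$idx_b)
  cc <- cc[ord, , drop = FALSE]
  n_keep <- ceiling(retain_fraction * nrow(cc))
  kept <- cc[seq_len(n_keep), , drop = FALSE]
  kept$xa <- a$keypoints$x[kept$idx_a]
  kept$ya <- a$keypoints$y[kept$idx_a]
  kept$xb <- b$keypoints$x[kept$idx_b]
  kept$yb <- b$keypoints$y[kept$idx_b]
  rownames(kept) <- NULL
  structure(list(pairs = kept, crosschecked = cc,
                 mean_distance = mean(kept$distance),
                 n_crosschecked = nrow(cc),
                 retained_fraction = retain_fraction, flagged = NULL),
            class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf("<match_set: %d retained of %d crosschecked, mean distance %.2f>\n",
              nrow(x$pairs), x$n_crosschecked, x$mean_distance))
  invisible(x)
}

#' Quality gate on the mean matching distance
#'
#' Registration is abandoned (and the original current frame shown) when the
#' mean Hamming distance of the retained matches strictly exceeds the
#' detector's threshold: 35 for ORB1000, 55 for A-KAZE, 65 for BRISK. The
#' thresholds are calibrated so that passing match sets correspond to a RANSAC
#' inlier ratio of about 0.6 at the 5 px reprojection threshold.
#'
#' @param matches A `match_set`.
#' @param detector Detector tag selecting the threshold.
#' @param threshold Explicit threshold overriding the detector default.
#' @return List with `pass` (logical), `reason`, `mean_distance`, `threshold`.
#' @export
quality_gate <- function(matches, detector = "orb1000", threshold = NULL) {
  if (is.null(threshold)) threshold <- gate_threshold_for(tolower(detector))
  if (nrow(matches$pairs) == 0 || is.na(matches$mean_distance))
    return(list(pass = FALSE, reason = "no matches",
                mean_distance = NA_real_, threshold = threshold))
  pass <- matches$mean_distance <= threshold # fail only when strictly greater
  list(pass = pass,
       reason = if (pass) "ok" else
         sprintf("mean distance %.2f > %.0f", matches$mean_distance, threshold),
       mean_distance = matches$mean_distance, threshold = threshold)
}
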