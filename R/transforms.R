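# Transformation estimation and application: robust single homography (RANSAC
# + normalized DLT refit), hierarchical multi-affine region transforms, affine
# moving-least-squares deformation fields, and backward bilinear warping.

normalize_h <- function(H) {
  if (abs(H[3, 3]) < 1e-12) stop("homography cannot be normalized", call. = FALSE)
  H / H[3, 3]
}

as_h_matrix <- function(transform) {
  if (inherits(transform, "homography_transform")) transform$H
  else if (is.matrix(transform) && all(dim(transform) == c(3, 3))) transform
  else stop("not a homography", call. = FALSE)
}

# Hartley-normalized direct linear transform. src, dst: n x 2 matrices.
dlt_homography <- function(src, dst) {
  n <- nrow(src)
  stopifnot(n >= 4, nrow(dst) == n)
  norm_pts <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    s <- if (mean(d) > 1e-12) sqrt(2) / mean(d) else 1
    T <- matrix(c(s, 0, -s * ctr[1], 0, s, -s * ctr[2], 0, 0, 1), 3, 3,
                byrow = TRUE)
    list(p = cbind(s * (p[, 1] - ctr[1]), s * (p[, 2] - ctr[2])), T = T)
  }
  ns <- norm_pts(src); nd <- norm_pts(dst)
  x <- ns$p[, 1]; y <- ns$p[, 2]; u <- nd$p[, 1]; v <- nd$p[, 2]
  A <- matrix(0, 2 * n, 9)
  A[seq(1, 2 * n, 2), ] <- cbind(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
  A[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  sv <- svd(A, nu = 0, nv = 9)
  if (sv$d[8] < 1e-10 * max(sv$d))
    stop("degenerate point configuration", call. = FALSE)
  Hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  normalize_h(solve(nd$T) %*% Hn %*% ns$T)
}

#' Apply a homography to points
#'
#' Homogeneous transform with perspective divide. Points mapping to (or very
#' near) the plane at infinity are returned as `NA` and flagged in the
#' `"valid"` attribute.
#'
#' @param H 3 x 3 homography matrix (or a `homography_transform`).
#' @param points n x 2 matrix of (x, y) coordinates.
#' @return n x 2 matrix of mapped points with logical attribute `"valid"`.
#' @export
apply_homography_to_points <- function(H, points) {
  H <- as_h_matrix(H)
  points <- rbind(points) # tolerate a single point given as a vector
  if (nrow(points) == 0) {
    out <- points
    attr(out, "valid") <- logical(0)
    return(out)
  }
  ph <- H %*% rbind(t(points), 1)
  w <- ph[3, ]
  valid <- abs(w) > 1e-12
  out <- cbind(ph[1, ] / w, ph[2, ] / w)
  out[!valid, ] <- NA_real_
  attr(out, "valid") <- valid
  out
}

transfer_errors <- function(H, src, dst) {
  mapped <- apply_homography_to_points(H, src)
  e <- sqrt(rowSums((mapped - dst)^2))
  e[!attr(mapped, "valid")] <- Inf
  e
}

match_points <- function(matches) {
  if (inherits(matches, "match_set"))
    list(src = cbind(matches$pairs$xa, matches$pairs$ya),
         dst = cbind(matches$pairs$xb, matches$pairs$yb))
  else if (is.list(matches) && !is.null(matches$src))
    list(src = rbind(matches$src), dst = rbind(matches$dst))
  else stop("matches must be a match_set or list(src, dst)", call. = FALSE)
}

#' Estimate a single homography with RANSAC
#'
#' Random 4-point samples are fit by DLT; the model with the most inliers
#' (transfer error strictly below `threshold` pixels) wins, with adaptive
#' early termination at the requested confidence. The winning model is refit
#' by Hartley-normalized DLT least squares on its inlier set. Fully seeded and
#' reproducible.
#'
#' @param matches A `match_set`, or `list(src, dst)` of n x 2 matrices of
#'   corresponding points (start frame -> current frame).
#' @param threshold Inlier reprojection threshold in pixels (default 5).
#' @param seed RNG seed (default 17).
#' @param max_iter Maximum RANSAC iterations (default 2000).
#' @param confidence Early-termination confidence (default 0.995).
#' @return Object of class `homography_transform`: normalized 3 x 3 `H`
#'   (`H[3,3] = 1`), `inlier_indices` into the match list, and the threshold.
#' @export
estimate_single_homography <- function(matches, threshold = 5, seed = 17,
                                       max_iter = 2000, confidence = 0.995) {
  mp <- match_points(matches)
  src <- mp$src; dst <- mp$dst
  n <- nrow(src)
  if (n < 4) stop("at least 4 point pairs are required", call. = FALSE)
  collinear4 <- function(p) {
    for (cmb in list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))) {
      a <- p[cmb[2], ] - p[cmb[1], ]; b <- p[cmb[3], ] - p[cmb[1], ]
      if (abs(a[1] * b[2] - a[2] * b[1]) < 1e-9) return(TRUE)
    }
    FALSE
  }
  best <- NULL
  with_seed(seed, {
    best_count <- 0L; best_err <- Inf
    iter <- 0L; needed <- max_iter
    while (iter < min(max_iter, needed)) {
      iter <- iter + 1L
      s <- sample.int(n, 4)
      if (collinear4(src[s, ]) || collinear4(dst[s, ])) next
      H4 <- tryCatch(dlt_homography(src[s, ], dst[s, ]), error = function(e) NULL)
      if (is.null(H4)) next
      err <- transfer_errors(H4, src, dst)
      inl <- err < threshold
      cnt <- sum(inl)
      serr <- sum(err[inl])
      if (cnt > best_count || (cnt == best_count && serr < best_err)) {
        best_count <- cnt; best_err <- serr
        best <- inl
        if (cnt > 4) {
          w <- cnt / n
          needed <- ceiling(log(1 - confidence) / log(1 - w^4))
        }
      }
    }
  })
  if (is.null(best) || sum(best) < 4)
    stop("homography estimation failed: no consensus set", call. = FALSE)
  H <- dlt_homography(src[best, , drop = FALSE], dst[best, , drop = FALSE])
  # final inlier set under the refit model
  inl <- transfer_errors(H, src, dst) < threshold
  if (sum(inl) >= 4) {
    H <- dlt_homography(src[inl, , drop = FALSE], dst[inl, , drop = FALSE])
    inl <- transfer_errors(H, src, dst) < threshold
  } else inl <- best
  if (abs(det(H)) < 1e-12) stop("degenerate homography", call. = FALSE)
  structure(list(H = normalize_h(H), inlier_indices = which(inl),
                 reproj_threshold = threshold, n_pairs = n),
            class = "homography_transform")
}

#' @export
print.homography_transform <- function(x, ...) {
  cat(sprintf("<homography_transform: %d/%d inliers at %.1f px>\n",
              length(x$inlier_indices), x$n_pairs, x$reproj_threshold))
  print(round(x$H, 4))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Hierarchical multi-affine (HMA) region transforms
# ---------------------------------------------------------------------------

#' Estimate hierarchical multi-affine region transforms
#'
#' Matches are clustered into regions of coherent motion: k-means on the
#' matched positions and displacement vectors seeds initial groups, each group
#' is fit by a local RANSAC homography, groups with inlier ratio below
#' `split_ratio` are bisected (k-means, k = 2, on positions) and refit, and
#' accepted groups are expanded by absorbing unassigned pairs whose transfer
#' error under the group's homography is below `expand_threshold`. Groups with
#' fewer than `min_region` inliers are discarded. A global single homography
#' over all pairs accompanies the regions.
#'
#' @param matches A `match_set` or `list(src, dst)`.
#' @param image_size `c(W, H)` in pixels.
#' @param split_ratio Minimum inlier ratio before a group is bisected
#'   (default 0.5).
#' @param min_region Minimum member count of a region (default 4).
#' @param expand_threshold Absorption transfer-error threshold in px
#'   (default 5, the RANSAC threshold).
#' @param k_init Initial cluster count; default `clamp(round(n/50), 2, 10)`.
#' @param max_depth Maximum bisection depth (default 4).
#' @param seed RNG seed.
#' @param ransac_threshold Local RANSAC reprojection threshold (default 5).
#' @return Object of class `region_transform_set`: list `regions` (each with
#'   `member_idx`, `H_local`, `support_polygon` = convex hull of member
#'   keypoints in current-frame coordinates) and `H_global`.
#' @export
estimate_hma <- function(matches, image_size, split_ratio = 0.5,
                         min_region = 4, expand_threshold = 5, k_init = NULL,
                         max_depth = 4, seed = 17, ransac_threshold = 5) {
  mp <- match_points(matches)
  src <- mp$src; dst <- mp$dst
  n <- nrow(src)
  if (n < 4) stop("at least 4 point pairs are required", call. = FALSE)
  H_global <- estimate_single_homography(mp, threshold = ransac_threshold,
                                         seed = seed)
  if (is.null(k_init)) k_init <- min(max(round(n / 50), 2), 10)
  k_init <- min(k_init, n)
  feats <- cbind(dst, dst - src)
  regions <- list()
  with_seed(seed + 1, {
    km <- suppressWarnings(kmeans(feats, centers = k_init, nstart = 5,
                                  iter.max = 50))
    queue <- lapply(seq_len(k_init), function(k) {
      list(idx = which(km$cluster == k), depth = 0L)
    })
    while (length(queue) > 0) {
      g <- queue[[1]]; queue <- queue[-1]
      if (length(g$idx) < min_region) next
      fit <- tryCatch(
        estimate_single_homography(list(src = src[g$idx, , drop = FALSE],
                                        dst = dst[g$idx, , drop = FALSE]),
                                   threshold = ransac_threshold, seed = seed),
        error = function(e) NULL)
      if (is.null(fit)) next
      ratio <- length(fit$inlier_indices) / length(g$idx)
      if (ratio < split_ratio && g$depth < max_depth &&
            length(g$idx) >= 2 * min_region) {
        km2 <- suppressWarnings(kmeans(dst[g$idx, , drop = FALSE], centers = 2,
                                       nstart = 5, iter.max = 50))
        queue <- c(queue, list(list(idx = g$idx[km2$cluster == 1],
                                    depth = g$depth + 1L),
                               list(idx = g$idx[km2$cluster == 2],
                                    depth = g$depth + 1L)))
      } else {
        regions[[length(regions) + 1]] <- list(
          member_idx = g$idx[fit$inlier_indices], fit = fit)
      }
    }
  })
  # Expansion: absorb unassigned pairs that fit an accepted region's model.
  assigned <- unlist(lapply(regions, `[[`, "member_idx"))
  unassigned <- setdiff(seq_len(n), assigned)
  regions <- lapply(regions, function(r) {
    if (length(unassigned) > 0) {
      err <- transfer_errors(r$fit$H, src[unassigned, , drop = FALSE],
                             dst[unassigned, , drop = FALSE])
      absorb <- unassigned[err < expand_threshold]
      if (length(absorb) > 0) {
        r$member_idx <- sort(c(r$member_idx, absorb))
        unassigned <<- setdiff(unassigned, absorb)
        H <- dlt_homography(src[r$member_idx, , drop = FALSE],
                            dst[r$member_idx, , drop = FALSE])
        r$fit$H <- normalize_h(H)
      }
    }
    r
  })
  regions <- Filter(function(r) length(r$member_idx) >= min_region, regions)
  regions <- lapply(regions, function(r) {
    pts <- dst[r$member_idx, , drop = FALSE]
    hull <- chull(pts)
    list(member_idx = r$member_idx,
         H_local = structure(list(H = r$fit$H,
                                  inlier_indices = r$member_idx,
                                  reproj_threshold = ransac_threshold,
                                  n_pairs = length(r$member_idx)),
                             class = "homography_transform"),
         support_polygon = pts[hull, , drop = FALSE])
  })
  structure(list(regions = regions, H_global = H_global,
                 image_size = image_size),
            class = "region_transform_set")
}

#' @export
print.region_transform_set <- function(x, ...) {
  cat(sprintf("<region_transform_set: %d regions>\n", length(x$regions)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Affine moving-least-squares deformation field
# ---------------------------------------------------------------------------

# Displaced positions of arbitrary query points under affine MLS.
# p, q: n x 2 control pairs; v: m x 2 query points.
mls_affine_map <- function(p, q, v, alpha = 1.0, snap_tol = 1e-9) {
  n <- nrow(p); m <- nrow(v)
  d2 <- outer(v[, 1], p[, 1], "-")^2 + outer(v[, 2], p[, 2], "-")^2 # m x n
  snap <- d2 < snap_tol^2
  w <- 1 / pmax(d2, snap_tol^2)^alpha # 1/|p_i - v|^(2*alpha)
  Sw <- rowSums(w)
  px <- p[, 1]; py <- p[, 2]; qx <- q[, 1]; qy <- q[, 2]
  Sx <- w %*% px; Sy <- w %*% py
  pxs <- Sx / Sw; pys <- Sy / Sw # p*
  qxs <- (w %*% qx) / Sw; qys <- (w %*% qy) / Sw # q*
  # weighted second moments of centered p, and cross moments with centered q
  a11 <- w %*% (px * px) - Sx^2 / Sw
  a12 <- w %*% (px * py) - Sx * Sy / Sw
  a22 <- w %*% (py * py) - Sy^2 / Sw
  b11 <- w %*% (px * qx) - Sx * (w %*% qx) / Sw
  b12 <- w %*% (px * qy) - Sx * (w %*% qy) / Sw
  b21 <- w %*% (py * qx) - Sy * (w %*% qx) / Sw
  b22 <- w %*% (py * qy) - Sy * (w %*% qy) / Sw
  det <- a11 * a22 - a12 * a12
  snapped <- rowSums(snap) > 0
  # vertices snapped onto a control point bypass the solve entirely; their
  # one-point-dominated system is legitimately near-singular
  det[snapped] <- 1
  if (any(abs(det) < 1e-12 * pmax(a11 * a22, 1)))
    stop("collinear control points: singular MLS system", call. = FALSE)
  # M = A^-1 B, f(v) = (v - p*) M + q*
  m11 <- (a22 * b11 - a12 * b21) / det
  m21 <- (a11 * b21 - a12 * b11) / det
  m12 <- (a22 * b12 - a12 * b22) / det
  m22 <- (a11 * b22 - a12 * b12) / det
  vx <- v[, 1] - pxs; vy <- v[, 2] - pys
  fx <- vx * m11 + vy * m21 + qxs
  fy <- vx * m12 + vy * m22 + qys
  # exact snap: a query point coinciding with a control point maps to its q
  if (any(snap)) {
    hit <- which(rowSums(snap) > 0)
    for (i in hit) {
      j <- which(snap[i, ])[1]
      fx[i] <- q[j, 1]; fy[i] <- q[j, 2]
    }
  }
  cbind(as.numeric(fx), as.numeric(fy))
}

#' Estimate an affine moving-least-squares deformation field
#'
#' Each vertex of a uniform lattice over the image receives its own
#' least-squares affine fit to the control pairs, with inverse-distance
#' weights `w_i = 1 / |p_i - v|^(2 * alpha)`; pixels between vertices are
#' bilinearly interpolated. The grid density of 0.2 puts the lattice spacing
#' at `round(1 / 0.2) = 5` px. A vertex coinciding with a control point maps
#' exactly to that control's target.
#'
#' @param control_points `list(p, q)` of n x 2 matrices (source -> target), or
#'   a `match_set`.
#' @param image_size `c(W, H)` in pixels.
#' @param grid_density Lattice vertices per pixel and axis (default 0.2,
#'   i.e. spacing 5 px).
#' @param alpha Weight exponent (default 1.0).
#' @return Object of class `deformation_field` with the lattice coordinates,
#'   the displaced vertex positions `fx`, `fy`, and the control pairs.
#' @export
estimate_mls_field <- function(control_points, image_size, grid_density = 0.2,
                               alpha = 1.0) {
  if (inherits(control_points, "match_set")) {
    mp <- match_points(control_points)
    p <- mp$src; q <- mp$dst
  } else {
    p <- rbind(control_points$p); q <- rbind(control_points$q)
  }
  if (nrow(p) < 3) stop("at least 3 control points are required", call. = FALSE)
  # non-collinearity check on the control points
  ctr <- sweep(p, 2, colMeans(p))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("collinear control points: singular MLS system", call. = FALSE)
  spacing <- max(1L, as.integer(round(1 / grid_density)))
  W <- image_size[1]; H <- image_size[2]
  grid_x <- seq(0L, by = spacing, length.out = ceiling((W - 1) / spacing) + 1L)
  grid_y <- seq(0L, by = spacing, length.out = ceiling((H - 1) / spacing) + 1L)
  verts <- cbind(rep(grid_x, each = length(grid_y)),
                 rep(grid_y, times = length(grid_x)))
  f <- mls_affine_map(p, q, verts, alpha = alpha)
  fx <- matrix(f[, 1], length(grid_y), length(grid_x))
  fy <- matrix(f[, 2], length(grid_y), length(grid_x))
  structure(list(grid_x = grid_x, grid_y = grid_y, fx = fx, fy = fy,
                 spacing = spacing, alpha = alpha, control_p = p,
                 control_q = q, image_size = image_size),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  cat(sprintf("<deformation_field: %d x %d lattice, spacing %d px, alpha %.2f>\n",
              length(x$grid_x), length(x$grid_y), x$spacing, x$alpha))
  invisible(x)
}

#' Evaluate a deformation field at points
#'
#' Bilinear interpolation of the displaced lattice vertices at each query
#' point. Points outside the lattice are clamped to the border cell and
#' flagged in the `"clamped"` attribute.
#'
#' @param field A `deformation_field`.
#' @param points n x 2 matrix of (x, y) coordinates.
#' @return n x 2 matrix of mapped points.
#' @export
apply_field_to_points <- function(field, points) {
  points <- rbind(points)
  s <- field$spacing
  nx <- length(field$grid_x); ny <- length(field$grid_y)
  gx <- points[, 1] / s; gy <- points[, 2] / s
  clamped <- gx < 0 | gx > nx - 1 | gy < 0 | gy > ny - 1
  i0 <- clamp(floor(gy), 0, ny - 2); j0 <- clamp(floor(gx), 0, nx - 2)
  fx <- clamp(gx - j0, 0, 1); fy <- clamp(gy - i0, 0, 1)
  idx <- function(i, j) i + 1L + (j) * ny # column-major linear index
  bilin <- function(M) {
    (1 - fy) * ((1 - fx) * M[idx(i0, j0)] + fx * M[idx(i0, j0 + 1)]) +
      fy * ((1 - fx) * M[idx(i0 + 1, j0)] + fx * M[idx(i0 + 1, j0 + 1)])
  }
  out <- cbind(bilin(field$fx), bilin(field$fy))
  attr(out, "clamped") <- clamped
  out
}

# ---------------------------------------------------------------------------
# Image warping
# ---------------------------------------------------------------------------

#' Warp an image by a homography or deformation field
#'
#' Backward warping with bilinear sampling: for each output pixel the source
#' location is found (through the inverse homography, or by evaluating the
#' deformation field, which is therefore interpreted as the backward map from
#' output coordinates to source coordinates) and the source image is sampled.
#' The validity mask is TRUE exactly where the source location falls inside
#' the source image.
#'
#' To warp a start frame into current-frame geometry with an MLS field, build
#' the field with reversed control pairs (current -> start) and pass it here;
#' [mls_backward_field()] does this.
#'
#' @param image A [frame_image()] or mono matrix.
#' @param transform A `homography_transform`, 3 x 3 matrix, or
#'   `deformation_field`.
#' @return Object of class `warp_result`: `image` (same type as the input,
#'   invalid pixels zeroed) and logical `validity`.
#' @export
warp_image <- function(image, transform) {
  px <- frame_pixels(image)
  is_frame <- length(dim(px)) == 3
  H <- if (is_frame) dim(px)[1] else nrow(px)
  W <- if (is_frame) dim(px)[2] else ncol(px)
  xs <- rep(0:(W - 1), each = H)
  ys <- rep(0:(H - 1), times = W)
  if (inherits(transform, "deformation_field")) {
    src <- apply_field_to_points(transform, cbind(xs, ys))
    sx <- src[, 1]; sy <- src[, 2]
    lattice_ok <- !attr(src, "clamped")
  } else {
    Hm <- as_h_matrix(transform)
    Hinv <- solve(Hm)
    src <- apply_homography_to_points(Hinv, cbind(xs, ys))
    sx <- src[, 1]; sy <- src[, 2]
    lattice_ok <- attr(src, "valid")
    sx[!lattice_ok] <- -1; sy[!lattice_ok] <- -1
  }
  sample_chan <- function(chan) {
    res <- cpp_bilinear_sample(chan, sx, sy)
    v <- res$values
    v[!res$valid] <- 0
    list(img = matrix(v, H, W), valid = matrix(res$valid & lattice_ok, H, W))
  }
  if (is_frame) {
    chans <- lapply(1:3, function(c) sample_chan(matrix(as.numeric(px[, , c]), H, W)))
    out <- array(0L, dim(px))
    for (c in 1:3) out[, , c] <- as_mono(chans[[c]]$img)
    validity <- chans[[1]]$valid
    res_img <- frame_image(out, if (inherits(image, "frame_image"))
      image$frame_index else 0L)
  } else {
    ch <- sample_chan(matrix(as.numeric(px), H, W))
    res_img <- as_mono(ch$img)
    validity <- ch$valid
  }
  structure(list(image = res_img, validity = validity), class = "warp_result")
}

#' Backward MLS field for image warping
#'
#' Builds the deformation field with reversed control pairs so that evaluating
#' it at output-pixel coordinates yields source coordinates, as required by
#' [warp_image()].
#'
#' @inheritParams estimate_mls_field
#' @return A `deformation_field` mapping output coordinates to source
#'   coordinates.
#' @export
mls_backward_field <- function(control_points, image_size, grid_density = 0.2,
                               alpha = 1.0) {
  if (inherits(control_points, "match_set")) {
    mp <- match_points(control_points)
    control_points <- list(p = mp$src, q = mp$dst)
  }
  estimate_mls_field(list(p = control_points$q, q = control_points$p),
                     image_size, grid_density, alpha)
}

#' Serialize a transform to JSON
#' @param transform A `homography_transform` or `deformation_field`.
#' @return JSON string.
#' @export
transform_to_json <- function(transform) {
  if (inherits(transform, "homography_transform")) {
    jsonlite::toJSON(list(type = "homography",
                          H = unclass(transform$H)), auto_unbox = TRUE,
                     digits = NA)
  } else if (inherits(transform, "deformation_field")) {
    jsonlite::toJSON(list(type = "mls", spacing = transform$spacing,
                          alpha = transform$alpha,
                          vertices = list(fx = transform$fx, fy = transform$fy)),
                     auto_unbox = TRUE, digits = NA)
  } else stop("unsupported transform", call. = FALSE)
}
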