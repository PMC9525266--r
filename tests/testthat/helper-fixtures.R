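# Shared fixtures (built in code, cached per test run) and independent
# brute-force oracles used across the suite.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small fast scene shared by evaluation/pipeline tests.
small_spec <- function(...) {
  phantom_spec(seed = 11, size = c(240L, 160L), n_frames = 8L,
               n_landmarks = 12L, max_translation = 8, n_glare = 2L,
               glare_radius = 6, ...)
}

small_scene <- function() cached("small_scene", generate_scene(small_spec()))

# Full-resolution phantom texture plus its detected keypoints.
phantom_tex <- function() cached("phantom_tex", {
  generate_phantom_texture(phantom_spec(seed = 7))
})

phantom_kp <- function() cached("phantom_kp", {
  pp <- preprocess_frame(phantom_tex())
  detect_describe(pp$mono, pp$mask)
})

rand_mono <- function(seed, H, W) {
  set.seed(seed)
  matrix(as.integer(sample(0:255, H * W, replace = TRUE)), H, W)
}

# ---- brute-force oracles -------------------------------------------------

# Grayscale dilation/erosion by direct evaluation over kernel offsets,
# restricted to the kernel positions that fall inside the image.
bf_dilate <- function(x, kern) {
  r <- (nrow(kern) - 1) / 2
  H <- nrow(x); W <- ncol(x)
  out <- matrix(-Inf, H, W)
  for (a in -r:r) for (b in -r:r) {
    if (!kern[a + r + 1, b + r + 1]) next
    si <- max(1, 1 - a):min(H, H - a)
    sj <- max(1, 1 - b):min(W, W - b)
    out[si, sj] <- pmax(out[si, sj], x[si + a, sj + b])
  }
  out
}

bf_erode <- function(x, kern) -bf_dilate(-x, kern)

bf_close <- function(x, kern) bf_erode(bf_dilate(x, kern), kern)

# Binary majority median over the window clipped to the image.
bf_binary_median <- function(mask, size) {
  r <- (size - 1) / 2
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    w <- mask[max(1, i - r):min(H, i + r), max(1, j - r):min(W, j + r)]
    out[i, j] <- sum(w) * 2 > length(w)
  }
  out
}

# Exhaustive mutual-nearest-neighbour Hamming matching on byte descriptors.
bf_hamming <- function(a, b) {
  popcount <- vapply(0:255, function(v) sum(bitwAnd(bitwShiftR(v, 0:7), 1L)),
                     numeric(1))
  d <- matrix(0L, nrow(a), nrow(b))
  for (c in seq_len(ncol(a)))
    d <- d + matrix(popcount[bitwXor(rep(a[, c], times = nrow(b)),
                                     rep(b[, c], each = nrow(a))) + 1L],
                    nrow(a), nrow(b))
  d
}

bf_mutual_nn <- function(a, b) {
  d <- bf_hamming(a, b)
  nn_ab <- apply(d, 1, which.min)
  nn_ba <- apply(d, 2, which.min)
  keep <- which(nn_ba[nn_ab] == seq_len(nrow(a)))
  data.frame(idx_a = keep, idx_b = nn_ab[keep],
             distance = d[cbind(keep, nn_ab[keep])])
}

# Direct (double-loop) SSIM with a replicate-padded 11x11 Gaussian window.
bf_ssim <- function(a, b) {
  k1d <- local({
    r <- 5; k <- exp(-((-r:r)^2) / (2 * 1.5^2)); k / sum(k)
  })
  k2d <- outer(k1d, k1d)
  H <- nrow(a); W <- ncol(a)
  pad <- function(x) x[pmin(pmax(-4:(H + 5), 1), H), pmin(pmax(-4:(W + 5), 1), W)]
  pa <- pad(a); pb <- pad(b)
  c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
  vals <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    wa <- pa[i:(i + 10), j:(j + 10)]
    wb <- pb[i:(i + 10), j:(j + 10)]
    mua <- sum(k2d * wa); mub <- sum(k2d * wb)
    va <- sum(k2d * wa^2) - mua^2
    vb <- sum(k2d * wb^2) - mub^2
    cab <- sum(k2d * wa * wb) - mua * mub
    vals[i, j] <- ((2 * mua * mub + c1) * (2 * cab + c2)) /
      ((mua^2 + mub^2 + c1) * (va + vb + c2))
  }
  mean(vals)
}

# Random small annotation set for round-trip property tests.
random_annotation_set <- function(seed, n_tracks = 5, n_frames = 6,
                                  size = c(200, 150)) {
  set.seed(seed)
  tracks <- lapply(seq_len(n_tracks), function(i) {
    frames <- sort(sample(0:(n_frames - 1), sample(2:n_frames, 1)))
    list(track_id = i - 1L,
         points = data.frame(
           frame = frames,
           x = round(runif(length(frames), 0, size[1] - 1), 3),
           y = round(runif(length(frames), 0, size[2] - 1), 3),
           visible = runif(length(frames)) > 0.2))
  })
  annotation_set(tracks, n_frames, size)
}

expect_annotations_equal <- function(a, b, tol = 1e-3) {
  expect_equal(length(a$tracks), length(b$tracks))
  expect_equal(a$n_frames, b$n_frames)
  for (i in seq_along(a$tracks)) {
    pa <- a$tracks[[i]]$points; pb <- b$tracks[[i]]$points
    expect_equal(a$tracks[[i]]$track_id, b$tracks[[i]]$track_id)
    expect_equal(pa$frame, pb$frame)
    expect_true(all(abs(pa$x - pb$x) < tol))
    expect_true(all(abs(pa$y - pb$y) < tol))
    expect_equal(pa$visible, pb$visible)
  }
}

corner_error <- function(H_est, H_true, size = c(854, 480)) {
  corners <- rbind(c(0, 0), c(size[1] - 1, 0), c(0, size[2] - 1),
                   c(size[1] - 1, size[2] - 1))
  a <- apply_homography_to_points(H_est, corners)
  b <- apply_homography_to_points(H_true, corners)
  mean(sqrt(rowSums((a - b)^2)))
}

# Backward-warp a single channel into an output canvas of arbitrary size.
warp_pad <- function(chan, H, out_hw) {
  Ho <- out_hw[1]; Wo <- out_hw[2]
  xs <- rep(0:(Wo - 1), each = Ho); ys <- rep(0:(Ho - 1), times = Wo)
  src <- apply_homography_to_points(solve(H), cbind(xs, ys))
  res <- lapreg:::cpp_bilinear_sample(chan, src[, 1], src[, 2])
  v <- res$values; v[!res$valid] <- 0
  list(img = matrix(v, Ho, Wo), valid = matrix(res$valid, Ho, Wo))
}

# Two-motion image pair: left half of the base translated by +dx, right half
# by -dx (backward construction, exact by integer shift).
two_motion_frame <- function(base, dx = 20L) {
  px <- base$pixels
  H <- dim(px)[1]; W <- dim(px)[2]
  out <- array(0L, dim(px))
  half <- floor(W / 2)
  for (c in 1:3) {
    plane <- px[, , c]
    moved <- matrix(0L, H, W)
    # left half moved +dx: current(x) = base(x - dx)
    moved[, (dx + 1):half] <- plane[, 1:(half - dx)]
    # right half moved -dx: current(x) = base(x + dx)
    moved[, (half + 1):(W - dx)] <- plane[, (half + 1 + dx):W]
    out[, , c] <- moved
  }
  frame_image(out, 1L)
}
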