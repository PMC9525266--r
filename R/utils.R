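# Internal numeric helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env)
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# Replicate-pad a matrix by r pixels on every side.
pad_replicate <- function(x, r) {
  ri <- c(rep(1L, r), seq_len(nrow(x)), rep(nrow(x), r))
  ci <- c(rep(1L, r), seq_len(ncol(x)), rep(ncol(x), r))
  x[ri, ci, drop = FALSE]
}

# Separable 2-D convolution with an odd-length 1-D kernel and replicate borders.
# Exact arithmetic (no FFT) so results are bit-reproducible across platforms.
conv_sep <- function(x, k) {
  stopifnot(length(k) %% 2 == 1)
  r <- (length(k) - 1L) / 2L
  H <- nrow(x); W <- ncol(x)
  xp <- pad_replicate(x, r)
  tmp <- matrix(0, H, W + 2L * r)
  for (i in seq_along(k)) tmp <- tmp + k[i] * xp[i:(i + H - 1L), , drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_along(k)) out <- out + k[i] * tmp[, i:(i + W - 1L), drop = FALSE]
  out
}

gaussian_kernel1d <- function(size = 11L, sigma = 1.5) {
  r <- (size - 1L) / 2L
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Filled elliptical structuring element of odd side n (inclusive analytic ellipse).
ellipse_kernel <- function(n) {
  stopifnot(n >= 1, n %% 2 == 1)
  r <- (n - 1) / 2
  d <- -r:r
  if (r == 0) return(matrix(TRUE, 1, 1))
  outer(d, d, function(dy, dx) (dx / r)^2 + (dy / r)^2 <= 1 + 1e-9)
}

# Integral-image sum of every h x w window clipped to the image (one value per pixel,
# window centered at the pixel). Used by the binary majority median filter.
window_sums <- function(x, r) {
  H <- nrow(x); W <- ncol(x)
  cs <- apply(x, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  cs <- rbind(0, cbind(0, cs)) # (H+1) x (W+1), cs[i+1, j+1] = sum x[1..i, 1..j]
  i0 <- pmax(seq_len(H) - r - 1L, 0L); i1 <- pmin(seq_len(H) + r, H)
  j0 <- pmax(seq_len(W) - r - 1L, 0L); j1 <- pmin(seq_len(W) + r, W)
  cs[i1 + 1L, j1 + 1L, drop = FALSE] - cs[i0 + 1L, j1 + 1L, drop = FALSE] -
    cs[i1 + 1L, j0 + 1L, drop = FALSE] + cs[i0 + 1L, j0 + 1L, drop = FALSE]
}

# Binary majority median with a (2r+1) x (2r+1) square window clipped at the borders.
# Ties (possible only in clipped even-sized border windows) resolve to FALSE.
binary_median <- function(mask, size) {
  stopifnot(size %% 2 == 1)
  r <- (size - 1L) / 2L
  H <- nrow(mask); W <- ncol(mask)
  counts <- window_sums(matrix(as.numeric(mask), H, W), r)
  sizes <- window_sums(matrix(1, H, W), r)
  counts * 2 > sizes
}

# ITU-R BT.601 luma of an RGB frame, rounded to 8-bit.
frame_luma <- function(frame) {
  px <- frame_pixels(frame)
  as_mono(0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3])
}

as_mono <- function(x) {
  m <- matrix(as.integer(round(clamp(x, 0, 255))), nrow(x), ncol(x))
  m
}
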