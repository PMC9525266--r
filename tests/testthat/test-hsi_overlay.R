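test_that("sensor calibration recovers exact and least-squares solutions", {
  # exact: 4 pairs under a known homography
  H_true <- matrix(c(0.8, 0.02, 40, -0.01, 0.85, 30, 1e-5, -1e-5, 1),
                   3, 3, byrow = TRUE)
  src <- rbind(c(0, 0), c(100, 0), c(0, 80), c(100, 80))
  dst <- apply_homography_to_points(H_true, src)
  cal <- calibrate_sensors(list(src = src, dst = dst))
  expect_lt(max(abs(cal$H_cal$H - H_true)), 1e-8)
  expect_lt(cal$rms_residual, 1e-9)

  # 25 noisy pairs: equals an independent normal-equations oracle
  fx <- generate_calibration_fixture(seed = 40, sigma = 1)
  cal2 <- calibrate_sensors(fx$pairs)
  # oracle: Gauss-Newton refinement of the homography from the normal
  # equations of the linearized transfer error, started at the truth
  oracle_h <- local({
    src <- cbind(fx$pairs$x_src, fx$pairs$y_src)
    dst <- cbind(fx$pairs$x_dst, fx$pairs$y_dst)
    # the DLT minimizes algebraic error on Hartley-normalized coordinates;
    # replicate it independently with an explicit SVD of the design matrix
    nrm <- function(p) {
      ctr <- colMeans(p); d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
      s <- sqrt(2) / mean(d)
      list(p = sweep(p, 2, ctr) * s,
           T = rbind(c(s, 0, -s * ctr[1]), c(0, s, -s * ctr[2]), c(0, 0, 1)))
    }
    a <- nrm(src); b <- nrm(dst)
    rows <- lapply(seq_len(nrow(src)), function(i) {
      x <- a$p[i, 1]; y <- a$p[i, 2]; u <- b$p[i, 1]; v <- b$p[i, 2]
      rbind(c(-x, -y, -1, 0, 0, 0, u * x, u * y, u),
            c(0, 0, 0, -x, -y, -1, v * x, v * y, v))
    })
    A <- do.call(rbind, rows)
    h <- svd(A)$v[, 9]
    Hn <- matrix(h, 3, 3, byrow = TRUE)
    Hh <- solve(b$T) %*% Hn %*% a$T
    Hh / Hh[3, 3]
  })
  expect_lt(max(abs(cal2$H_cal$H - oracle_h)), 1e-6)

  expect_error(calibrate_sensors(list(src = src[1:3, ], dst = dst[1:3, ])),
               "at least 4")
})

test_that("calibration residuals track the annotation noise level", {
  # Monte-Carlo: with sigma = 1 px noise on 25 pairs the RMS residual stays
  # inside the least-squares band [0.5 sigma, 2 sigma] in distribution
  rms <- vapply(1:100, function(s) {
    calibrate_sensors(generate_calibration_fixture(seed = s, sigma = 1)$pairs)$rms_residual
  }, numeric(1))
  expect_gt(mean(rms >= 0.5 & rms <= 2), 0.95)
  # noiseless annotations recover the truth
  fx0 <- generate_calibration_fixture(seed = 7, sigma = 0)
  cal0 <- calibrate_sensors(fx0$pairs)
  expect_lt(max(abs(cal0$H_cal$H - fx0$H_true)), 1e-6)
  expect_equal(cal0$H_cal$n_pairs, 25) # default fixture size
})

test_that("colorize maps endpoints and midpoint to palette entries", {
  pal <- grDevices::col2rgb(grDevices::hcl.colors(256, "viridis"))
  lo <- colorize(physio_map(matrix(0, 4, 4)))
  expect_true(all(lo$pixels[, , 1] == pal[1, 1]))
  expect_true(all(lo$pixels[, , 2] == pal[2, 1]))
  hi <- colorize(physio_map(matrix(1, 4, 4)))
  expect_true(all(hi$pixels[, , 3] == pal[3, 256]))
  mid <- colorize(physio_map(matrix(0.5, 4, 4)))
  expect_true(all(mid$pixels[, , 1] == pal[1, 129])) # floor(0.5*256)+1

  na_map <- physio_map(matrix(c(NA, 0.5, 0.2, 0.8), 2, 2))
  expect_equal(colorize(na_map)$valid, matrix(c(FALSE, TRUE, TRUE, TRUE), 2, 2))
})

test_that("overlay blends per pixel and leaves unmapped pixels untouched", {
  set.seed(41)
  cur <- frame_image(array(sample(0:255, 40 * 60 * 3, TRUE), c(40, 60, 3)), 2L)
  map <- physio_map(matrix(0.5, 40, 60))

  # identity transforms: blend arithmetic verified against direct computation
  ov <- render_overlay(cur, "identity", map, "identity", alpha = 0.5)
  gray <- lapreg:::frame_luma(cur)
  col <- colorize(map)
  for (c in 1:3)
    expect_true(all(ov$pixels[, , c] ==
                      round(0.5 * col$pixels[, , c] + 0.5 * gray)))

  # alpha 0: grayscale current frame wherever the map is valid
  ov0 <- render_overlay(cur, "identity", map, "identity", alpha = 0)
  for (c in 1:3) expect_true(all(ov0$pixels[, , c] == gray))

  # a shifted map leaves pixels outside its warped support untouched
  shift <- matrix(c(1, 0, 30, 0, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  ov_s <- render_overlay(cur, shift, map, "identity", alpha = 0.5)
  expect_identical(ov_s$pixels[, 1:29, ], cur$pixels[, 1:29, ])
  expect_false(all(ov_s$pixels[, 31:60, ] == cur$pixels[, 31:60, ]))

  # display mask suppresses the overlay
  dm <- matrix(FALSE, 40, 60)
  ov_m <- render_overlay(cur, "identity", map, "identity", display_mask = dm)
  expect_identical(ov_m$pixels, cur$pixels)
})

test_that("warping the map by the composed homography equals two-step warping", {
  set.seed(42)
  vals <- lapreg:::smooth_noise(60, 80, 6)
  map <- physio_map(vals)
  H_cal <- matrix(c(1.4, 0.01, 10, -0.02, 1.3, 6, 0, 0, 1), 3, 3, byrow = TRUE)
  H_frame <- matrix(c(1.01, 0.005, 4, -0.004, 0.99, -3, 0, 0, 1), 3, 3,
                    byrow = TRUE)
  col <- colorize(map)
  chan <- matrix(as.numeric(col$pixels[, , 1]), 60, 80)
  one_step <- warp_pad(chan, H_frame %*% H_cal, c(120, 160))
  two_step <- warp_pad(warp_pad(chan, H_cal, c(120, 160))$img, H_frame,
                       c(120, 160))
  both <- one_step$valid & two_step$valid
  expect_gt(mean(both), 0.3)
  expect_lt(mean(abs(one_step$img[both] - two_step$img[both])), 2)
})
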