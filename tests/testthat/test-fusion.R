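test_that("region validity enforces the area and homography-difference rules", {
  Hg <- diag(3)
  big_poly <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100)) # 10000 px^2
  small_poly <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)) # 100 px^2
  size <- c(300, 300) # image area 90000; 2% = 1800

  same <- list(H_local = Hg, support_polygon = big_poly)
  expect_true(validate_region(same, Hg, size))

  tiny <- list(H_local = Hg, support_polygon = small_poly)
  expect_false(validate_region(tiny, Hg, size)) # 1% of area: invalid always

  far <- diag(3); far[1, 3] <- 60 # one entry differing by 60 > 50
  expect_false(validate_region(list(H_local = far, support_polygon = big_poly),
                               Hg, size))
  near <- diag(3); near[1, 3] <- 49.9
  expect_true(validate_region(list(H_local = near, support_polygon = big_poly),
                              Hg, size))

  unnorm <- diag(3) * 2
  expect_error(validate_region(list(H_local = unnorm, support_polygon = big_poly),
                               Hg, size), "normalized")
})

test_that("error image matches a brute-force closing oracle on 64x64 crops", {
  kern <- lapreg:::ellipse_kernel(35)

  # exact alignment, all valid -> zero error everywhere
  set.seed(20)
  px <- array(sample(0:255, 64 * 64 * 3, replace = TRUE), c(64, 64, 3))
  f <- frame_image(px)
  warp_same <- structure(list(image = f, validity = matrix(TRUE, 64, 64)),
                         class = "warp_result")
  expect_true(all(build_error_image(warp_same, f) == 0))

  # invalid region forces saturated error there
  wv <- structure(list(image = f, validity = matrix(TRUE, 64, 64)),
                  class = "warp_result")
  wv$validity[1:20, 1:20] <- FALSE
  err_inv <- build_error_image(wv, f)
  expect_true(all(err_inv[1:10, 1:10] == 255))

  # random pair: abs green difference + closing equals the set-morphology oracle
  px2 <- array(sample(0:255, 64 * 64 * 3, replace = TRUE), c(64, 64, 3))
  f2 <- frame_image(px2)
  got <- build_error_image(warp_same, f2)
  raw <- abs(px[, , 2] - px2[, , 2])
  expected <- bf_close(raw / 255, kern) * 255
  expect_lt(max(abs(got - expected)), 1e-6)

  # isolated differing pixel amid zeros survives closing at its value
  base <- array(100L, c(64, 64, 3))
  spot <- base; spot[32, 32, 2] <- 180L
  wb <- structure(list(image = frame_image(base),
                       validity = matrix(TRUE, 64, 64)), class = "warp_result")
  err_spot <- build_error_image(wb, frame_image(spot))
  oracle <- bf_close(matrix(c(0, 80)[1 + (row(matrix(0, 64, 64)) == 32 &
                                            col(matrix(0, 64, 64)) == 32)],
                            64, 64) / 255, kern) * 255
  expect_lt(max(abs(err_spot - oracle)), 1e-6)
  expect_equal(err_spot[32, 32], 80)
})

test_that("fusion selects the per-pixel argmin with SH-first tie-breaking", {
  set.seed(21)
  mk_cand <- function(err, val) {
    img <- frame_image(array(val, c(32, 32, 3)))
    list(warp = structure(list(image = img, validity = matrix(TRUE, 32, 32)),
                          class = "warp_result"),
         error_image = err, label = sprintf("cand-%d", val))
  }
  e1 <- matrix(runif(1024, 0, 255), 32, 32)
  e2 <- matrix(runif(1024, 0, 255), 32, 32)
  fus <- fuse_candidates(list(mk_cand(e1, 10L), mk_cand(e2, 200L)))
  expect_equal(fus$combined_error, pmin(e1, e2))
  expect_equal(fus$source_index, matrix(ifelse(e2 < e1, 2L, 1L), 32, 32))
  expect_true(all(fus$fused_image$pixels[, , 1][fus$source_index == 1] == 10))
  expect_true(all(fus$fused_image$pixels[, , 1][fus$source_index == 2] == 200))

  # ties go to the earlier candidate (the single homography)
  fus_tie <- fuse_candidates(list(mk_cand(e1, 10L), mk_cand(e1, 200L)))
  expect_true(all(fus_tie$source_index == 1L))

  # single candidate: passthrough
  fus1 <- fuse_candidates(list(mk_cand(e1, 7L)))
  expect_true(all(fus1$source_index == 1L))
  expect_equal(fus1$combined_error, e1)

  # monotonicity: adding a candidate never increases the combined error
  e3 <- matrix(runif(1024, 0, 255), 32, 32)
  fus3 <- fuse_candidates(list(mk_cand(e1, 10L), mk_cand(e2, 200L),
                               mk_cand(e3, 90L)))
  expect_true(all(fus3$combined_error <= fus$combined_error + 1e-12))

  expect_error(fuse_candidates(list()), "no candidates")
})

test_that("display mask thresholds at 10% of range and median-filters", {
  # boundary: integer error 26 is suppressed, 25 is not (before filtering)
  e <- matrix(0, 64, 64)
  e[10:40, 10:40] <- 26
  m <- build_display_mask(e)
  expect_true(m[25, 25])
  e2 <- matrix(0, 64, 64); e2[10:40, 10:40] <- 25
  expect_false(any(build_display_mask(e2)))

  expect_false(any(build_display_mask(matrix(0, 64, 64))))

  # a single isolated high-error pixel is removed by the majority median
  e3 <- matrix(0, 64, 64); e3[32, 32] <- 255
  expect_false(any(build_display_mask(e3)))

  # exhaustive agreement with the brute-force majority-median oracle
  set.seed(22)
  for (rep in 1:3) {
    err <- matrix(sample(0:40, 64 * 64, replace = TRUE), 64, 64)
    got <- build_display_mask(err)
    expect_identical(got, bf_binary_median(err > 25.5, 35))
  }
})

test_that("output composition splices fused and original frames exactly", {
  set.seed(23)
  cur <- frame_image(array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3)), 5L)
  fus_img <- frame_image(array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3)))
  fus <- structure(list(fused_image = fus_img,
                        source_index = matrix(1L, 32, 32),
                        combined_error = matrix(0, 32, 32),
                        display_mask = NULL), class = "fusion_result")

  # no suppression: fused image everywhere
  fus$display_mask <- matrix(TRUE, 32, 32)
  expect_identical(compose_output(fus, cur)$pixels, fus_img$pixels)

  # full suppression: original frame
  fus$display_mask <- matrix(FALSE, 32, 32)
  expect_identical(compose_output(fus, cur)$pixels, cur$pixels)

  # half suppression: pixel-exact splice
  half <- matrix(FALSE, 32, 32); half[, 1:16] <- TRUE
  fus$display_mask <- half
  out <- compose_output(fus, cur)
  expect_identical(out$pixels[, 1:16, ], fus_img$pixels[, 1:16, ])
  expect_identical(out$pixels[, 17:32, ], cur$pixels[, 17:32, ])
  expect_equal(out$frame_index, 5L)
})
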