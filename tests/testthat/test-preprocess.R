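test_that("block-mean downsampling pools correctly and composes", {
  x <- array(c(1, 5, 3, 7), c(2, 2, 1))
  expect_equal(downsample_spatial(x, 2)[1, 1, 1], 4)
  m <- array(runif(12 * 12 * 3), c(12, 12, 3))
  expect_identical(downsample_spatial(m, 1), m)
  expect_equal(downsample_spatial(array(2.5, c(12, 12, 2)), 6),
               array(2.5, c(2, 2, 2)))
  # a then b equals a*b on divisible shapes
  expect_equal(downsample_spatial(downsample_spatial(m, 2), 3),
               downsample_spatial(m, 6), tolerance = 1e-12)
  # non-divisible shapes crop trailing rows/cols
  m2 <- array(runif(13 * 14 * 2), c(13, 14, 2))
  expect_equal(downsample_spatial(m2, 6),
               downsample_spatial(m2[1:12, 1:12, , drop = FALSE], 6))
  expect_error(downsample_spatial(m, 0), "positive")
})

test_that("dF/F matches its definition and centers at zero for mean baseline", {
  const <- array(3, c(4, 4, 10))
  expect_true(all(compute_dff(const) == 0))
  m <- array(2, c(2, 2, 4))
  m[1, 1, 3] <- 4    # F = 2 F0 at one frame (baseline percentile)
  d <- compute_dff(m, baseline_method = "percentile", percentile = 10)
  expect_equal(d[1, 1, 3], 1.0)
  truth <- quiet_session(seed = 3, T_frames = 50)
  dm <- compute_dff(truth$movie)
  expect_lt(max(abs(apply(dm, c(1, 2), mean))), 1e-12)
  neg <- array(c(-1, rep(1, 4 * 4 * 5 - 1)), c(4, 4, 5))
  expect_error(compute_dff(neg - 2), "pixel")
})

test_that("spatial bandpass removes DC and broad structure but keeps cell scale", {
  expect_lt(max(abs(spatial_bandpass(array(3.7, c(32, 32, 2)), c(5, 15)))),
            1e-12)
  H <- 64
  rows <- matrix(rep(1:H, H), H, H); cols <- t(rows)
  broad <- exp(-((rows - 32)^2 + (cols - 32)^2) / (2 * (H / 4)^2))
  out_b <- spatial_bandpass(array(broad, c(H, H, 1)), c(5, 31))[, , 1]
  expect_lt(sum(out_b^2), 0.05 * sum(broad^2))
  blob <- exp(-((rows - 32)^2 + (cols - 32)^2) / (2 * 3^2))
  out_c <- spatial_bandpass(array(blob, c(H, H, 1)), c(5, 31))[, , 1]
  expect_gt(max(out_c), 0.5 * max(blob))
  expect_error(spatial_bandpass(array(0, c(16, 16, 1)), c(10, 5)), "cutoff")
})

test_that("bandpass is linear and agrees with an independent Gaussian filter", {
  set.seed(1)
  x <- array(rnorm(32 * 32 * 2), c(32, 32, 2))
  y <- array(rnorm(32 * 32 * 2), c(32, 32, 2))
  lhs <- spatial_bandpass(2 * x + 3 * y, c(5, 15))
  rhs <- 2 * spatial_bandpass(x, c(5, 15)) + 3 * spatial_bandpass(y, c(5, 15))
  expect_equal(lhs, rhs, tolerance = 1e-10)

  skip_if_not_installed("EBImage")
  # interior agreement with EBImage's Gaussian blur (boundary handling differs)
  sig <- 5 / 4
  ours <- stimscope:::gaussian_blur_stack(x, sig)
  theirs <- EBImage::gblur(x, sigma = sig)
  # kernel truncation radii differ between the implementations
  interior <- ours[9:24, 9:24, ] - theirs[9:24, 9:24, ]
  expect_lt(max(abs(interior)), 2e-3)
})

test_that("rigid motion correction recovers injected shifts on quiescent data", {
  truth <- quiet_session(seed = 2, T_frames = 30)
  m <- truth$movie
  mc0 <- motion_correct_rigid(m, reference = m[, , 1], max_shift_px = 5)
  expect_lt(max(abs(mc0$shifts)), 0.5)     # already aligned

  sh <- matrix(0L, 30, 2)
  sh[10, ] <- c(3L, -2L)
  mc <- motion_correct_rigid(inject_jitter(m, sh), reference = m[, , 1],
                             max_shift_px = 5)
  expect_equal(mc$shifts[10, ], c(3, -2), tolerance = 0.5)
  # the corrected frame matches the original away from the filled edge
  expect_lt(max(abs(mc$movie[10:50, 10:50, 10] - m[10:50, 10:50, 10])), 1e-10)

  const <- array(1, c(32, 32, 3))
  mcc <- motion_correct_rigid(const, max_shift_px = 5)
  expect_true(all(mcc$shifts == 0))
  expect_error(motion_correct_rigid(m, max_shift_px = 40), "half")
})

test_that("motion correction round-trip residual stays subpixel at adequate SNR", {
  n_bad <- 0; n_tot <- 0
  for (s in 1:3) {
    truth <- quiet_session(seed = s, T_frames = 30)
    set.seed(100 + s)
    sh <- matrix(sample(-4:4, 60, replace = TRUE), 30, 2)
    mc <- motion_correct_rigid(inject_jitter(truth$movie, sh),
                               reference = truth$movie[, , 1],
                               max_shift_px = 5)
    res <- abs(mc$shifts - sh)
    n_tot <- n_tot + nrow(sh)
    n_bad <- n_bad + sum(rowSums(res > 0.5) > 0)
  }
  expect_lt(n_bad / n_tot, 0.05)
})
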