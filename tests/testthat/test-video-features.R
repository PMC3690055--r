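test_that("pixel difference is a symmetric mean absolute difference", {
  a <- matrix(0, 20, 20)
  b <- matrix(255, 20, 20)
  expect_equal(pixel_difference(a, a), 0)
  expect_equal(pixel_difference(a, b), 255)
  set.seed(3)
  cb <- matrix(rep(c(0, 255), length.out = 400), 20)
  cb2 <- cbind(cb[, -1], cb[, 1])
  expect_equal(pixel_difference(cb, cb2), oracle_pixel_diff(cb, cb2))
  expect_equal(pixel_difference(cb, cb2), pixel_difference(cb2, cb))
  expect_error(pixel_difference(a, matrix(0, 10, 20)), "mismatch")
})

test_that("Sobel magnitude matches an explicit convolution", {
  expect_true(all(sobel_magnitude(matrix(17, 12, 12)) == 0))
  # vertical step edge: horizontal mask responds with 4*255, vertical with 0
  step <- cbind(matrix(0, 10, 5), matrix(255, 10, 5))
  sm <- sobel_magnitude(step)
  expect_equal(sm[5, 5], 4 * 255) # column adjacent to the edge
  expect_equal(sm[5, 2], 0)
  set.seed(9)
  tx <- matrix(round(runif(15 * 17, 0, 255)), 15, 17)
  expect_equal(sobel_magnitude(tx), oracle_sobel(tx), tolerance = 1e-6)
})

test_that("edge pixel difference composes Sobel maps with the pixel difference", {
  expect_equal(edge_pixel_difference(matrix(10, 16, 16), matrix(200, 16, 16)), 0)
  set.seed(4)
  tx <- matrix(round(runif(30 * 30, 0, 255)), 30)
  expect_equal(edge_pixel_difference(tx, tx), 0)
  tx2 <- cbind(tx[, -(1:2)], tx[, 1:2])
  expect_equal(edge_pixel_difference(tx, tx2),
               oracle_pixel_diff(oracle_sobel(tx), oracle_sobel(tx2)),
               tolerance = 1e-6)
})

test_that("Lucas-Kanade tracking recovers known translations and drops the untrackable", {
  p <- make_shifted_pair(21, dx = 0)
  mv0 <- track_motion(p$a, p$a)
  expect_gt(nrow(mv0), 10)
  expect_lte(max(mv0$magnitude), 0.1)
  p5 <- make_shifted_pair(21, dx = 5)
  mv5 <- track_motion(p5$a, p5$b)
  expect_equal(mean(mv5$magnitude), 5, tolerance = 0.1)
  # crop moves right => scene content moves left
  expect_lt(mean(mv5$dx), 0)
  expect_gt(abs(mean(mv5$dx)), 10 * abs(mean(mv5$dy)))
  expect_equal(nrow(track_motion(matrix(50, 60, 60), matrix(50, 60, 60))), 0L)
})

test_that("motion-vector summaries threshold then average", {
  expect_equal(motion_features(numeric(0)), c(mv_avg_mag = 0, mv_count = 0))
  expect_equal(motion_features(c(3, 4, 5)), c(mv_avg_mag = 4, mv_count = 3))
  expect_equal(motion_features(c(0.1, 6, 8), min_mag = 0.5),
               c(mv_avg_mag = 7, mv_count = 2))
})

test_that("pixel difference and motion magnitude grow with translation size", {
  pd <- mv <- numeric(6)
  shifts <- c(0, 2, 4, 6, 8, 10)
  for (i in seq_along(shifts)) {
    p <- make_shifted_pair(31, dx = shifts[i])
    pd[i] <- pixel_difference(p$a, p$b)
    mv[i] <- motion_features(track_motion(p$a, p$b))["mv_avg_mag"]
  }
  expect_true(all(diff(pd) >= 0))
  expect_true(all(diff(mv) >= 0))
  expect_equal(mv, shifts, tolerance = 0.2)
})

test_that("the sequence feature table equals composing the per-pair operations", {
  cfg <- session_config(duration_s = 1.2, seed = 7)
  fs <- generate_frames(cfg, 2, seed = 5)
  vt <- video_feature_table(fs)
  expect_equal(nrow(vt), dim(fs$frames)[3] - 1)
  i <- 11
  a <- get_frame(fs, i); b <- get_frame(fs, i + 1)
  expect_equal(vt$pixel_diff[i], pixel_difference(a, b), tolerance = 1e-4)
  expect_equal(vt$edge_diff[i], edge_pixel_difference(a, b), tolerance = 1e-3)
  mf <- motion_features(track_motion(a, b))
  expect_equal(vt$mv_avg_mag[i], unname(mf["mv_avg_mag"]), tolerance = 1e-4)
  expect_equal(vt$mv_count[i], unname(mf["mv_count"]))
})
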