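test_that("the generator is deterministic under a fixed seed", {
  cfg <- session_config(duration_s = 3, n_subjects = 1, seed = 4)
  e1 <- generate_eeg(cfg, 2, seed = 9)
  e2 <- generate_eeg(cfg, 2, seed = 9)
  expect_identical(e1$samples, e2$samples)
  f1 <- generate_frames(cfg, 2, seed = 9)
  f2 <- generate_frames(cfg, 2, seed = 9)
  expect_identical(f1$frames, f2$frames)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$manifest, s2$manifest)
  expect_identical(s1$eeg[[1]]$samples, s2$eeg[[1]]$samples)
})

test_that("still-class EEG is low-frequency dominant and movement shifts energy up", {
  cfg <- session_config(duration_s = 6, seed = 1)
  st1 <- generate_eeg(cfg, 1, seed = 2)
  tab1 <- eeg_feature_table(st1, step = 16)
  expect_gt(mean(tab1$f_3_15), mean(tab1$f_20_30))
  st2 <- generate_eeg(cfg, 2, seed = 2)
  tab2 <- eeg_feature_table(st2, step = 16)
  ratio <- function(tab) mean(tab$f_20_30) / mean(tab$f_3_15)
  expect_gt(ratio(tab2), ratio(tab1))
})

test_that("frame counts, still/moving contrast and pan recovery match the motion model", {
  cfg <- session_config(duration_s = 4, seed = 3)
  fs1 <- generate_frames(cfg, 1, seed = 5)
  fs2 <- generate_frames(cfg, 2, seed = 5)
  expect_equal(dim(fs1$frames)[3], round(4 * 30))
  vf1 <- video_feature_table(fs1)
  vf2 <- video_feature_table(fs2)
  expect_lt(mean(vf1$pixel_diff), 0.02 * mean(vf2$pixel_diff))
  # at pan speed peaks the recovered magnitude tracks the true displacement
  dx <- abs(diff(fs2$truth$offset_x))
  pk <- which(dx > 0.95 * max(dx))
  expect_lt(max(abs(vf2$mv_avg_mag[pk] - dx[pk])), 1)
  # an overdriven pan that leaves the texture margin is an error
  cfg$motion_spec$pan_speed_px <- 4000
  expect_error(generate_frames(cfg, 2, seed = 5), "margin")
})

test_that("sessions are balanced, trial-pure and sized by the cadence formulas", {
  cfg <- session_config(duration_s = 3, n_subjects = 10, seed = 6)
  sess <- generate_session(cfg)
  expect_equal(nrow(sess$manifest), 40L)
  expect_equal(sum(sess$manifest$class == 1), 20L)
  expect_false(any(duplicated(sess$manifest$trial_id)))
  expect_setequal(unique(sess$manifest$fold), 1:2)
  # within each fold: every subject, both classes
  for (f in 1:2) {
    mf <- sess$manifest[sess$manifest$fold == f, ]
    expect_equal(sort(unique(mf$subject)), 1:10)
    expect_setequal(unique(mf$class), 1:2)
  }
  st <- sess$eeg[[1]]
  expect_equal(length(st$samples), round(3 * 128))
  expect_equal(length(sliding_epochs(st)$end_index), round(3 * 128) - 127)
})

test_that("stronger class contrast cannot worsen the end-to-end error", {
  errs <- vapply(list(
    list(pan = 0.25, hf = 1.3, lf = 0.9),
    list(pan = 1.0, hf = 2.0, lf = 0.7),
    list(pan = 4.0, hf = 4.0, lf = 0.5)), function(s) {
    cfg <- session_config(duration_s = 6, n_subjects = 2, seed = 17,
                          class2_spec = list(low_factor = s$lf,
                                             high_factor = s$hf))
    cfg$motion_spec$pan_speed_px <- s$pan
    feats <- extract_session_features(generate_session(cfg))
    pcfg <- pipeline_config(grid = data.frame(kernel = "radial", r = 2,
                                              c = NA, d = NA, cost = 10),
                            grid_stride = 4L, fit_stride = 2L)
    twofold_cv(feats, pcfg)$averaged$average
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9),
              label = sprintf("errors non-increasing: %s",
                              paste(round(errs, 2), collapse = " -> ")))
})
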