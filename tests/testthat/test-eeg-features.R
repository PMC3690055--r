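test_that("epoch normalization removes the mean then maps the range onto [-1, 1]", {
  expect_equal(normalize_epoch(c(1, 3, 5)), c(-1, 0, 1))
  expect_equal(normalize_epoch(c(0, 1, 3)), c(-1, -1 / 3, 1))
  for (seed in 1:20) {
    set.seed(seed)
    x <- rnorm(128)
    got <- normalize_epoch(x)
    expect_equal(min(got), -1)
    expect_equal(max(got), 1)
    expect_equal(got, oracle_normalize(x), tolerance = 1e-12)
  }
  expect_error(normalize_epoch(rep(2, 128), end_index = 421L), "421")
})

test_that("sliding epochs conserve counts and flag degenerate segments", {
  st <- eeg_stream(rnorm(128))
  expect_equal(length(sliding_epochs(st)$end_index), 1L)
  st <- eeg_stream(rnorm(130))
  ep <- sliding_epochs(st)
  expect_equal(ep$end_index, c(128L, 129L, 130L))
  st <- eeg_stream(rnorm(1000))
  expect_equal(length(sliding_epochs(st)$end_index), 873L)
  expect_equal(length(sliding_epochs(st, step = 128)$end_index),
               length(seq.int(128, 1000, by = 128)))
  # a constant-valued stretch is flagged, not dropped
  x <- rnorm(300)
  x[101:260] <- 7
  ep <- sliding_epochs(eeg_stream(x))
  expect_equal(length(ep$valid), 300 - 127)
  expect_true(any(!ep$valid))
  expect_true(all(is.na(ep$values[, !ep$valid])))
  # too-short stream: empty result plus a warning
  expect_warning(ep <- sliding_epochs(eeg_stream(rnorm(100))), "shorter")
  expect_equal(length(ep$end_index), 0L)
})

test_that("band magnitudes localize pure tones and match the DFT oracle", {
  expect_equal(unname(frequency_features(rep(0, 128))), rep(0, 12))
  bands <- default_bands()
  s10 <- sin(2 * pi * 10 * (0:127) / 128)
  ff <- frequency_features(s10)
  holds10 <- bands$low <= 10 & bands$high >= 10
  expect_gte(sum(ff[holds10]) / sum(ff), 0.99)
  for (seed in 1:5) {
    set.seed(seed)
    x <- normalize_epoch(rnorm(128))
    expect_equal(unname(frequency_features(x)),
                 oracle_band_features(x, bands), tolerance = 1e-9)
  }
  bad <- data.frame(name = "x", low = 3, high = 70)
  expect_error(frequency_features(s10, bands = bad), "Nyquist")
})

test_that("the 13 time-domain statistics follow their printed definitions", {
  alt <- rep(c(1, -1), 64)
  tf <- time_features(alt)
  expect_equal(unname(tf["zero_crossings"]), 127)
  expect_equal(unname(tf["minimum"]), -1)
  expect_equal(unname(tf["maximum"]), 1)
  expect_equal(unname(tf["rms_amplitude"]), 1 / sqrt(2))
  ramp <- seq(0, 1, length.out = 128)
  tf <- time_features(ramp)
  expect_equal(unname(tf["var_d1"]), 0)
  expect_equal(unname(tf["zc_d1"]), 0)
  for (seed in 1:20) {
    set.seed(seed)
    x <- rnorm(128)
    expect_equal(unname(time_features(x)), unname(oracle_time_features(x)),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_error(time_features(rep(3, 128)), "zero-variance")
})

test_that("feature scale behaviour: shape statistics invariant, energy statistics covariant", {
  scale_free <- c("kurtosis", "skewness", "mobility", "complexity")
  for (seed in 1:10) {
    set.seed(seed)
    x <- rnorm(128)
    cc <- runif(1, 0.1, 10)
    t1 <- time_features(x)
    t2 <- time_features(cc * x)
    expect_equal(t2[scale_free], t1[scale_free], tolerance = 1e-9)
    expect_equal(unname(t2["activity"]), unname(cc^2 * t1["activity"]),
                 tolerance = 1e-9)
    expect_equal(frequency_features(cc * x), cc * frequency_features(x),
                 tolerance = 1e-9)
    # integer counts stay integers
    expect_true(all(t1[c("zero_crossings", "zc_d1", "zc_d2")] %% 1 == 0))
  }
})

test_that("a pure tone maximizes a band that contains it", {
  bands <- default_bands()
  covered <- Filter(function(k) any(bands$low <= k & bands$high >= k), 3:63)
  for (k in covered) {
    ff <- frequency_features(sin(2 * pi * k * (0:127) / 128))
    top <- which.max(ff)
    expect_true(bands$low[top] <= k && bands$high[top] >= k,
                label = sprintf("%d Hz localized", k))
  }
})

test_that("the per-epoch feature table matches the single-epoch operations", {
  st <- eeg_stream(rnorm(400), trial_id = "t")
  tab <- eeg_feature_table(st)
  expect_equal(nrow(tab), 273)
  i <- 100
  ep <- normalize_epoch(st$samples[(tab$end_index[i] - 127):tab$end_index[i]])
  expect_equal(unlist(tab[i, default_bands()$name]),
               frequency_features(ep), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unlist(tab[i, time_feature_names()]),
               unname(time_features(ep)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(tab$end_time[i], st$t0 + tab$end_index[i] / st$rate)
})
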