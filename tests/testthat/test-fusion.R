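make_eeg_table <- function(n_epochs, rate = 128) {
  data.frame(end_index = seq_len(n_epochs) + 127,
             end_time = (seq_len(n_epochs) + 127) / rate,
             valid = TRUE, feat = rnorm(n_epochs))
}

test_that("synchronization pairs each frame with the nearest completed epoch", {
  ef <- make_eeg_table(512)
  im <- data.frame(time = 1.0, pixel_diff = 1)
  got <- synchronize_features(ef, im)
  expect_equal(got$epoch_end_time, 1.0) # exact coincidence: epoch 128
  im <- data.frame(time = c(0.5, 1.0), pixel_diff = c(1, 2))
  expect_message(got <- synchronize_features(ef, im), "dropped 1")
  expect_equal(nrow(got), 1L)
  # brute-force nearest-neighbour oracle over a 30 fps stream
  ef <- make_eeg_table(1280)
  ft <- 1 / 30 * (1:300)
  im <- data.frame(time = ft, pixel_diff = seq_along(ft))
  got <- suppressMessages(synchronize_features(ef, im))
  keep <- ft >= min(ef$end_time)
  expect_equal(nrow(got), sum(keep))
  oracle_idx <- vapply(ft[keep], function(t) {
    d <- abs(ef$end_time - t)
    which(d == min(d))[1] # tie -> earlier epoch
  }, integer(1))
  expect_equal(got$epoch_end_time, ef$end_time[oracle_idx])
  expect_error(synchronize_features(ef, data.frame(time = 1e5, pixel_diff = 1)),
               "overlap")
})

test_that("the leading Fisher direction matches the two-class closed form", {
  set.seed(5)
  x <- rbind(matrix(rnorm(200 * 2), ncol = 2),
             sweep(matrix(rnorm(200 * 2), ncol = 2), 2, c(4, 0), "+"))
  y <- rep(1:2, each = 200)
  proj <- fit_lda(x, y)
  u <- proj$vectors[, 1]
  expect_gte(abs(u[1]) / sqrt(sum(u^2)), 0.999) # collinear with (1, 0)
  # closed form u propto MW^-1 (m1 - m2)
  closed <- solve(proj$scatter_within,
                  proj$class_means[1, ] - proj$class_means[2, ])
  cosine <- abs(sum(u * closed)) / sqrt(sum(u^2) * sum(closed^2))
  expect_gte(cosine, 0.999)
  # the solution beats 200 random unit directions on the Fisher ratio
  set.seed(6)
  best_rand <- max(vapply(1:200, function(i) {
    v <- rnorm(2)
    fisher_ratio(proj, v / sqrt(sum(v^2)))
  }, numeric(1)))
  expect_gte(fisher_ratio(proj, u), best_rand)
  # and any single original feature axis
  expect_gte(fisher_ratio(proj, u),
             max(fisher_ratio(proj, c(1, 0)), fisher_ratio(proj, c(0, 1))))
})

test_that("identical class means give a null between-class scatter", {
  set.seed(8)
  x <- matrix(rnorm(800), ncol = 2)
  x[201:400, ] <- x[1:200, ] # identical clouds, identical means
  proj <- fit_lda(x, rep(1:2, each = 200))
  expect_lt(abs(proj$eigenvalues[1]), 1e-10)
  expect_error(fit_lda(x[c(1, 201:210), ], c(1, rep(2, 10))), "at least 2")
  expect_error(fit_lda(x[1:10, ], rep(1, 10)), "both classes")
})

test_that("empirical dimension selection discards pure-noise directions", {
  set.seed(12)
  n <- 300
  x <- cbind(rep(c(-2, 2), each = n / 2) + rnorm(n, sd = 0.5),
             matrix(rnorm(n * 5), ncol = 5))
  y <- rep(1:2, each = n / 2)
  k <- select_lda_dim(x, y, seed = 3)
  expect_equal(as.integer(k), 1L)
  expect_error(select_lda_dim(x, y, ks = integer(0)), "empty")
  # all candidates tie -> smallest k
  xsep <- cbind(rep(c(-9, 9), each = n / 2) + rnorm(n, sd = 0.1),
                matrix(rnorm(n * 3), ncol = 3))
  k2 <- select_lda_dim(xsep, y, ks = c(3, 1, 2), seed = 3)
  expect_equal(as.integer(k2), 1L)
  expect_equal(attr(k2, "errors"), attr(select_lda_dim(xsep, y, ks = c(3, 1, 2),
                                                       seed = 3), "errors"))
})

test_that("the SVM grid separates the separable and needs a kernel for XOR", {
  set.seed(20)
  x <- rbind(matrix(rnorm(100, sd = 0.3), ncol = 2),
             sweep(matrix(rnorm(100, sd = 0.3), ncol = 2), 2, c(3, 3), "+"))
  y <- rep(1:2, each = 50)
  m <- train_svm(x, y, grid = data.frame(kernel = "linear", r = NA, c = NA,
                                         d = NA, cost = 1))
  expect_equal(error_rates(ifelse(decision_values(m, x) > 0, 2, 1), y)$average, 0)
  # XOR pattern
  set.seed(21)
  ctr <- rbind(c(0, 0), c(3, 3), c(0, 3), c(3, 0))
  xx <- do.call(rbind, lapply(1:4, function(i)
    sweep(matrix(rnorm(120, sd = 0.35), ncol = 2), 2, ctr[i, ], "+")))
  yy <- rep(c(1, 1, 2, 2), each = 60)
  lin <- train_svm(xx, yy, grid = data.frame(kernel = "linear", r = NA, c = NA,
                                             d = NA, cost = c(1, 10)))
  rbf <- train_svm(xx, yy, grid = data.frame(kernel = "radial", r = 2, c = NA,
                                             d = NA, cost = 10))
  err <- function(m) error_rates(ifelse(decision_values(m, xx) > 0, 2, 1), yy)$average
  expect_gte(err(lin), 25)
  expect_equal(err(rbf), 0)
  expect_error(train_svm(xx[yy == 1, ], yy[yy == 1]), "both classes")
})

test_that("package decision values reproduce the libsvm kernel expansion", {
  set.seed(30)
  x <- rbind(matrix(rnorm(120), ncol = 3),
             sweep(matrix(rnorm(120), ncol = 3), 2, c(1.5, -1, 0.5), "+"))
  y <- rep(1:2, each = 40)
  for (g in list(data.frame(kernel = "radial", r = 0.5, c = NA, d = NA, cost = 1),
                 data.frame(kernel = "polynomial", r = 1, c = 1, d = 2, cost = 1),
                 data.frame(kernel = "sigmoid", r = 0.05, c = 0, d = NA, cost = 1),
                 data.frame(kernel = "linear", r = NA, c = NA, d = NA, cost = 1))) {
    m <- train_svm(x, y, grid = g)
    set.seed(31)
    xt <- matrix(rnorm(60), ncol = 3)
    mine <- decision_values(m, xt)
    p <- predict(m$libsvm_fit, xt, decision.values = TRUE)
    ref <- attr(p, "decision.values")[, 1]
    expect_equal(abs(mine), abs(ref), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(ifelse(mine > 0, 2L, 1L),
                 as.integer(as.character(p)))
  }
})

test_that("threshold tuning equals the exhaustive sweep and ties resolve toward zero", {
  # perfectly separated scores
  th <- select_threshold(c(-3, -2, -1, 1, 2, 3), c(1, 1, 1, 2, 2, 2))
  expect_equal(attr(th, "avg_error"), 0)
  expect_gt(th, -1); expect_lt(th, 1)
  # identical score multisets: 50% error, tie toward zero
  th <- select_threshold(c(1, 2, 1, 2), c(1, 1, 2, 2))
  expect_equal(attr(th, "avg_error"), 50)
  expect_equal(as.numeric(th), 1.5)
  for (seed in 1:20) {
    set.seed(seed)
    sc <- round(rnorm(40), 1) # rounding forces ties
    y <- sample(1:2, 40, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(y)) < 2) next
    th <- select_threshold(sc, y)
    expect_equal(attr(th, "avg_error"), oracle_min_avg_error(sc, y))
  }
})

test_that("classification is strict at the threshold and Class 1 on ties", {
  # identity decision model: f(x) = x
  m <- structure(list(kernel = "linear", r = NA, c = NA, d = NA, cost = 1,
                      SV = matrix(1), coefs = 1, rho = 0, flip = 1,
                      threshold = 0.5), class = "decision_model")
  expect_equal(decision_values(m, matrix(c(0.2, 0.5, 0.9))), c(0.2, 0.5, 0.9))
  expect_equal(classify_movement(m, matrix(c(0.2, 0.5, 0.50001, 0.9))),
               c(1L, 1L, 2L, 2L))
  m$threshold <- 10
  expect_true(all(classify_movement(m, matrix(rnorm(20))) == 1L))
})

test_that("error rates count per-class misclassifications in percent", {
  er <- error_rates(c(rep(1, 30)), c(rep(1, 10), rep(2, 20)))
  expect_equal(er$type2, 100)
  pred <- c(rep(2, 2), rep(1, 8), rep(1, 1), rep(2, 19))
  truth <- c(rep(1, 10), rep(2, 20))
  er <- error_rates(pred, truth)
  expect_equal(er$type1, 20)
  expect_equal(er$type2, 5)
  expect_equal(er$average, 12.5)
  expect_equal(error_rates(truth, truth)$average, 0)
  inv <- ifelse(truth == 1, 2, 1)
  expect_equal(error_rates(inv, truth)$average, 100)
  expect_error(error_rates(rep(1, 5), rep(1, 5)), "absent")
})

test_that("ROC area equals the pairwise-comparison estimator", {
  expect_equal(roc_curve(c(1, 2, 3, 11, 12, 13), rep(1:2, each = 3))$auc, 1)
  expect_equal(roc_curve(c(5, 6, 5, 6), c(1, 1, 2, 2))$auc, 0.5)
  for (seed in 1:15) {
    set.seed(seed)
    sc <- round(rnorm(10), 1)
    y <- c(rep(1, 5), rep(2, 5))
    rc <- roc_curve(sc, y)
    expect_equal(rc$auc, oracle_auc(sc, y))
    expect_true(!is.unsorted(rc$points$fpr))
    expect_true(!is.unsorted(rc$points$tpr))
  }
  expect_error(roc_curve(rnorm(5), rep(1, 5)), "both classes")
})

test_that("rejection bookkeeping merges label runs into half-open sections", {
  st <- eeg_stream(rnorm(640), rate = 128, t0 = 0) # 5 s
  # all still: one retained segment spanning the stream
  times <- (0:149) / 30
  r <- reject_sections(rep(1L, 150), times, st)
  expect_equal(nrow(r$sections), 1L)
  expect_equal(length(r$retained), 1L)
  expect_equal(length(r$retained[[1]]$samples), 640L)
  expect_equal(r$n_rejected_samples, 0L)
  # all moving: nothing retained
  r <- reject_sections(rep(2L, 150), times, st)
  expect_equal(length(r$retained), 0L)
  expect_equal(r$n_rejected_samples, 640L)
  # the mixed pattern 1,1,2,2,1
  r <- reject_sections(c(1, 1, 2, 2, 1), (0:4) / 30, st)
  expect_equal(r$sections$start_s, c(0, 2 / 30, 4 / 30))
  expect_equal(r$sections$end_s, c(2 / 30, 4 / 30, 5 / 30))
  expect_equal(r$sections$label, c(1, 2, 1))
  expect_equal(length(r$retained), 2L)
})

test_that("two-fold cross-validation is symmetric, trial-pure and reproducible", {
  feats <- tiny_session_feats()
  cfg <- pipeline_config(grid = data.frame(kernel = c("linear", "radial"),
                                           r = c(NA, 2), c = NA, d = NA,
                                           cost = 1),
                         grid_stride = 4L, fit_stride = 2L)
  cv1 <- twofold_cv(feats, cfg)
  # swapping fold order leaves the averaged report unchanged
  sw <- feats
  sw$fold <- ifelse(feats$fold == 1, 2, 1)
  cv2 <- twofold_cv(sw, cfg)
  expect_equal(cv1$averaged, cv2$averaged)
  # bitwise reproducibility
  cv3 <- twofold_cv(feats, cfg)
  expect_identical(cv1$averaged, cv3$averaged)
  expect_equal(cv1$averaged$average,
               (cv1$averaged$type1 + cv1$averaged$type2) / 2)
  # a trial straddling folds is refused
  bad <- feats
  bad$fold[which(bad$trial_id == bad$trial_id[1])[1:5]] <- 2
  expect_error(twofold_cv(bad, cfg), "straddles")
  # a fold missing a class is refused
  bad2 <- feats[!(feats$fold == 1 & feats$label == 2), ]
  expect_error(twofold_cv(bad2, cfg), "missing a class")
})
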