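# End-to-end pipeline: feature-set selection, standardization, LDA + SVM
# training, prediction, and the synthetic benchmark.

#' Resolve a feature-set name to its feature columns
#'
#' The six studied combinations are `freq`, `time`, `freq+time`,
#' `image+time`, `image+freq` and `image+time+freq`; `image` alone is also
#' accepted so single-modality comparisons can be run. Token order in the
#' name is free (`"freq+image"` equals `"image+freq"`).
#'
#' @param feature_set feature-set name.
#' @param bands band table, see [default_bands()].
#' @return character vector of feature column names.
#' @export
feature_set_columns <- function(feature_set, bands = default_bands()) {
  toks <- sort(unique(strsplit(feature_set, "+", fixed = TRUE)[[1]]))
  bad <- setdiff(toks, c("freq", "time", "image"))
  if (length(bad) || length(toks) == 0)
    stop("unknown feature set: ", feature_set)
  unlist(lapply(c("image", "freq", "time"), function(t) {
    if (!t %in% toks) return(character(0))
    switch(t, image = image_feature_names(), freq = bands$name,
           time = time_feature_names())
  }), use.names = FALSE)
}

#' Pipeline configuration
#'
#' Collects every knob of the detection pipeline. `grid_stride` and
#' `fit_stride` subsample the training fold (every n-th synchronized
#' vector) for, respectively, the kernel grid search and the final SVM
#' refit: consecutive vectors 1/30 s apart are highly redundant and libsvm
#' training is super-linear in sample count, while prediction and error
#' accounting always use every vector.
#'
#' @param feature_set see [feature_set_columns()].
#' @param classifier `"lda_svm"` (the full method), `"lda_only"`
#'   (projection + nearest class mean), or `"svm_only"` (SVM on the
#'   standardized features without projection).
#' @param window,step epoch length and hop, samples.
#' @param bands spectral band table.
#' @param video a [video_params()] list.
#' @param ks candidate LDA dimension counts (NULL = `1:min(d, 8)`).
#' @param grid SVM candidate table, see [default_kernel_grid()].
#' @param inner_frac inner train fraction for model selection.
#' @param seed RNG seed for the seed-fixed inner splits.
#' @param grid_stride,fit_stride training-fold subsampling strides.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(feature_set = "image+freq",
                            classifier = c("lda_svm", "lda_only", "svm_only"),
                            window = 128, step = 1, bands = default_bands(),
                            video = video_params(), ks = NULL,
                            grid = default_kernel_grid(), inner_frac = 0.7,
                            seed = 1L, grid_stride = 16L, fit_stride = 8L) {
  classifier <- match.arg(classifier)
  feature_set_columns(feature_set, bands) # validates
  structure(list(feature_set = feature_set, classifier = classifier,
                 window = window, step = step, bands = bands, video = video,
                 ks = ks, grid = grid, inner_frac = inner_frac,
                 seed = as.integer(seed), grid_stride = as.integer(grid_stride),
                 fit_stride = as.integer(fit_stride)),
            class = "pipeline_config")
}

clean_feature_rows <- function(features, cols) {
  x <- as.matrix(features[, cols, drop = FALSE])
  ok <- stats::complete.cases(x)
  if ("valid" %in% names(features)) ok <- ok & features$valid
  list(x = x[ok, , drop = FALSE], keep = ok)
}

fit_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1 # constant feature: centre only
  list(center = ctr, scale = scl)
}

apply_scaler <- function(scaler, x) {
  sweep(sweep(x, 2, scaler$center), 2, scaler$scale, "/")
}

#' Train the detection pipeline on a labeled training fold
#'
#' Standardizes the configured feature columns (z-score with training-fold
#' statistics), selects the LDA dimension count on a seed-fixed inner
#' split, fits the Fisher projection, runs the SVM kernel grid, refits the
#' winner, and tunes the decision threshold on the held-out inner part.
#'
#' @param features labeled synchronized feature data.frame (needs `label`
#'   plus the configured feature columns; rows with `valid == FALSE` or
#'   missing features are excluded from training).
#' @param config a [pipeline_config()].
#' @return a `pipeline_fit` with elements `config`, `cols`, `scaler`,
#'   `proj`, `k`, `model` (NULL for `lda_only`).
#' @export
train_pipeline <- function(features, config = pipeline_config()) {
  cols <- feature_set_columns(config$feature_set, config$bands)
  cl <- clean_feature_rows(features, cols)
  x <- cl$x
  y <- as.integer(features$label[cl$keep])
  scaler <- fit_scaler(x)
  xs <- apply_scaler(scaler, x)
  proj <- NULL
  k <- NA_integer_
  if (config$classifier %in% c("lda_svm", "lda_only")) {
    k <- select_lda_dim(xs, y, ks = config$ks, inner_frac = config$inner_frac,
                        seed = config$seed)
    proj <- fit_lda(xs, y)
    proj$k <- as.integer(k)
    z <- project_lda(proj, xs)
  } else {
    z <- xs
  }
  model <- NULL
  if (config$classifier %in% c("lda_svm", "svm_only")) {
    gi <- seq(1, nrow(z), by = config$grid_stride)
    sel <- train_svm(z[gi, , drop = FALSE], y[gi], grid = config$grid,
                     inner_frac = config$inner_frac, seed = config$seed)
    fi <- seq(1, nrow(z), by = config$fit_stride)
    model <- fit_svm_candidate(z[fi, , drop = FALSE], y[fi], sel$kernel,
                               sel$r, sel$c, sel$d, sel$cost)
    model$selection <- sel$selection
    tune <- stratified_split(y, config$inner_frac, config$seed)$test
    th <- select_threshold(decision_values(model, z[tune, , drop = FALSE]),
                           y[tune])
    model$threshold <- as.numeric(th)
  }
  structure(list(config = config, cols = cols, scaler = scaler, proj = proj,
                 k = k, model = model),
            class = "pipeline_fit")
}

#' Predict with a trained pipeline
#'
#' @param fit a `pipeline_fit` from [train_pipeline()].
#' @param features feature data.frame with the fit's feature columns
#'   (feature-name mismatch is an error). Rows flagged `valid == FALSE` or
#'   with missing features are conservatively labeled Class 2 (rejected)
#'   and excluded from `scores`/`truth`.
#' @return list: `labels` (all rows), `scores` and `truth` (clean rows,
#'   truth NULL when unlabeled), `keep` (logical clean-row mask).
#' @export
predict_pipeline <- function(fit, features) {
  if (!all(fit$cols %in% names(features)))
    stop("predict_pipeline: feature columns missing: ",
         paste(setdiff(fit$cols, names(features)), collapse = ", "))
  cl <- clean_feature_rows(features, fit$cols)
  xs <- apply_scaler(fit$scaler, cl$x)
  z <- if (!is.null(fit$proj)) project_lda(fit$proj, xs) else xs
  if (!is.null(fit$model)) {
    scores <- decision_values(fit$model, z)
    pred <- ifelse(scores > fit$model$threshold, 2L, 1L)
  } else {
    cm <- fit$proj$class_means %*% fit$proj$vectors[, seq_len(fit$proj$k), drop = FALSE]
    d1 <- rowSums(sweep(z, 2, cm[1, ])^2)
    d2 <- rowSums(sweep(z, 2, cm[2, ])^2)
    scores <- d1 - d2 # larger when nearer the Class-2 mean
    pred <- ifelse(scores > 0, 2L, 1L)
  }
  labels <- rep(2L, nrow(features)) # invalid epochs are not trusted
  labels[cl$keep] <- pred
  truth <- if ("label" %in% names(features))
    as.integer(features$label[cl$keep]) else NULL
  list(labels = labels, scores = scores, truth = truth, keep = cl$keep)
}

#' Synchronized feature table for one paired recording
#'
#' Extracts video features for every frame pair and EEG features for the
#' epochs completing nearest those instants (equivalent to pairing against
#' the full 1-sample-hop epoch stream, at a fraction of the cost), then
#' synchronizes the two.
#'
#' @param stream an [eeg_stream()].
#' @param frames a [frame_sequence()].
#' @param config a [pipeline_config()].
#' @return synchronized feature data.frame, see [synchronize_features()].
#' @export
trial_feature_table <- function(stream, frames, config = pipeline_config()) {
  vf <- video_feature_table(frames, config$video)
  n <- length(stream$samples)
  idx <- sort(unique(pmin(pmax(
    round((vf$time - stream$t0) * stream$rate), config$window), n)))
  ef <- eeg_feature_table(stream, window = config$window,
                          bands = config$bands, end_index = idx)
  suppressMessages(synchronize_features(ef, vf))
}

#' Detect and excise movement sections from a recording
#'
#' Runs the full detection path on one paired recording: EEG epoch features,
#' video features, synchronization, classification with a trained pipeline,
#' and section-level rejection.
#'
#' @param fit a `pipeline_fit`.
#' @param stream an [eeg_stream()].
#' @param frames a [frame_sequence()].
#' @return list as [reject_sections()], plus `features` and `labels`.
#' @export
detect_movement <- function(fit, stream, frames) {
  sync <- trial_feature_table(stream, frames, fit$config)
  pr <- predict_pipeline(fit, sync)
  out <- reject_sections(pr$labels, sync$time, stream)
  out$features <- sync
  out$labels <- pr$labels
  out
}
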