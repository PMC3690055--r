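# Readers and writers: EEG CSV, PNG frame directories, feature CSV,
# section TSV, and the versioned JSON model container.

#' Read an EEG stream from CSV
#'
#' Accepts either the channel-averaged schema (`timestamp_s,value`) or the
#' 14-electrode schema (`timestamp_s,ch1..ch14`), which is averaged across
#' electrodes on load. Timestamps must be strictly increasing and uniform
#' within 1% of the declared rate.
#'
#' @param path CSV file path.
#' @param rate declared sampling rate, S/s.
#' @param trial_id,label passed to [eeg_stream()].
#' @return an [eeg_stream()].
#' @export
read_eeg_csv <- function(path, rate = 128, trial_id = NA_character_,
                         label = NA_integer_) {
  if (!file.exists(path)) stop("read_eeg_csv: no such file: ", path)
  d <- read.csv(path, check.names = FALSE)
  if (!"timestamp_s" %in% names(d))
    stop("read_eeg_csv: missing timestamp_s column")
  vals <- if (ncol(d) == 2 && "value" %in% names(d)) {
    d$value
  } else if (ncol(d) == 15 && all(sprintf("ch%d", 1:14) %in% names(d))) {
    rowMeans(d[, sprintf("ch%d", 1:14)])
  } else {
    stop("read_eeg_csv: expected columns timestamp_s,value or timestamp_s,ch1..ch14 (got ",
         ncol(d), " columns)")
  }
  if (anyNA(vals) || anyNA(d$timestamp_s)) {
    stop("read_eeg_csv: NA sample at row ",
         which(is.na(vals) | is.na(d$timestamp_s))[1])
  }
  dt <- diff(d$timestamp_s)
  if (any(dt <= 0))
    stop("read_eeg_csv: non-increasing timestamp at row ", which(dt <= 0)[1] + 1)
  if (any(abs(dt - 1 / rate) > 0.01 / rate))
    stop("read_eeg_csv: sampling not uniform at the declared rate (row ",
         which(abs(dt - 1 / rate) > 0.01 / rate)[1] + 1, ")")
  eeg_stream(vals, rate = rate, t0 = d$timestamp_s[1], trial_id = trial_id,
             label = label)
}

#' Write an EEG stream to CSV
#' @param stream an [eeg_stream()].
#' @param path output file.
#' @export
write_eeg_csv <- function(stream, path) {
  stopifnot(inherits(stream, "eeg_stream"))
  t <- stream$t0 + (seq_along(stream$samples) - 1) / stream$rate
  write.csv(data.frame(timestamp_s = t, value = stream$samples), path,
            row.names = FALSE)
  invisible(path)
}

#' Read a frame sequence from a directory of PNG images
#'
#' Frames are ordered by file name and timestamped `t0 + i / rate`. Color
#' images are converted to grayscale with ITU-R 601 luma weights
#' (0.299 R + 0.587 G + 0.114 B). Video container files are not supported;
#' extract frames to PNG first.
#'
#' @param path directory containing the PNG frames.
#' @param rate frames per second.
#' @param t0 timestamp of the first frame.
#' @return a [frame_sequence()].
#' @export
read_frames <- function(path, rate = 30, t0 = 0) {
  if (!dir.exists(path)) {
    if (file.exists(path))
      stop("read_frames: video container input is not supported; ",
           "provide a directory of PNG frames")
    stop("read_frames: no such directory: ", path)
  }
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("read_frames: no PNG frames in ", path)
  frames <- lapply(files, function(f) {
    im <- png::readPNG(f)
    if (length(dim(im)) == 3) {
      ch <- dim(im)[3]
      im <- if (ch >= 3) {
        0.299 * im[, , 1] + 0.587 * im[, , 2] + 0.114 * im[, , 3]
      } else im[, , 1]
    }
    round(im * 255)
  })
  frame_sequence(frames, rate = rate, t0 = t0)
}

#' Write a frame sequence as numbered PNG files
#' @param x a [frame_sequence()].
#' @param path output directory (created if missing).
#' @export
write_frames <- function(x, path) {
  stopifnot(inherits(x, "frame_sequence"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n <- dim(x$frames)[3]
  for (i in seq_len(n)) {
    png::writePNG(x$frames[, , i] / 255,
                  file.path(path, sprintf("frame_%06d.png", i)))
  }
  invisible(path)
}

#' Write / read a synchronized feature table as CSV
#' @param features feature data.frame.
#' @param path file path.
#' @export
write_features_csv <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  if (!file.exists(path)) stop("read_features_csv: no such file: ", path)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a section table as TSV
#'
#' Three tab-separated columns `start_s`, `end_s`, `label` with half-open
#' `[start_s, end_s)` intervals, one row per merged section, for
#' consumption by downstream EEG tooling.
#'
#' @param sections data.frame as returned in `reject_sections()$sections`.
#' @param path file path.
#' @export
write_sections_tsv <- function(sections, path) {
  utils::write.table(sections[, c("start_s", "end_s", "label")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

MODEL_FORMAT_VERSION <- "movart-model-1"

#' Save / load a trained pipeline
#'
#' Serializes a `pipeline_fit` to a versioned JSON container holding the
#' feature-name order, standardization statistics, LDA projection, SVM
#' kernel spec, support set, weights, bias, sign orientation and decision
#' threshold. A loaded model predicts through the package's own kernel-sum
#' decision function; loading a file whose feature names do not match its
#' recorded feature set is a hard error, as is an unknown format version.
#'
#' @param fit a `pipeline_fit` from [train_pipeline()].
#' @param path JSON file path.
#' @export
save_model <- function(fit, path) {
  stopifnot(inherits(fit, "pipeline_fit"))
  obj <- list(
    format = MODEL_FORMAT_VERSION,
    feature_set = fit$config$feature_set,
    classifier = fit$config$classifier,
    cols = fit$cols,
    scaler = fit$scaler,
    k = fit$k,
    proj = if (is.null(fit$proj)) NULL else list(
      vectors = fit$proj$vectors, eigenvalues = fit$proj$eigenvalues,
      class_means = fit$proj$class_means, global_mean = fit$proj$global_mean,
      priors = fit$proj$priors, classes = fit$proj$classes,
      scatter_within = fit$proj$scatter_within,
      scatter_between = fit$proj$scatter_between),
    model = if (is.null(fit$model)) NULL else list(
      kernel = fit$model$kernel, r = fit$model$r, c = fit$model$c,
      d = fit$model$d, cost = fit$model$cost, SV = fit$model$SV,
      coefs = fit$model$coefs, rho = fit$model$rho, flip = fit$model$flip,
      threshold = fit$model$threshold),
    window = fit$config$window, step = fit$config$step,
    bands = fit$config$bands, video = unclass(fit$config$video))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname save_model
#' @return `load_model()` returns a `pipeline_fit`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("load_model: no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, MODEL_FORMAT_VERSION))
    stop("load_model: unknown model format: ", obj$format)
  cfg <- pipeline_config(feature_set = obj$feature_set,
                         classifier = obj$classifier,
                         window = obj$window, step = obj$step,
                         bands = obj$bands,
                         video = do.call(video_params, as.list(obj$video)))
  expected <- feature_set_columns(obj$feature_set, cfg$bands)
  if (!identical(unlist(obj$cols), expected))
    stop("load_model: feature-name mismatch between file and feature set")
  scaler <- list(center = setNames(unlist(obj$scaler$center), obj$cols),
                 scale = setNames(unlist(obj$scaler$scale), obj$cols))
  proj <- NULL
  if (!is.null(obj$proj)) {
    proj <- structure(list(
      vectors = as.matrix(obj$proj$vectors),
      eigenvalues = obj$proj$eigenvalues, k = as.integer(obj$k),
      class_means = as.matrix(obj$proj$class_means),
      global_mean = obj$proj$global_mean, priors = obj$proj$priors,
      classes = obj$proj$classes,
      scatter_within = as.matrix(obj$proj$scatter_within),
      scatter_between = as.matrix(obj$proj$scatter_between),
      feature_names = obj$cols), class = "lda_projection")
  }
  model <- NULL
  if (!is.null(obj$model)) {
    model <- structure(list(
      kernel = obj$model$kernel, r = obj$model$r, c = obj$model$c,
      d = obj$model$d, cost = obj$model$cost,
      SV = as.matrix(obj$model$SV), coefs = obj$model$coefs,
      rho = obj$model$rho, flip = obj$model$flip,
      threshold = obj$model$threshold), class = "decision_model")
  }
  structure(list(config = cfg, cols = expected, scaler = scaler, proj = proj,
                 k = as.integer(obj$k), model = model),
            class = "pipeline_fit")
}
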