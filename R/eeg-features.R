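#' Construct an EEG stream
#'
#' A single-channel EEG recording at a fixed sampling rate. Multi-electrode
#' recordings are expected to be channel-averaged before construction (the
#' CSV reader does this on load). Sample `i` carries timestamp
#' `t0 + (i - 1) / rate`; an epoch whose last sample has index `e` is
#' considered complete at `t0 + e / rate`, the instant its final sample has
#' been delivered.
#'
#' @param samples numeric vector of voltages (arbitrary units).
#' @param rate sampling rate in samples per second (default 128).
#' @param t0 timestamp of the first sample, seconds.
#' @param trial_id opaque trial identifier.
#' @param label optional trial class: 1 (no movement) or 2 (movement).
#' @return an object of class `eeg_stream`.
#' @export
eeg_stream <- function(samples, rate = 128, t0 = 0, trial_id = NA_character_,
                       label = NA_integer_) {
  stopifnot(is.numeric(samples), rate > 0)
  if (anyNA(samples)) stop("eeg_stream: samples contain NA")
  if (!is.na(label) && !label %in% c(1L, 2L)) stop("eeg_stream: label must be 1 or 2")
  structure(list(samples = as.numeric(samples), rate = rate, t0 = t0,
                 trial_id = trial_id, label = as.integer(label)),
            class = "eeg_stream")
}

#' @export
print.eeg_stream <- function(x, ...) {
  cat(sprintf("<eeg_stream> %d samples @ %g S/s, t0 = %g s, trial = %s, class = %s\n",
              length(x$samples), x$rate, x$t0, x$trial_id,
              ifelse(is.na(x$label), "?", x$label)))
  invisible(x)
}

#' The 12 analysis frequency bands
#'
#' Inclusive integer-Hz band edges used for the spectral features. The low
#' group (3-15 Hz and six overlapping 2-Hz sub-bands) covers theta/alpha
#' rhythms that dominate when the head is still; 15-30 and 20-30 Hz capture
#' beta-range power boosted by movement; 51-64 and 59-61 Hz capture
#' muscle/line-frequency contamination.
#'
#' @return a data.frame with columns `name`, `low`, `high` (Hz).
#' @export
default_bands <- function() {
  lo <- c(3, 4, 5, 6, 7, 8, 9, 10, 15, 20, 51, 59)
  hi <- c(15, 6, 7, 8, 9, 10, 11, 12, 30, 30, 64, 61)
  data.frame(name = sprintf("f_%d_%d", lo, hi), low = lo, high = hi,
             stringsAsFactors = FALSE)
}

#' Names of the 13 time-domain features
#' @return character vector in canonical order.
#' @export
time_feature_names <- function() {
  c("kurtosis", "skewness", "rms_amplitude", "zero_crossings", "minimum",
    "maximum", "var_d1", "var_d2", "zc_d1", "zc_d2", "activity", "mobility",
    "complexity")
}

#' Names of the 4 frame-motion features
#' @return character vector in canonical order.
#' @export
image_feature_names <- function() {
  c("pixel_diff", "edge_diff", "mv_avg_mag", "mv_count")
}

#' Normalize one epoch
#'
#' Removes the DC level (subtracts the epoch mean) and then min-max scales
#' the centred values onto \[-1, 1\], so the output minimum is exactly -1 and
#' the maximum exactly +1.
#'
#' @param raw numeric vector (one epoch of consecutive samples).
#' @param end_index optional index of the epoch's last sample in its parent
#'   stream, used only to make the degenerate-input error message traceable.
#' @return numeric vector of the same length, in \[-1, 1\].
#' @export
normalize_epoch <- function(raw, end_index = NA_integer_) {
  stopifnot(is.numeric(raw), length(raw) >= 2)
  x <- raw - mean(raw)
  rng <- range(x)
  if (rng[2] <= rng[1]) {
    stop(sprintf("normalize_epoch: constant segment (epoch ending at index %s)",
                 end_index))
  }
  2 * (x - rng[1]) / (rng[2] - rng[1]) - 1
}

# Column-wise two-step normalization of an epoch matrix (window x m).
# Returns list(values = matrix, valid = logical); degenerate columns are
# flagged invalid and left as NA rather than dropped.
normalize_epoch_matrix <- function(m) {
  mu <- colMeans(m)
  m <- m - rep(mu, each = nrow(m))
  cmin <- apply(m, 2, min)
  cmax <- apply(m, 2, max)
  rngw <- cmax - cmin
  valid <- rngw > 0
  scale <- ifelse(valid, rngw, NA_real_)
  m <- 2 * (m - rep(cmin, each = nrow(m))) / rep(scale, each = nrow(m)) - 1
  list(values = m, valid = valid)
}

#' Cut a stream into sliding epochs
#'
#' Slides a `window`-sample window over the stream in steps of `step`
#' samples (default 1 sample, i.e. a 127-sample overlap for the default
#' window) and normalizes each epoch with [normalize_epoch()]. Epochs whose
#' normalization fails (constant segment) are emitted with `valid = FALSE`
#' rather than dropped, so epoch counts are conserved.
#'
#' @param stream an [eeg_stream()].
#' @param window epoch length in samples (default 128).
#' @param step hop between consecutive epochs in samples (default 1).
#' @return a list with elements `values` (window x n matrix of normalized
#'   epochs, one column each), `end_index`, `end_time`, `valid`.
#' @export
sliding_epochs <- function(stream, window = 128, step = 1) {
  stopifnot(inherits(stream, "eeg_stream"), window >= 2, step >= 1)
  n <- length(stream$samples)
  if (n < window) {
    warning(sprintf("sliding_epochs: stream of %d samples is shorter than the %d-sample window",
                    n, window))
    return(list(values = matrix(numeric(0), nrow = window, ncol = 0),
                end_index = integer(0), end_time = numeric(0), valid = logical(0)))
  }
  ends <- seq.int(window, n, by = step)
  epochs_at(stream, ends, window = window)
}

#' Epochs ending at given sample indices
#'
#' Same contract as [sliding_epochs()] but for an explicit set of epoch end
#' indices (each must be >= `window`). Used to extract only frame-aligned
#' epochs.
#'
#' @inheritParams sliding_epochs
#' @param end_index integer vector of end-sample indices.
#' @return see [sliding_epochs()].
#' @export
epochs_at <- function(stream, end_index, window = 128) {
  stopifnot(inherits(stream, "eeg_stream"))
  end_index <- as.integer(end_index)
  stopifnot(all(end_index >= window), all(end_index <= length(stream$samples)))
  idx <- outer(seq_len(window) - window, end_index, "+")
  m <- matrix(stream$samples[idx], nrow = window)
  nrm <- normalize_epoch_matrix(m)
  list(values = nrm$values, end_index = end_index,
       end_time = stream$t0 + end_index / stream$rate, valid = nrm$valid)
}

#' Frequency-band magnitude features of one epoch
#'
#' Discrete Fourier magnitudes of the (rectangular-windowed) epoch are
#' averaged over the integer-Hz bins of each band, inclusive of both edges.
#' With the default 128-sample window at 128 S/s the bin resolution is
#' exactly 1 Hz.
#'
#' @param values numeric epoch (normally the output of [normalize_epoch()]).
#' @param bands band table as from [default_bands()].
#' @param rate sampling rate in samples per second.
#' @return named numeric vector, one non-negative magnitude per band.
#' @export
frequency_features <- function(values, bands = default_bands(), rate = 128) {
  frequency_feature_matrix(matrix(values, ncol = 1), bands, rate)[1, ]
}

# band features for an epoch matrix (window x m) -> m x nbands
frequency_feature_matrix <- function(m, bands = default_bands(), rate = 128) {
  window <- nrow(m)
  if (any(bands$low >= bands$high) || any(bands$low < 0))
    stop("frequency_features: malformed band")
  if (any(bands$high > rate / 2))
    stop("frequency_features: band exceeds the Nyquist frequency")
  hz_per_bin <- rate / window
  mag <- Mod(stats::mvfft(m))
  out <- matrix(NA_real_, nrow = ncol(m), ncol = nrow(bands),
                dimnames = list(NULL, bands$name))
  for (b in seq_len(nrow(bands))) {
    bins <- seq.int(ceiling(bands$low[b] / hz_per_bin),
                    floor(bands$high[b] / hz_per_bin))
    rows <- bins + 1L
    out[, b] <- colMeans(mag[rows, , drop = FALSE])
  }
  out
}

#' Time-domain features of one epoch
#'
#' Computes the 13 statistics in [time_feature_names()] order. Conventions
#' (centralised here so one place switches them): all moments and variances
#' are population (biased, divide-by-n) moments; kurtosis is the raw
#' standardized fourth moment `m4 / m2^2` (normal approx. 3) and skewness
#' `m3 / m2^1.5`; the reported RMS amplitude is the peak absolute value
#' divided by sqrt(2) (the conventional root-mean-square is returned in the
#' `"rms_conventional"` attribute); zero crossings count strict sign changes
#' (adjacent-sample product < 0; exact zeros neither count nor interrupt);
#' derivatives are first differences; activity/mobility/complexity are the
#' Hjorth parameters.
#'
#' @param values numeric epoch of length >= 3.
#' @return named numeric vector of the 13 statistics, with attribute
#'   `rms_conventional`.
#' @export
time_features <- function(values) {
  stopifnot(length(values) >= 3)
  m <- matrix(values, ncol = 1)
  tf <- time_feature_matrix(m)
  if (!attr(tf, "valid")[1])
    stop("time_features: zero-variance epoch; skewness/kurtosis/mobility undefined")
  out <- tf[1, ]
  attr(out, "rms_conventional") <- attr(tf, "rms_conventional")[1]
  out
}

# 13 time features for an epoch matrix (window x m) -> m x 13 with
# attributes valid (per-column) and rms_conventional
time_feature_matrix <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  mc <- m - rep(mu, each = n)
  m2 <- colMeans(mc^2)
  m3 <- colMeans(mc^3)
  m4 <- colMeans(mc^4)
  valid <- m2 > 0
  kurtosis <- ifelse(valid, m4 / m2^2, NA_real_)
  skewness <- ifelse(valid, m3 / m2^1.5, NA_real_)
  absmax <- apply(abs(m), 2, max)
  rms_amplitude <- absmax / sqrt(2)
  rms_conventional <- sqrt(colMeans(m^2))
  zero_crossings <- colSums(m[-1, , drop = FALSE] * m[-n, , drop = FALSE] < 0)
  minimum <- apply(m, 2, min)
  maximum <- apply(m, 2, max)
  d1 <- m[-1, , drop = FALSE] - m[-n, , drop = FALSE]
  n1 <- nrow(d1)
  d2 <- d1[-1, , drop = FALSE] - d1[-n1, , drop = FALSE]
  n2 <- nrow(d2)
  pvar <- function(x) colMeans(x^2) - colMeans(x)^2
  var_d1 <- pvar(d1)
  var_d2 <- pvar(d2)
  zc_d1 <- colSums(d1[-1, , drop = FALSE] * d1[-n1, , drop = FALSE] < 0)
  zc_d2 <- colSums(d2[-1, , drop = FALSE] * d2[-n2, , drop = FALSE] < 0)
  activity <- m2
  mobility <- ifelse(valid, sqrt(var_d1 / m2), NA_real_)
  mob_d1 <- ifelse(var_d1 > 0, sqrt(var_d2 / var_d1), NA_real_)
  complexity <- ifelse(valid & var_d1 > 0, mob_d1 / mobility, NA_real_)
  out <- cbind(kurtosis, skewness, rms_amplitude, zero_crossings, minimum,
               maximum, var_d1, var_d2, zc_d1, zc_d2, activity, mobility,
               complexity)
  colnames(out) <- time_feature_names()
  attr(out, "valid") <- valid
  attr(out, "rms_conventional") <- rms_conventional
  out
}

#' Per-epoch feature table for a stream
#'
#' Runs normalization plus the frequency- and time-domain feature extractors
#' over every epoch position and returns one row per epoch. Degenerate
#' (constant) epochs are kept with `valid = FALSE` and NA features so that
#' downstream synchronization can flag rather than silently lose them.
#'
#' @inheritParams sliding_epochs
#' @param bands band table, see [default_bands()].
#' @param end_index optional explicit epoch end indices (overrides
#'   `window`/`step` sliding).
#' @return data.frame with `end_index`, `end_time`, `valid`, 12 band columns
#'   and 13 time-domain columns.
#' @export
eeg_feature_table <- function(stream, window = 128, step = 1,
                              bands = default_bands(), end_index = NULL) {
  ep <- if (is.null(end_index)) sliding_epochs(stream, window, step)
        else epochs_at(stream, end_index, window)
  if (ncol(ep$values) == 0) {
    return(data.frame(end_index = integer(0), end_time = numeric(0),
                      valid = logical(0)))
  }
  vals <- ep$values
  vals[, !ep$valid] <- 0 # placeholder; rows flagged invalid below
  fr <- frequency_feature_matrix(vals, bands, stream$rate)
  tf <- time_feature_matrix(vals)
  out <- data.frame(end_index = ep$end_index, end_time = ep$end_time,
                    valid = ep$valid)
  out <- cbind(out, as.data.frame(fr), as.data.frame(unclass(tf)))
  out[!ep$valid, c(bands$name, time_feature_names())] <- NA_real_
  rownames(out) <- NULL
  out
}
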