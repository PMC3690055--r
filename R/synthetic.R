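# Synthetic paired EEG + frontal-video sessions with trial-level ground
# truth, emulating the class-conditional structure of still vs yaw-movement
# recordings.

#' Session configuration for the synthetic generator
#'
#' Defaults describe one emulated recording session: `n_subjects` subjects,
#' each contributing two still (Class 1) and two movement (Class 2) trials
#' of `duration_s` seconds, EEG at 128 S/s and frontal video at 30 fps with
#' 160x120 px frames.
#'
#' Class structure: the EEG is a sum of sinusoids (random phases) over a
#' 1/f-noise floor; Class 2 scales components above 15 Hz by
#' `class2_spec$high_factor` and components at or below 12 Hz by
#' `class2_spec$low_factor`, reproducing the movement-related shift from
#' low- to high-frequency spectral content. Each subject carries a fixed
#' log-normal spectral tilt (sd `subject_sd`) on the low and high component
#' groups, emulating inter-person variability. Video frames crop a seeded
#' smoothed-noise texture: Class 1 undergoes sub-pixel stabilization jitter
#' only (`motion_spec$jitter_sd`, default 0.01 px so that the still-class
#' mean pixel difference stays below 2% of the movement-class mean), Class 2
#' additionally a sinusoidal horizontal pan (yaw surrogate) with peak speed
#' `motion_spec$pan_speed_px` px/frame at `motion_spec$pan_freq_hz`. The
#' pan's sinusoidal turning points produce near-static frames inside
#' movement trials, which is what keeps the image modality alone from being
#' a perfect classifier.
#'
#' @param duration_s trial length, seconds.
#' @param n_subjects number of synthetic subjects.
#' @param trials_per_class trials per class per subject.
#' @param eeg_rate EEG sampling rate, S/s.
#' @param frame_rate video frame rate, fps.
#' @param frame_size frame width x height, px.
#' @param class1_spec list: `components` (data.frame `freq`, `amp`),
#'   `pink_sd`, `white_sd`.
#' @param class2_spec list: `low_factor`, `high_factor`.
#' @param subject_sd sd of the per-subject log-normal spectral tilt.
#' @param motion_spec list: `pan_speed_px`, `pan_freq_hz`, `jitter_sd`.
#' @param seed master seed; fixed seed gives bit-identical sessions.
#' @return a list of class `session_config`.
#' @export
session_config <- function(duration_s = 47, n_subjects = 10,
                           trials_per_class = 2, eeg_rate = 128,
                           frame_rate = 30, frame_size = c(160, 120),
                           class1_spec = list(
                             components = data.frame(
                               freq = c(4, 6, 8, 10, 12, 18, 22, 26, 55, 60),
                               amp = c(0.5, 1.0, 0.9, 0.7, 0.4,
                                       0.12, 0.12, 0.10, 0.06, 0.08)),
                             pink_sd = 0.35, white_sd = 0.12),
                           class2_spec = list(low_factor = 0.5,
                                              high_factor = 4),
                           subject_sd = 0.25,
                           motion_spec = list(pan_speed_px = 4,
                                              pan_freq_hz = 0.25,
                                              jitter_sd = 0.01),
                           seed = 0L) {
  stopifnot(eeg_rate > 0, frame_rate > 0, duration_s * eeg_rate >= 128,
            length(frame_size) == 2)
  structure(list(duration_s = duration_s, n_subjects = n_subjects,
                 trials_per_class = trials_per_class, eeg_rate = eeg_rate,
                 frame_rate = frame_rate, frame_size = frame_size,
                 class1_spec = class1_spec, class2_spec = class2_spec,
                 subject_sd = subject_sd, motion_spec = motion_spec,
                 seed = as.integer(seed)),
            class = "session_config")
}

# 1/f-shaped noise via spectral shaping of white noise, unit sd
pink_noise <- function(n, rate) {
  w <- rnorm(n)
  f <- c(0, seq_len(n - 1)) * rate / n
  f <- pmin(f, rate - f) # two-sided frequency axis
  shape <- 1 / sqrt(pmax(f, 1))
  shape[1] <- 0
  x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
  x / sd(x)
}

#' Generate one synthetic EEG trial
#'
#' @param config a [session_config()].
#' @param class trial class: 1 (still) or 2 (movement).
#' @param seed trial seed.
#' @param gains per-subject spectral tilt, `c(low = , high = )`.
#' @param trial_id,t0 passed through to the stream.
#' @return an [eeg_stream()] of `duration_s * eeg_rate` samples.
#' @export
generate_eeg <- function(config, class, seed, gains = c(low = 1, high = 1),
                         trial_id = NA_character_, t0 = 0) {
  stopifnot(class %in% c(1, 2))
  n <- round(config$duration_s * config$eeg_rate)
  comps <- config$class1_spec$components
  amp <- comps$amp
  if (class == 2) {
    amp[comps$freq <= 12] <- amp[comps$freq <= 12] * config$class2_spec$low_factor
    amp[comps$freq > 15] <- amp[comps$freq > 15] * config$class2_spec$high_factor
  }
  amp[comps$freq <= 12] <- amp[comps$freq <= 12] * gains["low"]
  amp[comps$freq > 15] <- amp[comps$freq > 15] * gains["high"]
  x <- with_seed(seed, {
    tt <- (seq_len(n) - 1) / config$eeg_rate
    ph <- runif(nrow(comps), 0, 2 * pi)
    sig <- rowSums(vapply(seq_len(nrow(comps)), function(i)
      amp[i] * sin(2 * pi * comps$freq[i] * tt + ph[i]), numeric(n)))
    sig + config$class1_spec$pink_sd * pink_noise(n, config$eeg_rate) +
      config$class1_spec$white_sd * rnorm(n)
  })
  eeg_stream(x, rate = config$eeg_rate, t0 = t0, trial_id = trial_id,
             label = as.integer(class))
}

# separable smoothing with a 5-tap binomial kernel, replicate border
smooth5 <- function(m) {
  k <- c(1, 4, 6, 4, 1) / 16
  pad_idx <- function(n) pmin(pmax(seq(-1, n + 2), 1), n)
  one_pass <- function(m) { # along rows
    acc <- 0
    ri <- pad_idx(nrow(m))
    for (j in 1:5) acc <- acc + k[j] * m[ri[seq_len(nrow(m)) + j - 1], , drop = FALSE]
    acc
  }
  t(one_pass(t(one_pass(m))))
}

#' Generate one synthetic frontal-video trial
#'
#' Renders `round(duration_s * frame_rate)` frames by cropping a seeded
#' smoothed-noise texture (rich in trackable corners) at per-frame
#' sub-pixel offsets; see [session_config()] for the motion model.
#'
#' @inheritParams generate_eeg
#' @return a [frame_sequence()] with attributes `offsets_x`, `offsets_y`
#'   (true per-frame crop positions, px) carried in `$truth`.
#' @export
generate_frames <- function(config, class, seed, t0 = 0) {
  stopifnot(class %in% c(1, 2))
  w <- config$frame_size[1]
  h <- config$frame_size[2]
  nf <- round(config$duration_s * config$frame_rate)
  ms <- config$motion_spec
  amp_px <- ms$pan_speed_px * config$frame_rate / (2 * pi * ms$pan_freq_hz)
  mx <- ceiling(amp_px) + 6
  my <- 6
  if (mx > 4 * w)
    stop(sprintf(paste("generate_frames: pan amplitude %.0f px exceeds the",
                       "texture margin supported for a %d px frame"),
                 amp_px, w))
  res <- with_seed(seed, {
    tex <- matrix(runif((h + 2 * my) * (w + 2 * mx)), h + 2 * my)
    tex <- smooth5(tex)
    tex <- (tex - min(tex)) / (max(tex) - min(tex)) * 235 + 10
    tt <- (seq_len(nf) - 1) / config$frame_rate
    jx <- rnorm(nf, 0, ms$jitter_sd)
    jy <- rnorm(nf, 0, ms$jitter_sd)
    pan <- if (class == 2) {
      phase <- runif(1, 0, 2 * pi)
      amp_px * sin(2 * pi * ms$pan_freq_hz * tt + phase)
    } else rep(0, nf)
    list(tex = tex, ox = pan + jx, oy = jy)
  })
  if (max(abs(res$ox)) > mx - 2 || max(abs(res$oy)) > my - 2)
    stop("generate_frames: pan/jitter amplitude exceeds the texture margin")
  arr <- .cpp_render_pan(res$tex, mx + res$ox, my + res$oy, w, h)
  fs <- frame_sequence(arr, rate = config$frame_rate, t0 = t0)
  fs$truth <- data.frame(time = t0 + (seq_len(nf) - 1) / config$frame_rate,
                         offset_x = res$ox, offset_y = res$oy)
  fs
}

#' Generate a full labeled session
#'
#' For each subject, `trials_per_class` paired EEG + video trials per class
#' with aligned `t0 = 0` per trial. EEG streams are generated eagerly
#' (they are small); frames are rendered on demand with [trial_frames()]
#' from the per-trial seeds recorded in the manifest, so a 40-trial session
#' does not hold ~4 GB of pixels.
#'
#' @param config a [session_config()].
#' @return list of class `session`: `config`, `manifest` (data.frame with
#'   `trial_id`, `subject`, `class`, `rep`, `fold`, `seed_eeg`,
#'   `seed_frames`, `gain_low`, `gain_high`), `eeg` (list of streams named
#'   by trial id).
#' @export
generate_session <- function(config = session_config()) {
  n_tr <- config$n_subjects * 2 * config$trials_per_class
  draws <- with_seed(config$seed, {
    list(gl = exp(rnorm(config$n_subjects, 0, config$subject_sd)),
         gh = exp(rnorm(config$n_subjects, 0, config$subject_sd)),
         seeds = sample.int(.Machine$integer.max - 1L, 2 * n_tr))
  })
  rows <- expand.grid(rep = seq_len(config$trials_per_class), class = 1:2,
                      subject = seq_len(config$n_subjects))
  manifest <- data.frame(
    trial_id = sprintf("s%02d_c%d_r%d", rows$subject, rows$class, rows$rep),
    subject = rows$subject, class = rows$class, rep = rows$rep,
    fold = rows$rep, # first vs second trials
    seed_eeg = draws$seeds[seq_len(n_tr)],
    seed_frames = draws$seeds[n_tr + seq_len(n_tr)],
    gain_low = draws$gl[rows$subject], gain_high = draws$gh[rows$subject],
    stringsAsFactors = FALSE)
  eeg <- lapply(seq_len(n_tr), function(i) {
    generate_eeg(config, manifest$class[i], manifest$seed_eeg[i],
                 gains = c(low = manifest$gain_low[i],
                           high = manifest$gain_high[i]),
                 trial_id = manifest$trial_id[i])
  })
  names(eeg) <- manifest$trial_id
  structure(list(config = config, manifest = manifest, eeg = eeg),
            class = "session")
}

#' Render the frames of one session trial
#'
#' @param session a [generate_session()] result.
#' @param trial_id trial identifier from the manifest.
#' @return a [frame_sequence()].
#' @export
trial_frames <- function(session, trial_id) {
  i <- match(trial_id, session$manifest$trial_id)
  if (is.na(i)) stop("unknown trial: ", trial_id)
  generate_frames(session$config, session$manifest$class[i],
                  session$manifest$seed_frames[i])
}

#' Extract synchronized labeled features for every trial of a session
#'
#' Runs the EEG and video feature extractors over each trial (rendering and
#' discarding frames one trial at a time) and synchronizes them, returning
#' the labeled feature table consumed by [twofold_cv()].
#'
#' @param session a [generate_session()] result.
#' @param config a [pipeline_config()].
#' @param progress print one line per trial.
#' @return data.frame: `trial_id`, `subject`, `fold`, `label`, `time`,
#'   `valid`, and all 29 feature columns.
#' @export
extract_session_features <- function(session, config = pipeline_config(),
                                     progress = FALSE) {
  out <- lapply(seq_len(nrow(session$manifest)), function(i) {
    mf <- session$manifest[i, ]
    if (progress) message("extracting ", mf$trial_id)
    stream <- session$eeg[[mf$trial_id]]
    frames <- trial_frames(session, mf$trial_id)
    sync <- trial_feature_table(stream, frames, config)
    data.frame(trial_id = mf$trial_id, subject = mf$subject, fold = mf$fold,
               label = mf$class, sync, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run the synthetic end-to-end benchmark
#'
#' For each seed, generates a fresh default-sized session, extracts all
#' features once, and evaluates the configured method variants with
#' two-fold cross-validation by trial. The standard variants mirror the
#' modality comparison of the source experiment: the fused image+frequency
#' feature set with LDA+SVM, the same features with LDA only, and each
#' single modality with LDA+SVM.
#'
#' @param seeds integer vector of session seeds.
#' @param session_args named list of overrides passed to [session_config()]
#'   (seed is supplied per run).
#' @param methods data.frame with columns `method`, `feature_set`,
#'   `classifier`; NULL for the standard four variants.
#' @param config base [pipeline_config()] whose feature set/classifier are
#'   overridden per method.
#' @param progress print progress lines.
#' @return data.frame: `seed`, `method`, `feature_set`, `classifier`,
#'   `type1`, `type2`, `average`, `auc` (mean of the two test folds).
#' @export
run_benchmark <- function(seeds = 0:9, session_args = list(), methods = NULL,
                          config = pipeline_config(), progress = FALSE) {
  if (is.null(methods)) {
    methods <- data.frame(
      method = c("fused_lda_svm", "fused_lda_only", "image_lda_svm",
                 "freq_lda_svm"),
      feature_set = c("image+freq", "image+freq", "image", "freq"),
      classifier = c("lda_svm", "lda_only", "lda_svm", "lda_svm"),
      stringsAsFactors = FALSE)
  }
  res <- list()
  for (s in seeds) {
    if (progress) message("benchmark seed ", s)
    sess <- generate_session(do.call(session_config,
                                     c(session_args, list(seed = s))))
    feats <- extract_session_features(sess, config, progress = FALSE)
    for (i in seq_len(nrow(methods))) {
      cfg <- config
      cfg$feature_set <- methods$feature_set[i]
      cfg$classifier <- methods$classifier[i]
      cv <- twofold_cv(feats, cfg)
      res[[length(res) + 1]] <- data.frame(
        seed = s, method = methods$method[i],
        feature_set = methods$feature_set[i],
        classifier = methods$classifier[i],
        type1 = cv$averaged$type1, type2 = cv$averaged$type2,
        average = cv$averaged$average, auc = mean(cv$auc),
        stringsAsFactors = FALSE)
      if (progress)
        message(sprintf("  %-15s avg error %.2f%%", methods$method[i],
                        cv$averaged$average))
    }
  }
  do.call(rbind, res)
}
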