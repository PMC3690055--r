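# Error accounting, ROC, two-fold cross-validation and section rejection.

#' Type-1/Type-2/average error report
#'
#' Type 1 error is the percentage of Class-1 (still) samples misclassified
#' as Class 2; Type 2 the percentage of Class-2 (movement) samples
#' misclassified as Class 1; the average error is their mean. Both classes
#' must occur in `truth`, otherwise the corresponding rate is undefined and
#' an error is raised rather than reporting 0.
#'
#' @param predicted,truth integer vectors of classes (1 or 2), same length.
#' @return an `error_report` list: `type1`, `type2`, `average` (percent),
#'   and `counts` (per-class totals and miscounts).
#' @export
error_rates <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  predicted <- as.integer(predicted)
  truth <- as.integer(truth)
  if (!all(truth %in% c(1L, 2L))) stop("error_rates: truth classes must be 1 or 2")
  n1 <- sum(truth == 1L)
  n2 <- sum(truth == 2L)
  if (n1 == 0 || n2 == 0)
    stop("error_rates: a truth class is absent; its rate is undefined")
  m1 <- sum(truth == 1L & predicted == 2L)
  m2 <- sum(truth == 2L & predicted == 1L)
  t1 <- 100 * m1 / n1
  t2 <- 100 * m2 / n2
  structure(list(type1 = t1, type2 = t2, average = (t1 + t2) / 2,
                 counts = c(n_class1 = n1, n_class2 = n2,
                            miss_class1 = m1, miss_class2 = m2)),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("Type 1: %.2f%%  Type 2: %.2f%%  average: %.2f%%\n",
              x$type1, x$type2, x$average))
  invisible(x)
}

#' ROC curve and area under it
#'
#' Sweeps the decision threshold over the unique score values (Class 2 =
#' positive = high scores). Tied scores advance true- and false-positive
#' counts together, so the trapezoidal area equals the pairwise-comparison
#' (Mann-Whitney) estimator with ties counted one half.
#'
#' @param scores raw decision values.
#' @param truth true classes (1/2); both must be present.
#' @return list with `points` (data.frame `threshold`, `fpr`, `tpr`,
#'   monotone in fpr) and `auc`.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.integer(truth)
  if (length(unique(truth)) < 2) stop("roc_curve: need both classes present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  pos <- truth[o] == 2L
  last <- !duplicated(s, fromLast = TRUE) # end of each tie group
  tp <- cumsum(pos)[last]
  fp <- cumsum(!pos)[last]
  tpr <- c(0, tp / sum(pos))
  fpr <- c(0, fp / sum(!pos))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(points = data.frame(threshold = c(Inf, s[last]), fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Two-fold cross-validation by trial
#'
#' Trains the full pipeline (standardization, LDA dimension, kernel and
#' threshold selection) on one fold, tests on the other, swaps, and reports
#' per-fold and averaged Type-1/Type-2/average errors. Folds must be
#' defined at trial level (a `fold` column constant within each
#' `trial_id`); the function refuses data where a trial straddles folds.
#'
#' @param features synchronized labeled feature data.frame with columns
#'   `trial_id`, `fold` (1 or 2), `label`, `valid`, and the feature columns
#'   of the configured feature set.
#' @param config a [pipeline_config()].
#' @return list: `per_fold` (data.frame with errors, chosen `k`, kernel,
#'   threshold per training fold), `averaged` (`type1`, `type2`,
#'   `average`), `auc` (per test fold).
#' @export
twofold_cv <- function(features, config = pipeline_config()) {
  stopifnot(all(c("trial_id", "fold", "label") %in% names(features)))
  ft <- table(features$trial_id, features$fold)
  if (any(rowSums(ft > 0) > 1)) stop("twofold_cv: a trial straddles folds")
  folds <- sort(unique(features$fold))
  if (length(folds) != 2) stop("twofold_cv: need exactly two folds")
  per <- list()
  aucs <- numeric(2)
  for (i in 1:2) {
    tr <- features[features$fold == folds[i], , drop = FALSE]
    te <- features[features$fold == folds[-i][1], , drop = FALSE]
    if (length(unique(tr$label)) < 2 || length(unique(te$label)) < 2)
      stop("twofold_cv: a fold is missing a class")
    fit <- train_pipeline(tr, config)
    pr <- predict_pipeline(fit, te)
    er <- error_rates(pr$labels, pr$truth)
    aucs[i] <- roc_curve(pr$scores, pr$truth)$auc
    per[[i]] <- data.frame(train_fold = folds[i], type1 = er$type1,
                           type2 = er$type2, average = er$average,
                           k = fit$k,
                           kernel = if (is.null(fit$model)) NA_character_ else fit$model$kernel,
                           threshold = if (is.null(fit$model)) NA_real_ else fit$model$threshold)
  }
  per <- do.call(rbind, per)
  list(per_fold = per,
       averaged = list(type1 = mean(per$type1), type2 = mean(per$type2),
                       average = mean(per$average)),
       auc = aucs)
}

#' Excise movement-labeled sections from an EEG stream
#'
#' Each frame-cadence label governs the half-open EEG interval from its
#' timestamp to the next label's timestamp (the last label governs one
#' frame period). Consecutive equal labels merge into one section. Sections
#' are clipped to the stream's span; EEG samples inside Class-2 sections
#' are rejected, the rest are returned as retained segments.
#'
#' @param labels integer classes (1/2) at frame cadence.
#' @param times timestamps of the labels, seconds, strictly increasing.
#' @param stream the [eeg_stream()] the labels refer to.
#' @return list: `sections` (data.frame `start_s`, `end_s`, `label`),
#'   `retained` (list of `eeg_stream` segments), `retained_table`
#'   (data.frame of retained spans), `n_rejected_samples`.
#' @export
reject_sections <- function(labels, times, stream) {
  stopifnot(length(labels) == length(times), length(labels) >= 1,
            inherits(stream, "eeg_stream"), !is.unsorted(times, strictly = TRUE))
  labels <- as.integer(labels)
  period <- if (length(times) > 1) median(diff(times)) else 1 / 30
  bounds <- c(times, times[length(times)] + period)
  r <- rle(labels)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  sections <- data.frame(start_s = bounds[starts_i], end_s = bounds[ends_i + 1L],
                         label = r$values)
  span <- c(stream$t0, stream$t0 + length(stream$samples) / stream$rate)
  sections$start_s <- pmax(sections$start_s, span[1])
  sections$end_s <- pmin(sections$end_s, span[2])
  sections <- sections[sections$end_s > sections$start_s, , drop = FALSE]
  rownames(sections) <- NULL
  st <- stream$t0 + (seq_along(stream$samples) - 1) / stream$rate
  keep <- sections[sections$label == 1L, , drop = FALSE]
  retained <- lapply(seq_len(nrow(keep)), function(i) {
    sel <- st >= keep$start_s[i] & st < keep$end_s[i]
    if (!any(sel)) return(NULL)
    eeg_stream(stream$samples[sel], rate = stream$rate, t0 = st[which(sel)[1]],
               trial_id = stream$trial_id, label = stream$label)
  })
  retained <- Filter(Negate(is.null), retained)
  in_rejected <- rep(FALSE, length(st))
  rej <- sections[sections$label == 2L, , drop = FALSE]
  for (i in seq_len(nrow(rej)))
    in_rejected <- in_rejected | (st >= rej$start_s[i] & st < rej$end_s[i])
  list(sections = sections, retained = retained,
       retained_table = keep[, c("start_s", "end_s")],
       n_rejected_samples = sum(in_rejected))
}
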