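# Feature-level fusion: synchronization, Fisher LDA, kernel SVM with a
# tuned decision threshold.

# Evaluate code under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synchronize EEG epoch features with image features
#'
#' Pairs each frame-pair instant with the EEG epoch whose completion time is
#' nearest (ties to the earlier epoch). Frames earlier than the first
#' complete epoch are dropped with a message reporting the count.
#'
#' @param eeg_features data.frame from [eeg_feature_table()] (needs
#'   `end_time` and `valid`).
#' @param image_features data.frame from [video_feature_table()] (needs
#'   `time`).
#' @return data.frame with one row per retained frame instant: `time`,
#'   `epoch_end_time`, `valid`, all EEG feature columns, all image feature
#'   columns.
#' @export
synchronize_features <- function(eeg_features, image_features) {
  stopifnot(nrow(eeg_features) > 0, nrow(image_features) > 0)
  et <- eeg_features$end_time
  ft <- image_features$time
  if (min(ft) > max(et) + 1 || max(ft) < min(et) - 1)
    stop("synchronize_features: EEG and image time ranges do not overlap")
  keep <- ft >= min(et)
  if (any(!keep))
    message(sprintf("synchronize_features: dropped %d frame(s) earlier than the first complete epoch",
                    sum(!keep)))
  ft <- ft[keep]
  # nearest end_time; et is sorted (epoch order); ties -> earlier epoch
  pos <- findInterval(ft, et)
  pos[pos < 1] <- 1L
  nxt <- pmin(pos + 1L, length(et))
  use_next <- (et[nxt] - ft) < (ft - et[pos])
  idx <- ifelse(use_next, nxt, pos)
  eeg_cols <- setdiff(names(eeg_features), c("end_index", "end_time"))
  img <- image_features[keep, , drop = FALSE]
  out <- data.frame(time = ft, epoch_end_time = et[idx],
                    eeg_features[idx, eeg_cols, drop = FALSE],
                    img[, setdiff(names(img), "time"), drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Fit a Fisher-criterion LDA projection
#'
#' Builds the prior-weighted within-class scatter `M_W = sum_j q_j M_j`
#' (with `M_j` the population covariance of class `j`) and between-class
#' scatter `M_B = sum_j q_j (m_j - m)(m_j - m)^T`, then solves the
#' generalized eigenproblem of `M_W^{-1} M_B`. All eigendirections are
#' retained in descending-eigenvalue order: with two classes `M_B` has rank
#' one so only the leading direction is theoretically discriminative, but
#' trailing directions are kept so that the empirical dimension selection of
#' [select_lda_dim()] can consider them. When `M_W` is numerically singular
#' a Moore-Penrose pseudo-inverse is used and a warning is raised.
#'
#' @param x numeric matrix, rows = samples, columns = features.
#' @param y class labels (1 or 2), one per row; both classes must have at
#'   least 2 samples.
#' @param priors `"empirical"` (class frequencies) or `"uniform"`.
#' @return an object of class `lda_projection`: `vectors` (columns, unit
#'   norm), `eigenvalues`, `k` (selected dimensions, initially 1),
#'   `class_means`, `global_mean`, `priors`, `scatter_within`,
#'   `scatter_between`, `feature_names`.
#' @export
fit_lda <- function(x, y, priors = c("empirical", "uniform")) {
  priors <- match.arg(priors)
  x <- as.matrix(x)
  y <- as.integer(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("fit_lda: need both classes present")
  counts <- table(factor(y, levels = classes))
  if (any(counts < 2)) stop("fit_lda: each class needs at least 2 samples")
  d <- ncol(x)
  q <- if (priors == "empirical") as.numeric(counts) / length(y)
       else rep(1 / length(classes), length(classes))
  m <- colMeans(x)
  MW <- matrix(0, d, d)
  MB <- matrix(0, d, d)
  means <- matrix(0, length(classes), d,
                  dimnames = list(paste0("class", classes), colnames(x)))
  for (j in seq_along(classes)) {
    xj <- x[y == classes[j], , drop = FALSE]
    mj <- colMeans(xj)
    means[j, ] <- mj
    cj <- sweep(xj, 2, mj)
    MW <- MW + q[j] * crossprod(cj) / nrow(xj)
    MB <- MB + q[j] * tcrossprod(mj - m)
  }
  A <- tryCatch({
    if (rcond(MW) < 1e-12) stop("singular")
    solve(MW, MB)
  }, error = function(e) {
    warning("fit_lda: within-class scatter is singular; using pseudo-inverse")
    MASS::ginv(MW) %*% MB
  })
  eig <- eigen(A)
  ord <- order(Re(eig$values), decreasing = TRUE)
  vec <- Re(eig$vectors[, ord, drop = FALSE])
  vec <- sweep(vec, 2, sqrt(colSums(vec^2)), "/")
  structure(list(vectors = vec, eigenvalues = Re(eig$values)[ord], k = 1L,
                 class_means = means, global_mean = m, priors = q,
                 classes = classes, scatter_within = MW, scatter_between = MB,
                 feature_names = colnames(x)),
            class = "lda_projection")
}

#' Project features onto the leading LDA directions
#'
#' @param proj an [fit_lda()] result.
#' @param x feature matrix with the same columns used for fitting.
#' @param k number of leading directions (default `proj$k`).
#' @return n x k matrix of projected coordinates.
#' @export
project_lda <- function(proj, x, k = proj$k) {
  stopifnot(inherits(proj, "lda_projection"), k >= 1, k <= ncol(proj$vectors))
  as.matrix(x) %*% proj$vectors[, seq_len(k), drop = FALSE]
}

#' Fisher ratio of a direction
#'
#' `|u' M_B u| / |u' M_W u|` for a candidate direction `u`; the quantity the
#' leading LDA direction maximises.
#'
#' @param proj an [fit_lda()] result.
#' @param u numeric direction of length `ncol(proj$vectors)`.
#' @return non-negative scalar.
#' @export
fisher_ratio <- function(proj, u) {
  u <- as.numeric(u)
  abs(drop(t(u) %*% proj$scatter_between %*% u)) /
    abs(drop(t(u) %*% proj$scatter_within %*% u))
}

# nearest-class-mean classifier in a projected space
centroid_classify <- function(proj, k, x) {
  z <- project_lda(proj, x, k)
  cm <- proj$class_means %*% proj$vectors[, seq_len(k), drop = FALSE]
  d <- vapply(seq_len(nrow(cm)), function(j)
    rowSums(sweep(z, 2, cm[j, ])^2), numeric(nrow(z)))
  proj$classes[max.col(-d, ties.method = "first")]
}

#' Select the LDA dimension count empirically
#'
#' Splits the training data into a seed-fixed stratified inner split, fits
#' the projection on the inner-train part, and for each candidate `k`
#' scores the average of the two per-class error rates on the held-out part
#' with a nearest-class-mean classifier. Returns the `k` with the smallest
#' average error; ties break toward smaller `k`.
#'
#' @param x,y training features and labels.
#' @param ks candidate dimension counts (default `1:min(d, 8)`).
#' @param inner_frac fraction of samples in the inner-train part.
#' @param seed RNG seed for the split.
#' @return the selected integer `k`, with attribute `errors` (the per-k
#'   average errors).
#' @export
select_lda_dim <- function(x, y, ks = NULL, inner_frac = 0.7, seed = 1L) {
  x <- as.matrix(x)
  if (is.null(ks)) ks <- seq_len(min(ncol(x), 8L))
  if (length(ks) == 0) stop("select_lda_dim: empty candidate set")
  ks <- sort(unique(as.integer(ks)))
  stopifnot(all(ks >= 1), all(ks <= ncol(x)))
  sp <- stratified_split(y, inner_frac, seed)
  proj <- fit_lda(x[sp$train, , drop = FALSE], y[sp$train])
  errs <- vapply(ks, function(k) {
    pred <- centroid_classify(proj, k, x[sp$test, , drop = FALSE])
    error_rates(pred, y[sp$test])$average
  }, numeric(1))
  k <- ks[which.min(errs)] # which.min takes the first minimum; ks sorted
  attr(k, "errors") <- setNames(errs, ks)
  k
}

stratified_split <- function(y, frac, seed) {
  idx <- with_seed(seed, {
    unlist(lapply(unique(y), function(cl) {
      i <- which(y == cl)
      sample(i, max(1L, round(frac * length(i))))
    }))
  })
  list(train = sort(idx), test = setdiff(seq_along(y), idx))
}

#' Default SVM kernel/parameter search grid
#'
#' Covers the four libsvm kernel families: linear; polynomial (degree 2 and
#' 3 with `r = c = 1`); RBF over `r` in {0.125, 0.5, 2, 8, 32}; sigmoid
#' over `r` in {0.01, 0.1} with `c = 0`; each crossed with misclassification
#' cost `C` in {1, 10}.
#'
#' @return data.frame with columns `kernel`, `r`, `c`, `d`, `cost`.
#' @export
default_kernel_grid <- function() {
  g <- rbind(
    data.frame(kernel = "linear", r = NA_real_, c = NA_real_, d = NA_real_),
    data.frame(kernel = "polynomial", r = 1, c = 1, d = c(2, 3)),
    data.frame(kernel = "radial", r = c(0.125, 0.5, 2, 8, 32), c = NA, d = NA),
    data.frame(kernel = "sigmoid", r = c(0.01, 0.1), c = 0, d = NA))
  out <- merge(g, data.frame(cost = c(1, 10)))
  out[order(match(out$kernel, c("linear", "polynomial", "radial", "sigmoid")),
            out$r, out$d, out$cost), c("kernel", "r", "c", "d", "cost")]
}

fit_svm_candidate <- function(x, y, kernel, r, c0, d, cost) {
  yf <- factor(y, levels = c(1, 2))
  args <- list(x = x, y = yf, type = "C-classification", kernel = kernel,
               cost = cost, scale = FALSE)
  if (kernel != "linear") args$gamma <- r
  if (kernel %in% c("polynomial", "sigmoid")) args$coef0 <- c0
  if (kernel == "polynomial") args$degree <- d
  fit <- do.call(e1071::svm, args)
  model <- structure(list(kernel = kernel, r = r, c = c0, d = d, cost = cost,
                          SV = fit$SV, coefs = as.numeric(fit$coefs),
                          rho = as.numeric(fit$rho), flip = 1,
                          threshold = 0, libsvm_fit = fit),
                     class = "decision_model")
  # orient the raw decision value so Class 2 is the positive side
  f <- decision_values(model, x)
  if (mean(f[y == 2]) < mean(f[y == 1])) model$flip <- -1
  model
}

#' Raw SVM decision values
#'
#' Evaluates the kernel expansion `sum_k a_k y_k K(x_k, x) + b` over the
#' stored support set directly (so a deserialized model needs no fitted
#' libsvm object), with the sign oriented so that Class 2 is positive.
#'
#' @param model a `decision_model` from [train_svm()].
#' @param x feature matrix on the model's input scale.
#' @return numeric vector of raw (un-thresholded) decision values.
#' @export
decision_values <- function(model, x) {
  x <- as.matrix(x)
  sv <- model$SV
  K <- switch(model$kernel,
    linear = x %*% t(sv),
    polynomial = (model$r * (x %*% t(sv)) + model$c)^model$d,
    radial = {
      d2 <- outer(rowSums(x^2), rowSums(sv^2), "+") - 2 * x %*% t(sv)
      exp(-model$r * pmax(d2, 0))
    },
    sigmoid = tanh(model$r * (x %*% t(sv)) + model$c),
    stop("unknown kernel: ", model$kernel))
  model$flip * (drop(K %*% model$coefs) - model$rho)
}

#' Train the kernel SVM over a parameter grid
#'
#' Fits a soft-margin SVM for every kernel/parameter candidate on a
#' seed-fixed stratified inner split of the training data, scores the
#' average of the per-class error rates on the held-out part (at the
#' default zero threshold), refits the winning candidate on all of `x`,
#' and returns it. Class 1 maps to the -1 side and Class 2 to the +1 side
#' of the decision function.
#'
#' @param x training feature matrix (already standardized/projected).
#' @param y labels, 1 or 2, both present.
#' @param grid candidate table as from [default_kernel_grid()].
#' @param inner_frac fraction of samples used for candidate fitting.
#' @param seed RNG seed for the inner split.
#' @return a `decision_model`: kernel spec, support set, weights, bias,
#'   sign orientation, `threshold` (0 until [select_threshold()] is
#'   applied), plus the `selection` table of per-candidate errors.
#' @export
train_svm <- function(x, y, grid = default_kernel_grid(), inner_frac = 0.7,
                      seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("train_svm: need both classes present")
  if (any(!is.finite(x))) stop("train_svm: non-finite features")
  sp <- stratified_split(y, inner_frac, seed)
  errs <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cand <- tryCatch(
      fit_svm_candidate(x[sp$train, , drop = FALSE], y[sp$train],
                        g$kernel, g$r, g$c, g$d, g$cost),
      error = function(e) NULL)
    if (is.null(cand)) next
    pred <- ifelse(decision_values(cand, x[sp$test, , drop = FALSE]) > 0, 2L, 1L)
    errs[i] <- error_rates(pred, y[sp$test])$average
  }
  if (all(is.na(errs))) stop("train_svm: no grid candidate could be fitted")
  best <- grid[which.min(errs), ]
  model <- fit_svm_candidate(x, y, best$kernel, best$r, best$c, best$d, best$cost)
  model$selection <- cbind(grid, avg_error = errs)
  model
}

#' @export
print.decision_model <- function(x, ...) {
  cat(sprintf("<decision_model> %s kernel (r=%s, c=%s, d=%s), cost=%g, %d SVs, threshold=%.4g\n",
              x$kernel, format(x$r), format(x$c), format(x$d), x$cost,
              nrow(x$SV), x$threshold))
  invisible(x)
}

#' Tune the decision threshold
#'
#' Sweeps candidate cutoffs (the midpoints of consecutive sorted unique
#' decision values, plus -Inf and +Inf) and returns the one minimising the
#' average of the two per-class error rates under the rule "Class 2 iff
#' value > threshold". Ties break toward the threshold nearest 0.
#'
#' @param scores raw decision values of a labeled tuning set, or a
#'   `decision_model` (then `x` must be supplied and scores are computed).
#' @param y true classes (1/2) of the tuning set.
#' @param x tuning feature matrix when `scores` is a model.
#' @return the selected threshold, with attribute `avg_error`.
#' @export
select_threshold <- function(scores, y, x = NULL) {
  if (inherits(scores, "decision_model")) {
    stopifnot(!is.null(x))
    scores <- decision_values(scores, x)
  }
  y <- as.integer(y)
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  n1 <- sum(y == 1)
  n2 <- sum(y == 2)
  errs <- vapply(cand, function(th) {
    t1 <- if (n1) 100 * sum(scores[y == 1] > th) / n1 else 0
    t2 <- if (n2) 100 * sum(scores[y == 2] <= th) / n2 else 0
    (t1 + t2) / 2
  }, numeric(1))
  best <- which(errs == min(errs))
  th <- cand[best[which.min(abs(cand[best]))]]
  attr(th, "avg_error") <- min(errs)
  th
}

#' Classify feature vectors with a thresholded decision model
#'
#' Class 2 (movement) iff the raw decision value strictly exceeds the
#' model's threshold; values at or below it (including exact ties) are
#' Class 1, so EEG is only rejected on strict evidence.
#'
#' @param model a `decision_model` with a tuned `threshold`.
#' @param x feature matrix on the model's input scale.
#' @return integer vector of predicted classes (1 or 2).
#' @export
classify_movement <- function(model, x) {
  ifelse(decision_values(model, x) > model$threshold, 2L, 1L)
}
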