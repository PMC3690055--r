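# Independent brute-force oracles used to freeze expected values.
# These deliberately re-derive every quantity from its printed definition
# with naive loops, sharing no code with the package internals.

oracle_normalize <- function(x) {
  centred <- x - sum(x) / length(x)
  lo <- min(centred); hi <- max(centred)
  -1 + 2 * (centred - lo) / (hi - lo)
}

# O(n^2) discrete Fourier magnitude at bins 0..n-1
oracle_dft_mag <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k) {
    Mod(sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)))
  }, numeric(1))
}

oracle_band_features <- function(x, bands, rate = 128) {
  mag <- oracle_dft_mag(x)
  hz_per_bin <- rate / length(x)
  vapply(seq_len(nrow(bands)), function(b) {
    ks <- seq.int(ceiling(bands$low[b] / hz_per_bin),
                  floor(bands$high[b] / hz_per_bin))
    mean(mag[ks + 1])
  }, numeric(1))
}

oracle_time_features <- function(x) {
  n <- length(x)
  pop_var <- function(v) sum((v - mean(v))^2) / length(v)
  zc <- function(v) {
    cnt <- 0
    for (i in seq_len(length(v) - 1)) if (v[i] * v[i + 1] < 0) cnt <- cnt + 1
    cnt
  }
  mu <- mean(x)
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  d1 <- x[-1] - x[-n]
  d2 <- d1[-1] - d1[-length(d1)]
  mob <- sqrt(pop_var(d1) / pop_var(x))
  c(kurtosis = m4 / m2^2,
    skewness = m3 / m2^1.5,
    rms_amplitude = max(abs(x)) / sqrt(2),
    zero_crossings = zc(x),
    minimum = min(x),
    maximum = max(x),
    var_d1 = pop_var(d1),
    var_d2 = pop_var(d2),
    zc_d1 = zc(d1),
    zc_d2 = zc(d2),
    activity = pop_var(x),
    mobility = mob,
    complexity = sqrt(pop_var(d2) / pop_var(d1)) / mob)
}

oracle_pixel_diff <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a)))
    for (j in seq_len(ncol(a)))
      s <- s + abs(a[i, j] - b[i, j])
  s / (nrow(a) * ncol(a))
}

# explicit 2-D convolution with the two Sobel masks, replicate padding
oracle_sobel <- function(frame) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3) # columns = x direction
  ky <- t(kx)
  h <- nrow(frame); w <- ncol(frame)
  cl <- function(i, n) min(max(i, 1), n)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      gx <- 0; gy <- 0
      for (di in -1:1) for (dj in -1:1) {
        v <- frame[cl(i + di, h), cl(j + dj, w)]
        gx <- gx + kx[di + 2, dj + 2] * v
        gy <- gy + ky[di + 2, dj + 2] * v
      }
      out[i, j] <- sqrt(gx^2 + gy^2)
    }
  }
  out
}

# pairwise-comparison (Mann-Whitney) AUC estimator, ties counted one half
oracle_auc <- function(scores, truth) {
  s1 <- scores[truth == 1]
  s2 <- scores[truth == 2]
  tot <- 0
  for (a in s2) for (b in s1)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(s1) * length(s2))
}

# exhaustive threshold sweep; returns the minimal average error (percent)
oracle_min_avg_error <- function(scores, truth) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- Inf
  for (th in cand) {
    t1 <- 100 * mean(scores[truth == 1] > th)
    t2 <- 100 * mean(scores[truth == 2] <= th)
    best <- min(best, (t1 + t2) / 2)
  }
  best
}

# textured frame pair: crops of one smooth-noise texture at two offsets
make_shifted_pair <- function(seed, dx = 0, dy = 0, w = 160, h = 120,
                              margin = 16) {
  set.seed(seed)
  tex <- matrix(runif((h + 2 * margin) * (w + 2 * margin)), h + 2 * margin)
  # triple smoothing: ~4 px correlation length, so differences stay
  # monotone in the shift over the tested 0-10 px range
  for (i in 1:3) tex <- movart:::smooth5(tex)
  tex <- (tex - min(tex)) / (max(tex) - min(tex)) * 235 + 10
  fr <- movart:::.cpp_render_pan(tex, c(margin, margin + dx),
                                 c(margin, margin + dy), w, h)
  list(a = fr[, , 1], b = fr[, , 2])
}

# one tiny labeled session feature table, computed once per test run
tiny_session_feats <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$feats)) {
      cfg <- session_config(duration_s = 8, n_subjects = 2, seed = 11)
      sess <- generate_session(cfg)
      cache$feats <- extract_session_features(sess)
    }
    cache$feats
  }
})
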