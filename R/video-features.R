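#' Construct a frame sequence
#'
#' Grayscale 8-bit frames at a fixed rate, stored as an `h x w x n` integer
#' array (column-major; row = image y, column = image x). Frame `i` carries
#' timestamp `t0 + (i - 1) / rate`.
#'
#' @param frames `h x w x n` integer array of intensities in 0..255, or a
#'   list of equally sized matrices.
#' @param rate frames per second (default 30).
#' @param t0 timestamp of the first frame, seconds.
#' @return an object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, rate = 30, t0 = 0) {
  if (is.list(frames)) {
    dims <- vapply(frames, dim, integer(2))
    if (ncol(dims) > 1 && any(dims[, -1] != dims[, 1]))
      stop("frame_sequence: frames have inconsistent shapes")
    arr <- array(0L, c(dims[1, 1], dims[2, 1], length(frames)))
    for (i in seq_along(frames)) arr[, , i] <- as.integer(round(frames[[i]]))
    frames <- arr
  }
  stopifnot(length(dim(frames)) == 3, rate > 0)
  storage.mode(frames) <- "integer"
  if (min(frames) < 0 || max(frames) > 255)
    stop("frame_sequence: intensities must lie in 0..255")
  structure(list(frames = frames, rate = rate, t0 = t0),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_sequence> %d frames of %dx%d px @ %g fps, t0 = %g s\n",
              d[3], d[2], d[1], x$rate, x$t0))
  invisible(x)
}

#' @rdname frame_sequence
#' @param x a `frame_sequence`.
#' @param i frame index.
#' @export
get_frame <- function(x, i) {
  stopifnot(inherits(x, "frame_sequence"))
  x$frames[, , i]
}

#' Frame times of a sequence
#' @param x a `frame_sequence`.
#' @return numeric vector of per-frame timestamps in seconds.
#' @export
frame_times <- function(x) {
  stopifnot(inherits(x, "frame_sequence"))
  x$t0 + (seq_len(dim(x$frames)[3]) - 1) / x$rate
}

#' Tracker and feature parameters for the video pipeline
#'
#' Defaults are sized for the package's 160x120 working resolution: up to
#' 100 Shi-Tomasi corners (quality 0.01 of the strongest response, minimum
#' 5 px apart) tracked with a 15x15 pyramidal Lucas-Kanade window over 3
#' pyramid levels. `min_mag` is the motion-vector acceptance floor in px
#' (0 = count every successfully tracked vector).
#'
#' @param max_corners maximum number of corners to track per frame pair.
#' @param quality corner quality level, fraction of the maximal
#'   minimum-eigenvalue response.
#' @param min_distance minimum distance between accepted corners, px.
#' @param win odd tracking window side length, px.
#' @param levels number of pyramid levels.
#' @param max_iter maximum Lucas-Kanade iterations per level.
#' @param eps iteration convergence threshold, px.
#' @param min_mag acceptance threshold on motion-vector magnitude, px.
#' @return a named list of class `video_params`.
#' @export
video_params <- function(max_corners = 100, quality = 0.01, min_distance = 5,
                         win = 15, levels = 3, max_iter = 20, eps = 0.01,
                         min_mag = 0) {
  stopifnot(win %% 2 == 1, win >= 3, levels >= 1, max_corners >= 1)
  structure(list(max_corners = max_corners, quality = quality,
                 min_distance = min_distance, win = win, levels = levels,
                 max_iter = max_iter, eps = eps, min_mag = min_mag),
            class = "video_params")
}

check_frame_pair <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop(sprintf("frame shape mismatch: %dx%d vs %dx%d",
                 nrow(a), ncol(a), nrow(b), ncol(b)))
}

#' Mean absolute pixel difference of two frames
#'
#' The per-pixel absolute intensity difference averaged over the frame, so
#' the value is resolution independent; 0 iff the frames are identical.
#'
#' @param a,b grayscale frames (numeric matrices, same shape).
#' @return non-negative scalar in intensity units.
#' @export
pixel_difference <- function(a, b) {
  check_frame_pair(a, b)
  mean(abs(a - b))
}

#' Sobel gradient-magnitude map
#'
#' Applies the horizontal and vertical 3x3 Sobel masks (replicate border
#' handling) and combines the two responses as their L2 norm per pixel.
#'
#' @param frame grayscale frame, at least 3x3.
#' @return matrix of gradient magnitudes, same shape as `frame`.
#' @export
sobel_magnitude <- function(frame) {
  stopifnot(nrow(frame) >= 3, ncol(frame) >= 3)
  .cpp_sobel_mag(matrix(as.numeric(frame), nrow(frame)))
}

#' Mean absolute difference of Sobel edge maps
#'
#' [pixel_difference()] applied to the [sobel_magnitude()] maps of the two
#' frames; responds to moving structure while ignoring global intensity
#' shifts.
#'
#' @inheritParams pixel_difference
#' @return non-negative scalar.
#' @export
edge_pixel_difference <- function(a, b) {
  check_frame_pair(a, b)
  pixel_difference(sobel_magnitude(a), sobel_magnitude(b))
}

#' Detect Shi-Tomasi corners
#'
#' Minimum-eigenvalue corner detector on the Sobel structure tensor with
#' 3x3 integration window, non-maximum suppression and greedy
#' minimum-distance thinning.
#'
#' @param frame grayscale frame.
#' @param params a [video_params()] list.
#' @return data.frame with 1-based pixel coordinates `x` (column), `y`
#'   (row) and `score`.
#' @export
detect_corners <- function(frame, params = video_params()) {
  border <- (params$win %/% 2 + 2) * 2^(params$levels - 1)
  while (border > 2 && (2 * border >= nrow(frame) - 2 ||
                        2 * border >= ncol(frame) - 2)) border <- border %/% 2
  m <- .cpp_corners(matrix(as.numeric(frame), nrow(frame)),
                    params$max_corners, params$quality, params$min_distance,
                    as.integer(border))
  data.frame(x = m[, "x"] + 1, y = m[, "y"] + 1, score = m[, "score"])
}

#' Track corners between two frames (pyramidal Lucas-Kanade)
#'
#' Detects corners in `a` and tracks each into `b` by iteratively minimising
#' the windowed squared brightness residual, coarse-to-fine over an image
#' pyramid. Points whose spatial-gradient matrix is near-singular or that
#' leave the frame are dropped, never fabricated; a cornerless (e.g.
#' uniform) frame yields an empty result.
#'
#' @param a,b grayscale frames of identical shape.
#' @param params a [video_params()] list.
#' @param corners optional precomputed corner data.frame (as from
#'   [detect_corners()]); detected in `a` when NULL.
#' @return data.frame of motion vectors: origin `x`, `y` (1-based px in
#'   `a`), displacement `dx`, `dy`, and `magnitude` (px).
#' @export
track_motion <- function(a, b, params = video_params(), corners = NULL) {
  check_frame_pair(a, b)
  if (is.null(corners)) corners <- detect_corners(a, params)
  if (nrow(corners) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), dx = numeric(0),
                      dy = numeric(0), magnitude = numeric(0)))
  }
  pts <- cbind(corners$x - 1, corners$y - 1)
  tr <- .cpp_track(matrix(as.numeric(a), nrow(a)),
                   matrix(as.numeric(b), nrow(b)), pts,
                   params$win, params$levels, params$max_iter, params$eps)
  ok <- tr[, "status"] > 0
  data.frame(x = corners$x[ok], y = corners$y[ok],
             dx = tr[ok, "dx"], dy = tr[ok, "dy"],
             magnitude = sqrt(tr[ok, "dx"]^2 + tr[ok, "dy"]^2))
}

#' Summarise motion vectors into the two scalar features
#'
#' Vectors with magnitude below `min_mag` are discarded; the features are
#' the count of the remaining vectors and their mean magnitude (0 when none
#' remain).
#'
#' @param vectors data.frame as from [track_motion()] (only `magnitude` is
#'   used), or a bare numeric vector of magnitudes.
#' @param min_mag acceptance threshold in px.
#' @return named numeric vector `c(mv_avg_mag, mv_count)`.
#' @export
motion_features <- function(vectors, min_mag = 0) {
  mags <- if (is.data.frame(vectors)) vectors$magnitude else as.numeric(vectors)
  mags <- mags[mags >= min_mag]
  c(mv_avg_mag = if (length(mags)) mean(mags) else 0,
    mv_count = length(mags))
}

#' Per-frame-pair feature table for a sequence
#'
#' Computes all four motion features for every consecutive frame pair in
#' one pass (edge maps and pyramids are shared between neighbouring pairs).
#' Row `i` describes the transition from frame `i` to frame `i + 1` and is
#' stamped with the time of frame `i + 1` (the instant the change is
#' observable); the first frame of a sequence therefore has no feature row.
#'
#' @param x a [frame_sequence()].
#' @param params a [video_params()] list.
#' @return data.frame with `time`, `pixel_diff`, `edge_diff`, `mv_avg_mag`,
#'   `mv_count`.
#' @export
video_feature_table <- function(x, params = video_params()) {
  stopifnot(inherits(x, "frame_sequence"))
  n <- dim(x$frames)[3]
  if (n < 2) stop("video_feature_table: need at least 2 frames")
  m <- .cpp_video_features(x$frames, params$max_corners, params$quality,
                           params$min_distance, params$win, params$levels,
                           params$max_iter, params$eps, params$min_mag)
  data.frame(time = frame_times(x)[-1], as.data.frame(m))
}
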