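# Motion scoring: sliding-window background model -> per-pixel 1-D
# Mahalanobis distance -> binary motion mask -> A index (fraction of
# "active" pixels per frame).

#' Background model from a window of preceding frames
#'
#' Per-pixel mean and standard deviation over the last `W` frames that
#' precede the frame about to be scored (the scored frame itself is never in
#' the window). The default window of 28 frames at the nominal 14 Hz spans
#' about 2 seconds. The SD uses the population convention (divide by `W`)
#' and is floored at `sd_floor` so that perfectly static pixels, whose
#' empirical SD collapses to 0 under 8-bit quantisation, do not blow up the
#' distance.
#'
#' @param window list of `W >= 2` grayscale matrices of one geometry, oldest
#'   first; must hold exactly the configured window size.
#' @param window_size expected window length `W` (default 28).
#' @param sd_floor lower bound on the per-pixel SD, in intensity levels
#'   (default 2).
#' @return An object of class `background_model` with matrices `mean`, `sd`
#'   and the scalar `window_size`.
#' @export
update_background <- function(window, window_size = 28L, sd_floor = 2) {
  stopifnot(is.list(window), window_size >= 2L, sd_floor > 0)
  if (length(window) != window_size)
    stop(sprintf("warm-up not complete: background window has %d of %d frames",
                 length(window), window_size))
  d <- dim(window[[1L]])
  if (!all(vapply(window, function(f) identical(dim(f), d), TRUE)))
    stop("window frames must share one geometry")
  W <- length(window)
  m <- Reduce(`+`, window) / W
  m2 <- Reduce(`+`, lapply(window, function(f) f * f)) / W
  s <- sqrt(pmax(m2 - m * m, 0))
  structure(list(mean = m, sd = pmax(s, sd_floor), window_size = W),
            class = "background_model")
}

#' Per-pixel grayscale Mahalanobis distance to the background
#'
#' In one dimension the Mahalanobis distance reduces to
#' `d = |x - mean| / sd`, the deviation of each pixel from the background
#' model in background-SD units.
#'
#' @param frame grayscale matrix with the model's geometry.
#' @param model a [update_background()] result.
#' @return Non-negative numeric matrix of distances.
#' @export
mahalanobis_map <- function(frame, model) {
  stopifnot(inherits(model, "background_model"))
  if (!identical(dim(frame), dim(model$mean)))
    stop("frame geometry does not match background model")
  abs(frame - model$mean) / model$sd
}

#' Binary motion mask
#'
#' Pixels whose distance strictly exceeds the threshold `k` are classified
#' "active" (1, white); all others stay 0 (black). `k = 3` is the 3-sigma
#' default; the original recorder's exact value is not published, so it is a
#' tunable.
#'
#' @param dist distance matrix from [mahalanobis_map()].
#' @param k positive pixel-level threshold in SD units.
#' @return Integer 0/1 matrix of the same geometry.
#' @export
threshold_mask <- function(dist, k = 3) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0) stop("k must be > 0")
  m <- dist > k
  storage.mode(m) <- "integer"
  m
}

#' A index of a motion mask
#'
#' The per-frame activity score: the fraction of active (white) pixels in
#' the whole image, in `[0, 1]`.
#'
#' @param mask 0/1 matrix from [threshold_mask()].
#' @return Scalar in `[0, 1]`.
#' @export
frame_A <- function(mask) {
  if (length(mask) == 0L) stop("empty mask")
  sum(mask) / length(mask)
}

#' Per-frame A index series for a frame sequence
#'
#' Runs the full scoring chain frame by frame: each frame after the
#' `window_size`-frame warm-up is scored against the background model of the
#' `window_size` frames immediately preceding it (sliding by one frame per
#' step). Warm-up frames yield no sample.
#'
#' @param frames a [frame_series()] (or plain list of grayscale matrices, in
#'   which case `timestamps` indexes frames 1..n in seconds).
#' @param window_size background window length `W` (default 28).
#' @param k pixel threshold in SD units (default 3).
#' @param sd_floor SD floor in intensity levels (default 2).
#' @return `data.frame` with columns `timestamp`, `A`, one row per scored
#'   frame; attribute `fps` carries the frame rate for aggregation.
#' @export
compute_A_series <- function(frames, window_size = 28L, k = 3, sd_floor = 2) {
  if (inherits(frames, "frame_series")) {
    ts <- frames$timestamps
    fps <- frames$fps
    frames <- frames$frames
  } else {
    stopifnot(is.list(frames))
    ts <- as_motact_time(seq_along(frames))
    fps <- 1
  }
  n <- length(frames)
  W <- as.integer(window_size)
  if (W < 2L) stop("window_size must be >= 2")
  if (k <= 0) stop("k must be > 0")
  if (n <= W)
    stop(sprintf("warm-up not complete: need more than %d frames, got %d", W, n))
  npx <- length(frames[[1L]])
  # sliding sums; flush accumulated rounding error every `reset_every` steps
  S <- Reduce(`+`, frames[seq_len(W)])
  S2 <- Reduce(`+`, lapply(frames[seq_len(W)], function(f) f * f))
  reset_every <- 5000L
  A <- numeric(n - W)
  for (t in seq.int(W + 1L, n)) {
    if ((t - W) %% reset_every == 0L) {
      idx <- seq.int(t - W, t - 1L)
      S <- Reduce(`+`, frames[idx])
      S2 <- Reduce(`+`, lapply(frames[idx], function(f) f * f))
    }
    mu <- S / W
    sdv <- pmax(sqrt(pmax(S2 / W - mu * mu, 0)), sd_floor)
    A[t - W] <- sum(abs(frames[[t]] - mu) / sdv > k) / npx
    f_new <- frames[[t]]; f_old <- frames[[t - W]]
    S <- S + (f_new - f_old)
    S2 <- S2 + (f_new * f_new - f_old * f_old)
  }
  out <- data.frame(timestamp = ts[seq.int(W + 1L, n)], A = A)
  attr(out, "fps") <- fps
  class(out) <- c("A_series", "data.frame")
  out
}
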