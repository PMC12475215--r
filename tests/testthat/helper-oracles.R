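# Independent oracles and fixture builders. The oracles deliberately avoid
# the package's code paths: the motion oracle is a per-pixel loop over a 3-D
# array; the ephemeris oracle root-finds the solar-altitude crossing instead
# of inverting the hour-angle formula.

# naive per-pixel A-series oracle: for every scored frame, loop pixels,
# take mean / population SD of the 28-frame window with base helpers
naive_A_series <- function(frames, window_size = 28L, k = 3, sd_floor = 2) {
  arr <- simplify2array(frames)  # h x w x n
  h <- dim(arr)[1L]; w <- dim(arr)[2L]; n <- dim(arr)[3L]
  W <- window_size
  out <- numeric(n - W)
  for (t in seq.int(W + 1L, n)) {
    n_active <- 0L
    for (i in seq_len(h)) for (j in seq_len(w)) {
      x <- arr[i, j, seq.int(t - W, t - 1L)]
      m <- mean(x)
      s <- max(sqrt(mean((x - m)^2)), sd_floor)
      if (abs(arr[i, j, t] - m) / s > k) n_active <- n_active + 1L
    }
    out[t - W] <- n_active / (h * w)
  }
  out
}

random_video <- function(n_frames, h = 16L, w = 16L) {
  replicate(n_frames, matrix(sample(0:255, h * w, replace = TRUE), h, w),
            simplify = FALSE)
}

as_fs <- function(frames, fps = 14, t0 = "2016-03-01 10:00:00") {
  t0 <- as.POSIXct(t0, tz = "Etc/GMT-1")
  frame_series(frames, t0 + (seq_along(frames) - 1) / fps, fps = fps)
}

# deterministic non-revisiting blob video: an 8x8 square on a flat
# background sweeps the frame by its own width each frame (lane by lane),
# so no pixel is visited twice within any 28-frame window
sweep_blob_video <- function(n_frames, dim_px = 128L, blob = 8L,
                             bg = 120, value = 220) {
  lanes <- dim_px / blob
  lapply(seq_len(n_frames), function(t) {
    f <- matrix(bg, dim_px, dim_px)
    pos <- (t - 1L) %% (lanes * lanes)
    row0 <- (pos %/% lanes) * blob
    col0 <- (pos %% lanes) * blob
    f[row0 + seq_len(blob), col0 + seq_len(blob)] <- value
    f
  })
}

# high-accuracy-style ephemeris oracle: root-find the instant the true
# solar altitude crosses -0.833 degrees (self-contained formulas)
oracle_sun_event <- function(date, lat, lon, rise = TRUE) {
  alt <- function(min_utc) {
    jd <- as.numeric(as.Date(date) - as.Date("2000-01-01")) + 2451544.5 +
      min_utc / 1440
    T <- (jd - 2451545) / 36525
    L0 <- (280.46646 + 36000.76983 * T) %% 360
    M <- (357.52911 + 35999.05029 * T) * pi / 180
    C <- 1.914602 * sin(M) + 0.019993 * sin(2 * M) + 0.000289 * sin(3 * M)
    lam <- (L0 + C - 0.00569 - 0.00478 * sin((125.04 - 1934.136 * T) * pi / 180)) * pi / 180
    eps <- (23.439291 - 0.0130042 * T) * pi / 180
    decl <- asin(sin(eps) * sin(lam))
    # apparent sidereal time -> local hour angle of the sun
    ra <- atan2(cos(eps) * sin(lam), cos(lam))
    gmst <- (280.46061837 + 360.98564736629 * (jd - 2451545)) %% 360
    H <- ((gmst + lon) * pi / 180 - ra)
    asin(sin(lat * pi / 180) * sin(decl) +
           cos(lat * pi / 180) * cos(decl) * cos(H)) * 180 / pi + 0.833
  }
  # search the appropriate half-day around local solar noon
  noon <- 720 - 4 * lon
  iv <- if (rise) c(noon - 719, noon - 1) else c(noon + 1, noon + 719)
  stats::uniroot(alt, iv, tol = 1e-4)$root
}

# toy daily activity table covering the full study range
toy_daily <- function(seed = 1, sd = 0.006) {
  set.seed(seed)
  dates <- seq(as.Date("2016-03-01"), as.Date("2016-04-29"), by = "day")
  pre <- dates < as.Date("2016-03-14")
  data.frame(date = dates,
             A1 = ifelse(pre, 0.0512, 0.0419) + rnorm(length(dates), 0, sd))
}
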