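# Binning per-frame A samples into the A1 activity index and reshaping
# 10-minute series into the day x time-of-day actogram matrix.

utc_offset_seconds <- function(tz = MOTACT_TZ) {
  off <- as.POSIXlt(as.POSIXct("2016-01-01 12:00:00", tz = tz))$gmtoff
  if (!is.null(off) && !is.na(off) && off != 0L) return(as.integer(off))
  # tz database unavailable: parse fixed-offset POSIX names (Etc/GMT-1 is
  # UTC+1; the POSIX sign is inverted)
  m <- regmatches(tz, regexec("^Etc/GMT([+-])(\\d+)$", tz))[[1L]]
  if (length(m) == 3L)
    return(as.integer(ifelse(m[2L] == "+", -1L, 1L) * as.numeric(m[3L]) * 3600))
  0L
}

#' Aggregate per-frame A samples into the binned A1 index
#'
#' Within each bin, A1 is the fraction of frames whose A index strictly
#' exceeds `a_threshold` (default 0.01, the noise-suppression level): the
#' fraction of the bin during which noticeable group motor activity was
#' detected. Bins are aligned to local standard-time midnight. A bin's
#' `coverage` is the fraction of its expected `fps * bin_length` frames that
#' actually carry samples; bins below `coverage_min` (and empty bins inside
#' the series span) are reported as missing (`NA`), never as zero.
#'
#' @param samples an `A_series` from [compute_A_series()], or any data.frame
#'   with `timestamp` and `A` columns (ordered).
#' @param bin_length_s bin length in seconds; 600 for actograms, 86400 for
#'   daily values. Must divide 24 h for heatmap use.
#' @param a_threshold frame-level A threshold (strict "exceeds").
#' @param fps expected frames per second (taken from the sample attribute
#'   when present).
#' @param coverage_min minimum coverage for a bin to be reported (default 0.5).
#' @return An `activity_series` data.frame with columns `bin_start`,
#'   `bin_length_s`, `A1`, `n_frames`, `coverage`.
#' @export
aggregate_A1 <- function(samples, bin_length_s = 600, a_threshold = 0.01,
                         fps = NULL, coverage_min = 0.5) {
  stopifnot(all(c("timestamp", "A") %in% names(samples)))
  if (bin_length_s <= 0) stop("bin_length_s must be positive")
  if (a_threshold < 0) stop("a_threshold must be >= 0")
  if (is.null(fps)) fps <- attr(samples, "fps")
  if (is.null(fps)) stop("fps not given and not carried by the samples")
  ts <- as_motact_time(samples$timestamp)
  if (is.unsorted(as.numeric(ts))) stop("samples must be time-ordered")
  off <- utc_offset_seconds()
  bin_idx <- floor((as.numeric(ts) + off) / bin_length_s)
  full_idx <- seq.int(min(bin_idx), max(bin_idx))
  hit <- samples$A > a_threshold  # strict
  n_f <- tabulate(bin_idx - full_idx[1L] + 1L, nbins = length(full_idx))
  n_hit <- vapply(split(hit, factor(bin_idx, levels = full_idx)), sum, 0)
  expected <- fps * bin_length_s
  coverage <- pmin(n_f / expected, 1)
  A1 <- ifelse(n_f > 0, n_hit / n_f, NA_real_)
  A1[coverage < coverage_min] <- NA_real_
  out <- data.frame(
    bin_start = as.POSIXct(full_idx * bin_length_s - off,
                           origin = "1970-01-01", tz = MOTACT_TZ),
    bin_length_s = bin_length_s,
    A1 = unname(A1),
    n_frames = n_f,
    coverage = unname(coverage))
  class(out) <- c("activity_series", "data.frame")
  out
}

#' Collapse a binned activity series to daily A1
#'
#' Daily A1 is the frame-weighted mean of the day's bin values, i.e. the
#' fraction of the day's scored frames with noticeable activity. Days whose
#' non-missing bins cover less than `coverage_min` of the day are `NA`.
#'
#' @param series an `activity_series` at sub-daily bins.
#' @param coverage_min minimal fraction of the day that must be covered.
#' @return data.frame with columns `date`, `A1`, `n_frames`, `coverage`.
#' @export
daily_A1 <- function(series, coverage_min = 0.5) {
  stopifnot(inherits(series, "data.frame"), "A1" %in% names(series))
  bl <- series$bin_length_s[1L]
  day <- as.Date(series$bin_start, tz = MOTACT_TZ)
  ok <- !is.na(series$A1)
  agg <- function(f, x) vapply(split(x, day), f, 0)
  w_sum <- agg(sum, ifelse(ok, series$n_frames, 0))
  a_sum <- agg(sum, ifelse(ok, series$A1 * series$n_frames, 0))
  bins_per_day <- 86400 / bl
  cov <- agg(sum, as.numeric(ok)) / bins_per_day
  out <- data.frame(
    date = as.Date(names(w_sum)),
    A1 = ifelse(w_sum > 0 & cov >= coverage_min, a_sum / w_sum, NA_real_),
    n_frames = unname(w_sum),
    coverage = unname(cov))
  rownames(out) <- NULL
  out
}

#' Day x time-of-day actogram matrix
#'
#' Reshapes a 10-minute activity series into the chronobiology actogram
#' raster: one row per calendar day, 144 columns of 10-minute bins, all bin
#' starts expressed on the fixed standard-time clock (UTC+1) regardless of
#' civil DST, so a bin labelled 05:00 civil summer time lands in the 04:00
#' column.
#'
#' @param series `activity_series` with `bin_length_s = 600` throughout.
#' @return An `activity_heatmap`: list with `matrix` (days x 144),
#'   `day_labels` (`Date`), `clock_basis`.
#' @export
build_heatmap <- function(series) {
  stopifnot(inherits(series, "data.frame"))
  if (length(unique(series$bin_length_s)) != 1L)
    stop("mixed bin lengths in series")
  bl <- series$bin_length_s[1L]
  if (bl != 600) stop("heatmap requires 10-minute bins (bin_length_s = 600)")
  ts <- as_motact_time(series$bin_start)
  day <- as.Date(ts, tz = MOTACT_TZ)
  lt <- as.POSIXlt(ts)
  col <- (lt$hour * 3600 + lt$min * 60 + lt$sec) %/% bl + 1L
  days <- seq(min(day), max(day), by = "day")
  m <- matrix(NA_real_, nrow = length(days), ncol = 86400 / bl,
              dimnames = list(as.character(days), NULL))
  m[cbind(match(day, days), col)] <- series$A1
  structure(list(matrix = m, day_labels = days, clock_basis = "UTC+1 (standard time)"),
            class = "activity_heatmap")
}

#' @export
print.activity_heatmap <- function(x, ...) {
  cat(sprintf("<activity_heatmap> %d days x %d bins, clock %s, %.1f%% missing\n",
              nrow(x$matrix), ncol(x$matrix), x$clock_basis,
              100 * mean(is.na(x$matrix))))
  invisible(x)
}

# ---- CSV schemas -------------------------------------------------------

iso_stamp <- function(t) format(t, "%Y-%m-%dT%H:%M:%S")

#' Write / read an activity series CSV
#'
#' Schema: `bin_start_iso, bin_length_s, A1, n_frames, coverage`; timestamps
#' ISO 8601 in fixed UTC+1.
#'
#' @param series an `activity_series`.
#' @param path file path.
#' @return `path` (writer) or the parsed `activity_series` (reader).
#' @export
write_activity_csv <- function(series, path) {
  out <- data.frame(bin_start_iso = iso_stamp(as_motact_time(series$bin_start)),
                    bin_length_s = series$bin_length_s,
                    A1 = series$A1, n_frames = series$n_frames,
                    coverage = series$coverage)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_activity_csv
#' @export
read_activity_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bin_start_iso", "bin_length_s", "A1", "n_frames", "coverage")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("activity CSV missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(bin_start = as_motact_time(x$bin_start_iso),
                    bin_length_s = x$bin_length_s, A1 = x$A1,
                    n_frames = x$n_frames, coverage = x$coverage)
  class(out) <- c("activity_series", "data.frame")
  out
}
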