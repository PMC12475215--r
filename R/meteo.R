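# Station pressure ingestion: raw synoptic observations -> daily means p
# -> day-to-day changes delta_p (the biometeorological stimulus).

#' Read a station pressure table
#'
#' Parses a delimited text export of synoptic observations. Public-data
#' exports vary in dialect, so the delimiter, decimal mark and column names
#' are configurable. Rows with an unparseable date or pressure are skipped
#' with a message; pressures may be given in Pa and converted.
#'
#' @param path file path.
#' @param col_date name of the date column (`YYYY-MM-DD`, or anything
#'   `as.Date` accepts).
#' @param col_pressure name of the pressure column.
#' @param col_time optional name of a time-of-day column (kept, not required).
#' @param sep field delimiter.
#' @param dec decimal mark (`","` in many European exports).
#' @param unit `"hPa"` (default) or `"Pa"` (divided by 100).
#' @return data.frame of observations with columns `date`, `pressure_hpa`
#'   (and `time` when present).
#' @export
read_station_table <- function(path, col_date = "date", col_pressure = "pressure",
                               col_time = NULL, sep = ",", dec = ".",
                               unit = c("hPa", "Pa")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"")
  if (nrow(raw) == 0L) stop("empty station table: ", path)
  for (cn in c(col_date, col_pressure))
    if (!cn %in% names(raw)) stop("station table missing column: ", cn)
  dt <- suppressWarnings(as.Date(as.character(raw[[col_date]])))
  p <- suppressWarnings(as.numeric(raw[[col_pressure]]))
  bad <- is.na(dt) | is.na(p)
  if (any(bad))
    message(sprintf("read_station_table: skipped %d unparseable row(s)", sum(bad)))
  if (all(bad)) stop("no parseable observations in ", path)
  if (unit == "Pa") p <- p / 100
  out <- data.frame(date = dt[!bad], pressure_hpa = p[!bad])
  if (!is.null(col_time) && col_time %in% names(raw))
    out$time <- as.character(raw[[col_time]])[!bad]
  out
}

#' Daily mean pressure series
#'
#' Arithmetic mean of all available observations per calendar day (local
#' standard-time day boundary, consistent with the activity series). Values
#' outside the plausible station range 870--1085 hPa are flagged, not
#' dropped.
#'
#' @param obs data.frame with `date` and `pressure_hpa` (e.g. from
#'   [read_station_table()]).
#' @return A `pressure_series` data.frame: `date`, `p`, `n_obs`, `flagged`.
#' @export
daily_mean <- function(obs) {
  stopifnot(all(c("date", "pressure_hpa") %in% names(obs)), nrow(obs) >= 1L)
  sp <- split(obs$pressure_hpa, as.Date(obs$date))
  out <- data.frame(date = as.Date(names(sp)),
                    p = vapply(sp, mean, 0),
                    n_obs = vapply(sp, length, 0L))
  out$flagged <- out$p < 870 | out$p > 1085
  if (any(out$flagged))
    message(sprintf("daily_mean: %d day(s) outside the plausible 870-1085 hPa range",
                    sum(out$flagged)))
  rownames(out) <- NULL
  class(out) <- c("pressure_series", "data.frame")
  out
}

#' Day-to-day pressure change
#'
#' `delta_p[i] = p[i] - p[i-1]`, defined only where both calendar day `i`
#' and day `i-1` have a daily mean: the first day, and any day following a
#' gap, are missing.
#'
#' @param series a `pressure_series` from [daily_mean()].
#' @return data.frame with `date` and `delta_p` (NA where undefined).
#' @export
delta_series <- function(series) {
  stopifnot(all(c("date", "p") %in% names(series)), nrow(series) >= 2L)
  d <- as.Date(series$date)
  if (any(diff(as.numeric(d)) <= 0)) stop("dates must be strictly increasing")
  dp <- c(NA_real_, diff(series$p))
  gap <- c(TRUE, diff(as.numeric(d)) != 1)  # first day or day after a gap
  dp[gap] <- NA_real_
  data.frame(date = d, delta_p = dp)
}

#' Write the daily pressure CSV
#'
#' Schema: `date, p_hpa, delta_p_hpa, n_obs`.
#'
#' @param series a `pressure_series`.
#' @param path file path.
#' @export
write_pressure_csv <- function(series, path) {
  dp <- delta_series(series)
  utils::write.csv(
    data.frame(date = as.character(series$date), p_hpa = series$p,
               delta_p_hpa = dp$delta_p, n_obs = series$n_obs),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pressure_csv
#' @export
read_pressure_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "p_hpa")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("pressure CSV missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(date = as.Date(x$date), p = x$p_hpa,
                    n_obs = if ("n_obs" %in% names(x)) x$n_obs else NA_integer_)
  out$flagged <- out$p < 870 | out$p > 1085
  class(out) <- c("pressure_series", "data.frame")
  out
}
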