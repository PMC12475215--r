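# Base-graphics renderings of the study's standard displays: the actogram
# heatmap, the daily trend panel, period means +- SD, and the pressure
# panels.

#' Plot an actogram heatmap
#'
#' Day on the x axis, standard-time clock on the y axis, A1 as colour
#' (missing bins blank).
#'
#' @param hm an `activity_heatmap` from [build_heatmap()].
#' @param ... passed to [graphics::image()].
#' @export
plot_heatmap <- function(hm, ...) {
  stopifnot(inherits(hm, "activity_heatmap"))
  m <- hm$matrix
  graphics::image(x = seq_len(nrow(m)), y = seq_len(ncol(m)) / 6, z = m,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "day of study", ylab = sprintf("hour (%s)", hm$clock_basis),
                  main = "A1 activity actogram", ...)
  invisible(hm)
}

#' Plot daily A1 with per-period linear fits
#'
#' @param daily data.frame `date`, `A1`.
#' @param periods a [study_periods()].
#' @export
plot_daily_trends <- function(daily, periods = study_periods()) {
  d <- as.Date(daily$date)
  plot(d, daily$A1, type = "p", pch = 16, cex = 0.7,
       xlab = "date", ylab = "daily A1", main = "Daily A1 with period trends")
  graphics::abline(v = as.numeric(periods$prenatal[2L] + 1), lty = 2, col = "purple")
  graphics::abline(v = as.numeric(periods$dst[1L]), lty = 2, col = "blue")
  sub <- split_periods(daily, periods)
  for (nm in c("standard_time", "dst")) {
    s <- sub[[nm]]
    xi <- as.numeric(as.Date(s$date) - as.Date(s$date)[1L])
    tr <- linear_trend(xi, s$A1)
    yy <- attr(tr, "intercept") + tr$estimate * xi
    graphics::lines(as.Date(s$date), yy,
                    col = if (nm == "standard_time") "darkgreen" else "red", lwd = 2)
  }
  invisible(daily)
}

#' Plot period means with SD bars
#'
#' @param daily data.frame `date`, `A1`.
#' @param periods a [study_periods()].
#' @export
plot_period_means <- function(daily, periods = study_periods()) {
  sub <- split_periods(daily, periods)
  m <- c(mean(sub$prenatal$A1), mean(sub$postnatal$A1))
  s <- c(stats::sd(sub$prenatal$A1), stats::sd(sub$postnatal$A1))
  x <- c(1, 2)
  plot(x, m, xlim = c(0.5, 2.5), ylim = range(c(m - s, m + s)) * c(0.9, 1.1),
       pch = 15, cex = 1.5, xaxt = "n", xlab = "", ylab = "mean daily A1",
       main = "A1 before/after parturition (mean ± SD)")
  graphics::axis(1, at = x, labels = c("prenatal", "postnatal"))
  graphics::arrows(x, m - s, x, m + s, angle = 90, code = 3, length = 0.08)
  invisible(daily)
}

#' Plot A1 against pressure and its day-to-day change
#'
#' Two panels: daily A1 vs daily mean pressure p, and vs delta-p.
#'
#' @param daily data.frame `date`, `A1`.
#' @param pressure a `pressure_series`.
#' @export
plot_pressure_panels <- function(daily, pressure) {
  dp <- delta_series(pressure)
  i <- match(as.Date(daily$date), as.Date(pressure$date))
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(pressure$p[i], daily$A1, pch = 16, xlab = "daily mean p (hPa)",
       ylab = "daily A1", main = "A1 vs p")
  plot(dp$delta_p[i], daily$A1, pch = 16, xlab = expression(Delta * p ~ "(hPa)"),
       ylab = "daily A1", main = expression("A1 vs " * Delta * p))
  invisible(daily)
}
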