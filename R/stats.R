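# The study's statistical stage: period splitting, OLS trend with slope
# t-test, two-sample mean comparison (pooled / Welch), F test of variances,
# Pearson correlation, and the assembled study report.
#
# Conventions, fixed and documented: sample SDs (n-1) throughout this file
# (the background model uses the population convention instead); all tests
# two-sided; no multiple-testing correction.

#' Named study periods
#'
#' The default intervals reproduce the two-month observation campaign:
#' prenatal 2016-03-04..2016-03-13 and postnatal 2016-03-17..2016-04-29
#' around the parturition; standard_time 2016-03-01..2016-03-26 and dst
#' 2016-03-27..2016-04-29 around the civil clock change; with
#' 2016-03-14/15 (recording stoppage) excluded from every subset. After
#' exclusions the default sample sizes are 10/44/24/34 days.
#'
#' @param prenatal,postnatal,standard_time,dst length-2 `Date` vectors
#'   (inclusive start/end).
#' @param excluded_days `Date` vector removed from every analysis subset.
#' @return A `study_periods` list.
#' @export
study_periods <- function(prenatal = as.Date(c("2016-03-04", "2016-03-13")),
                          postnatal = as.Date(c("2016-03-17", "2016-04-29")),
                          standard_time = as.Date(c("2016-03-01", "2016-03-26")),
                          dst = as.Date(c("2016-03-27", "2016-04-29")),
                          excluded_days = as.Date(c("2016-03-14", "2016-03-15"))) {
  iv <- list(prenatal = as.Date(prenatal), postnatal = as.Date(postnatal),
             standard_time = as.Date(standard_time), dst = as.Date(dst))
  for (nm in names(iv))
    if (length(iv[[nm]]) != 2L || iv[[nm]][1L] > iv[[nm]][2L])
      stop("interval '", nm, "' must be an ordered start/end Date pair")
  if (iv$prenatal[2L] >= iv$postnatal[1L]) stop("prenatal/postnatal overlap")
  if (iv$standard_time[2L] >= iv$dst[1L]) stop("standard_time/dst overlap")
  structure(c(iv, list(excluded_days = as.Date(excluded_days))),
            class = "study_periods")
}

#' Split a daily activity series into the named period subsets
#'
#' @param daily data.frame with `date` and `A1` (e.g. from [daily_A1()]).
#' @param periods a [study_periods()] object.
#' @return Named list of data.frames (`prenatal`, `postnatal`,
#'   `standard_time`, `dst`), excluded days removed everywhere.
#' @export
split_periods <- function(daily, periods = study_periods()) {
  stopifnot(all(c("date", "A1") %in% names(daily)))
  d <- as.Date(daily$date)
  keep <- !(d %in% periods$excluded_days) & !is.na(daily$A1)
  out <- lapply(c("prenatal", "postnatal", "standard_time", "dst"), function(nm) {
    iv <- periods[[nm]]
    sub <- daily[keep & d >= iv[1L] & d <= iv[2L], , drop = FALSE]
    if (nrow(sub) == 0L) stop("period '", nm, "' selects no days")
    rownames(sub) <- NULL
    sub
  })
  names(out) <- c("prenatal", "postnatal", "standard_time", "dst")
  out
}

#' Container for a single statistical result
#'
#' @param estimate point estimate (slope, mean difference, F ratio, R, ...).
#' @param se standard error of the estimate (NA where not defined).
#' @param statistic test statistic.
#' @param df degrees of freedom (length 1 or 2).
#' @param p_value two-sided p-value.
#' @param test_name short identifier.
#' @param sides `"two-sided"` throughout this package.
#' @return A `stat_result` list.
#' @export
stat_result <- function(estimate, se, statistic, df, p_value, test_name,
                        sides = "two-sided") {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1),
            is.na(se) || se >= 0)
  structure(list(estimate = estimate, se = se, statistic = statistic, df = df,
                 p_value = p_value, test_name = test_name, sides = sides),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: estimate %.6g (se %.3g), %s = %.4g, df = %s, p = %.4g (%s)\n",
              x$test_name, x$estimate, x$se, sub("_.*", "", x$test_name),
              x$statistic, paste(signif(x$df, 6), collapse = ","),
              x$p_value, x$sides))
  invisible(x)
}

#' Ordinary least-squares trend with slope significance
#'
#' Fits `y = a + b x` by OLS and tests `b = 0` with the slope t-test:
#' `t = b / se(b)`, `df = n - 2`, two-sided p. A perfect fit (`se = 0`)
#' yields `p = 0` for a nonzero slope.
#'
#' @param x predictor (e.g. day index); must not be constant.
#' @param y response (e.g. daily A1); pairs with NA dropped.
#' @return A [stat_result()] with the slope as estimate; the intercept is
#'   attached as attribute `intercept`.
#' @export
linear_trend <- function(x, y) {
  ok <- !(is.na(x) | is.na(y))
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete points")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("degenerate predictor: all x equal")
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  rss <- sum((y - a - b * x)^2)
  se <- sqrt(rss / (n - 2L) / sxx)
  if (se > 0) {
    tt <- b / se
    p <- 2 * stats::pt(-abs(tt), df = n - 2L)
  } else {
    tt <- if (b == 0) 0 else sign(b) * Inf
    p <- if (b == 0) 1 else 0
  }
  out <- stat_result(b, se, tt, n - 2L, p, "t_slope")
  attr(out, "intercept") <- a
  out
}

# shared two-sample t core on summary statistics
t_core <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                   variant = c("auto", "pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(n_a >= 2L, n_b >= 2L, sd_a >= 0, sd_b >= 0)
  if (variant == "auto") {
    # pooled unless the F test rejects variance equality at alpha = 0.05
    variant <- if (sd_a > 0 && sd_b > 0 &&
                   f_core(sd_a^2, n_a, sd_b^2, n_b)$p < 0.05) "welch" else "pooled"
  }
  diff <- mean_a - mean_b
  if (sd_a == 0 && sd_b == 0) {
    if (diff == 0) {
      message("compare_means: both variances zero with equal means; p = 1 by convention")
      return(list(diff = 0, se = 0, t = 0, df = n_a + n_b - 2L, p = 1,
                  variant = variant))
    }
    return(list(diff = diff, se = 0, t = sign(diff) * Inf, df = n_a + n_b - 2L,
                p = 0, variant = variant))
  }
  if (variant == "pooled") {
    df <- n_a + n_b - 2L
    sp2 <- ((n_a - 1L) * sd_a^2 + (n_b - 1L) * sd_b^2) / df
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  } else {
    va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1L) + vb^2 / (n_b - 1L))
  }
  tt <- diff / se
  list(diff = diff, se = se, t = tt, df = df, p = 2 * stats::pt(-abs(tt), df),
       variant = variant)
}

f_core <- function(v_a, n_a, v_b, n_b) {
  # plain first-over-second ratio (so scaling sample a by c scales F by
  # c^2); two-sided p = 2 * min(tail areas), invariant under swapping
  f <- v_a / v_b
  d1 <- n_a - 1L; d2 <- n_b - 1L
  pr <- stats::pf(f, d1, d2)
  list(f = f, df = c(d1, d2), p = min(1, 2 * min(pr, 1 - pr)))
}

#' Two-sample comparison of means (Student's t)
#'
#' `variant = "pooled"` uses the classical equal-variance statistic with
#' `df = n_a + n_b - 2`; `"welch"` uses the unequal-variance statistic with
#' Welch–Satterthwaite df; `"auto"` (default) applies pooled unless an F
#' test rejects variance equality at alpha = 0.05.
#'
#' @param a,b numeric samples (`n >= 2` each, NAs dropped).
#' @param variant `"auto"`, `"pooled"` or `"welch"`.
#' @return A [stat_result()]; estimate is `mean(a) - mean(b)`.
#' @export
compare_means <- function(a, b, variant = c("auto", "pooled", "welch")) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  compare_means_summary(mean(a), stats::sd(a), length(a),
                        mean(b), stats::sd(b), length(b), variant)
}

#' @rdname compare_means
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b summary statistics of the two
#'   samples (sample SDs, n-1 convention).
#' @export
compare_means_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                                  variant = c("auto", "pooled", "welch")) {
  r <- t_core(mean_a, sd_a, n_a, mean_b, sd_b, n_b, variant)
  stat_result(r$diff, r$se, r$t, r$df, r$p, paste0("t_", r$variant))
}

#' F test comparing two variances
#'
#' Reports `F = s_a^2 / s_b^2` with df `(n_a - 1, n_b - 1)`; the two-sided
#' p (twice the smaller tail area) is invariant under swapping the samples.
#'
#' @param a,b numeric samples (`n >= 2`, at least one nonzero variance).
#' @return A [stat_result()]; estimate is the variance ratio.
#' @export
compare_variances <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) stop("both variances are zero")
  r <- f_core(va, length(a), vb, length(b))
  stat_result(r$f, NA_real_, r$f, r$df, r$p, "F_variance")
}

#' Pearson correlation with t-based significance
#'
#' Pairwise-complete: pairs with a missing value in either variable are
#' dropped. `t = R sqrt(n-2) / sqrt(1-R^2)`, `df = n-2`, two-sided p.
#'
#' @param x,y paired numeric vectors.
#' @return A [stat_result()]; estimate is `R`, with attribute `n` the number
#'   of complete pairs.
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !(is.na(x) | is.na(y))
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  sx <- x - mean(x); sy <- y - mean(y)
  den <- sqrt(sum(sx^2) * sum(sy^2))
  if (den == 0) stop("zero variance in x or y")
  r <- sum(sx * sy) / den
  if (abs(r) < 1) {
    tt <- r * sqrt(n - 2L) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(tt), df = n - 2L)
  } else {
    tt <- sign(r) * Inf; p <- 0
  }
  out <- stat_result(r, NA_real_, tt, n - 2L, p, "pearson")
  attr(out, "n") <- n
  out
}

stat_row <- function(res, test_name, period) {
  data.frame(test_name = test_name, period = period,
             estimate = res$estimate, se = res$se,
             statistic = res$statistic, df = res$df[1L],
             df2 = if (length(res$df) > 1L) res$df[2L] else NA_real_,
             p_value = res$p_value)
}

#' Run the full study analysis
#'
#' Assembles the study's seven results from a daily activity series and a
#' daily pressure series: OLS trends of daily A1 within the standard-time
#' and DST periods, the prenatal/postnatal mean comparison, the
#' standard-time/DST mean and variance comparisons, and Pearson correlations
#' of daily A1 with daily mean pressure `p` and with its day-to-day change
#' `delta_p`. Correlations use all non-excluded study days with
#' pairwise-complete deletion across the recording gap.
#'
#' @param activity daily data.frame with `date`, `A1`.
#' @param pressure a `pressure_series` (daily `date`, `p`).
#' @param periods a [study_periods()].
#' @param variant mean-comparison variant, see [compare_means()].
#' @return data.frame with one row per result: `test_name`, `period`,
#'   `estimate`, `se`, `statistic`, `df`, `df2`, `p_value`.
#' @export
run_study_analysis <- function(activity, pressure, periods = study_periods(),
                               variant = "auto") {
  stopifnot(all(c("date", "A1") %in% names(activity)),
            all(c("date", "p") %in% names(pressure)))
  act <- activity[!(as.Date(activity$date) %in% periods$excluded_days) &
                    !is.na(activity$A1), , drop = FALSE]
  missing_p <- setdiff(as.character(act$date), as.character(pressure$date))
  if (length(missing_p))
    stop("pressure series lacks study dates: ", paste(missing_p, collapse = ", "))
  sub <- split_periods(act, periods)

  trend_of <- function(s) {
    day_idx <- as.numeric(as.Date(s$date) - as.Date(s$date)[1L])
    linear_trend(day_idx, s$A1)
  }
  dp <- delta_series(pressure)
  i <- match(as.Date(act$date), as.Date(pressure$date))
  rows <- rbind(
    stat_row(trend_of(sub$standard_time), "trend_slope", "standard_time"),
    stat_row(trend_of(sub$dst), "trend_slope", "dst"),
    stat_row(compare_means(sub$prenatal$A1, sub$postnatal$A1, variant),
             "mean_diff", "prenatal_vs_postnatal"),
    stat_row(compare_means(sub$standard_time$A1, sub$dst$A1, variant),
             "mean_diff", "standard_time_vs_dst"),
    stat_row(compare_variances(sub$standard_time$A1, sub$dst$A1),
             "variance_ratio", "standard_time_vs_dst"),
    stat_row(pearson_corr(act$A1, pressure$p[i]), "pearson_R", "A1_vs_p"),
    stat_row(pearson_corr(act$A1, dp$delta_p[i]), "pearson_R", "A1_vs_delta_p"))
  rownames(rows) <- NULL
  rows
}

#' Write the flat study-results CSV
#'
#' @param results data.frame from [run_study_analysis()].
#' @param path file path.
#' @export
write_results_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
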