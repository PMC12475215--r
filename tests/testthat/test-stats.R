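# statistical stage: periods, trend, t / F / Pearson, assembled report

test_that("study_periods defaults carry the printed date ranges", {
  sp <- study_periods()
  expect_equal(as.numeric(sp$prenatal[2] - sp$prenatal[1]) + 1, 10)
  expect_equal(as.numeric(sp$postnatal[2] - sp$postnatal[1]) + 1, 44)
  expect_equal(length(sp$excluded_days), 2L)
  expect_error(study_periods(prenatal = as.Date(c("2016-03-20", "2016-03-25"))),
               "overlap")
})

test_that("split_periods removes excluded days and yields the printed sizes", {
  daily <- toy_daily()
  sub <- split_periods(daily)
  expect_equal(nrow(sub$prenatal), 10L)
  expect_equal(nrow(sub$postnatal), 44L)
  expect_equal(nrow(sub$standard_time), 24L)
  expect_equal(nrow(sub$dst), 34L)
  all_dates <- do.call(c, lapply(sub, function(s) as.Date(s$date)))
  expect_false(as.Date("2016-03-14") %in% all_dates)
  expect_false(as.Date("2016-03-15") %in% all_dates)

  few <- daily[as.Date(daily$date) > as.Date("2016-04-01"), ]
  expect_error(split_periods(few), "prenatal")
})

test_that("linear_trend matches lm() to 1e-10 and handles a perfect fit", {
  x <- 1:10; y <- 2 * x + 1
  tr <- linear_trend(x, y)
  expect_equal(tr$estimate, 2)
  expect_equal(tr$se, 0)
  expect_equal(tr$p_value, 0)

  set.seed(5)
  for (rep in 1:10) {
    x <- rnorm(30); y <- 0.3 * x + rnorm(30)
    tr <- linear_trend(x, y)
    ref <- summary(lm(y ~ x))$coefficients["x", ]
    expect_equal(tr$estimate, unname(ref["Estimate"]), tolerance = 1e-10)
    expect_equal(tr$se, unname(ref["Std. Error"]), tolerance = 1e-10)
    expect_equal(tr$p_value, unname(ref["Pr(>|t|)"]), tolerance = 1e-10)
  }
  expect_error(linear_trend(rep(1, 5), rnorm(5)), "degenerate")
})

test_that("compare_means matches t.test() to 1e-10 (pooled and Welch)", {
  set.seed(11)
  for (rep in 1:10) {
    a <- rnorm(12, 0, 1); b <- rnorm(20, 0.5, 1.7)
    pooled <- compare_means(a, b, "pooled")
    ref_p <- t.test(a, b, var.equal = TRUE)
    expect_equal(pooled$statistic, unname(ref_p$statistic), tolerance = 1e-10)
    expect_equal(pooled$p_value, ref_p$p.value, tolerance = 1e-10)
    welch <- compare_means(a, b, "welch")
    ref_w <- t.test(a, b)
    expect_equal(welch$statistic, unname(ref_w$statistic), tolerance = 1e-10)
    expect_equal(welch$df, unname(ref_w$parameter), tolerance = 1e-10)
    expect_equal(welch$p_value, ref_w$p.value, tolerance = 1e-10)
  }
})

test_that("compare_means degenerate and summary-consistency cases", {
  r <- compare_means(c(1, 2, 3), c(1, 2, 3), "pooled")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  expect_message(z <- compare_means_summary(5, 0, 4, 5, 0, 6, "pooled"),
                 "convention")
  expect_equal(z$p_value, 1)

  # hand-computed pooled 3+3 toy: a = 1,2,3 ; b = 4,6,8 ; diff = 2 - 6
  # sp2 = (2*1 + 2*4)/4 = 2.5 ; se = sqrt(2.5 * 2/3) ; t = -4/se
  r <- compare_means(1:3, c(4, 6, 8), "pooled")
  expect_equal(r$se, sqrt(2.5 * 2 / 3))
  expect_equal(r$statistic, -4 / sqrt(2.5 * 2 / 3))

  set.seed(2)
  a <- rnorm(10); b <- rnorm(15)
  raw <- compare_means(a, b, "pooled")
  summ <- compare_means_summary(mean(a), sd(a), 10, mean(b), sd(b), 15, "pooled")
  expect_identical(raw$statistic, summ$statistic)
  expect_identical(raw$p_value, summ$p_value)
})

test_that("compare_variances matches var.test() and is scale-equivariant", {
  r <- compare_variances(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$estimate, 1)
  expect_equal(r$p_value, 1)

  set.seed(13)
  for (rep in 1:10) {
    a <- rnorm(20, 0, 2); b <- rnorm(20)
    r <- compare_variances(a, b)
    ref <- var.test(a, b)
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
  }
  a <- rnorm(15); b <- rnorm(15)
  expect_equal(compare_variances(a * 3, b)$estimate /
                 compare_variances(a, b)$estimate,
               9, tolerance = 1e-10)
  expect_error(compare_variances(rep(1, 5), rep(2, 5)), "zero")
})

test_that("pearson_corr matches cor.test() with pairwise deletion", {
  expect_equal(pearson_corr(1:3, c(2, 4, 6))$estimate, 1)
  expect_equal(pearson_corr(1:3, c(3, 2, 1))$estimate, -1)

  set.seed(17)
  for (rep in 1:10) {
    x <- rnorm(40); y <- 0.3 * x + rnorm(40)
    x[sample(40, 5)] <- NA; y[sample(40, 5)] <- NA
    r <- pearson_corr(x, y)
    ok <- complete.cases(x, y)
    ref <- cor.test(x[ok], y[ok])
    expect_equal(r$estimate, unname(ref$estimate), tolerance = 1e-10)
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(r$df, unname(ref$parameter))
  }
  expect_error(pearson_corr(rep(1, 5), rnorm(5)), "variance")
})

test_that("pearson_corr is invariant under affine maps, sign follows slope", {
  set.seed(19)
  x <- rnorm(30); y <- rnorm(30)
  r0 <- pearson_corr(x, y)$estimate
  expect_equal(pearson_corr(2 * x + 5, y)$estimate, r0, tolerance = 1e-12)
  expect_equal(pearson_corr(x, -3 * y + 1)$estimate, -r0, tolerance = 1e-12)
})

test_that("run_study_analysis emits the seven named results on aligned dates", {
  daily <- toy_daily(seed = 4)
  ps <- simulate_pressure(daily$date, seed = 8)
  res <- run_study_analysis(daily, ps)
  expect_equal(nrow(res), 7L)
  expect_setequal(
    paste(res$test_name, res$period),
    c("trend_slope standard_time", "trend_slope dst",
      "mean_diff prenatal_vs_postnatal", "mean_diff standard_time_vs_dst",
      "variance_ratio standard_time_vs_dst",
      "pearson_R A1_vs_p", "pearson_R A1_vs_delta_p"))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # delta-p correlation: 57 complete pairs (58 study days minus 1 Mar)
  expect_equal(res$df[res$period == "A1_vs_delta_p"], 55)
  expect_equal(res$df[res$period == "A1_vs_p"], 56)

  expect_error(run_study_analysis(daily, ps[-10, ]), "lacks study dates")
})
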