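# synthetic generator: schedule construction, series simulation, rendering,
# AR(1) pressure, determinism

test_that("make_schedule gates activity between sunrise onset and rest time", {
  cfg <- schedule_config(start = "2016-03-01", end = "2016-03-03",
                         pressure_coupling = 0)
  sched <- make_schedule(cfg)
  expect_equal(nrow(sched), 3 * 144)
  expect_true(all(sched$p_active >= 0 & sched$p_active <= 1))
  # nothing before sunrise or from 17:00
  lt <- as.POSIXlt(sched$bin_start)
  minute <- lt$hour * 60 + lt$min
  expect_true(all(sched$p_active[minute >= 17 * 60] == 0))
  ev <- sunrise_sunset("2016-03-01", cfg$latitude, cfg$longitude, 1)
  day1 <- sched[sched$date == as.Date("2016-03-01"), ]
  expect_true(all(day1$p_active[minute[1:144] < ev$sunrise_min] == 0))

  zero <- make_schedule(schedule_config(start = "2016-03-01",
                                        end = "2016-03-02",
                                        baseline_active_prob = 0))
  expect_true(all(zero$p_active == 0))
})

test_that("activity onset moves earlier through a northern spring", {
  sched <- make_schedule(schedule_config())
  onset <- vapply(split(sched, sched$date), function(d) {
    lt <- as.POSIXlt(d$bin_start[d$p_active > 0][1])
    lt$hour * 60 + lt$min
  }, 0)
  expect_true(all(diff(onset) <= 0))
  expect_lt(onset[length(onset)], onset[1] - 60)  # > 1 h earlier by late April
})

test_that("calibrated schedule hits the emulation targets exactly", {
  cfg <- calibrate_schedule_config()
  gt <- attr(make_schedule(cfg), "ground_truth")$daily
  sp <- study_periods()
  pre <- gt$true_mean_A1[gt$date >= sp$prenatal[1] & gt$date <= sp$prenatal[2]]
  post <- gt$true_mean_A1[gt$date >= sp$postnatal[1] & gt$date <= sp$postnatal[2] &
                            !(gt$date %in% sp$excluded_days)]
  expect_equal(mean(pre), 0.0512, tolerance = 1e-4)
  expect_equal(mean(post), 0.0419, tolerance = 1e-4)
  dst <- gt[gt$date >= sp$dst[1] & gt$date <= sp$dst[2], ]
  sl <- linear_trend(as.numeric(dst$date - dst$date[1]), dst$true_mean_A1)
  expect_equal(sl$estimate, 2.57e-4, tolerance = 1e-2)
  # the step is a genuine drop across parturition
  expect_lt(mean(post), mean(pre))
})

test_that("simulate_A1_series: exact limit, determinism, binomial accuracy", {
  cfg <- schedule_config(start = "2016-03-01", end = "2016-03-02",
                         baseline_active_prob = 1, sunrise_onset_offset = -1440,
                         pressure_coupling = 0, post_shift_trend = 0)
  sched <- make_schedule(cfg)
  sched$p_active <- round(sched$p_active)  # p in {0, 1}
  sim <- simulate_A1_series(sched, noise_sd = 0, day_cv = 0, seed = 1)
  expect_equal(sim$bins$A1, sched$p_active)

  s1 <- simulate_A1_series(sched, seed = 99)
  s2 <- simulate_A1_series(sched, seed = 99)
  expect_identical(s1$bins$A1, s2$bins$A1)

  # per-bin mean over replicates within 3 binomial SEs in >= 99% of bins
  cfg2 <- schedule_config(start = "2016-03-05", end = "2016-03-06")
  sched2 <- make_schedule(cfg2)
  n <- 8400
  set.seed(123)
  reps <- replicate(200, simulate_A1_series(sched2, noise_sd = 0,
                                            day_cv = 0)$bins$A1)
  m <- rowMeans(reps)
  se <- sqrt(sched2$p_active * (1 - sched2$p_active) / n) / sqrt(200)
  inside <- abs(m - sched2$p_active) <= pmax(3 * se, 1e-12)
  expect_gte(mean(inside), 0.99)
})

test_that("render_frames: static when inactive, truth tracks the geometry", {
  cfg <- schedule_config(start = "2016-03-05", end = "2016-03-05")
  sched <- make_schedule(cfg)
  quiet <- sched[40, , drop = FALSE]; quiet$p_active <- 0
  rc <- render_config(noise_sd = 0)
  seg <- render_frames(quiet, rc, frames_per_bin = 10, seed = 2)
  for (i in 2:10)
    expect_identical(seg$series$frames[[i]], seg$series$frames[[1]])
  expect_true(all(seg$truth$changed_frac == 0))

  # one blob forced to move every frame: changed fraction ~ 2 x disc area
  busy <- quiet; busy$p_active <- 1
  seg1 <- render_frames(busy, rc, frames_per_bin = 30, n_blobs = 1, seed = 3)
  area <- sum(outer((-11):11, (-11):11,
                    function(dx, dy) dx^2 + dy^2 <= 11^2)) / (352 * 288)
  ch <- seg1$truth$changed_frac[-1]
  expect_true(all(ch > 0))
  expect_lt(abs(mean(ch) - 2 * area) / (2 * area), 0.25)

  # determinism
  sa <- render_frames(busy, rc, frames_per_bin = 5, seed = 7)
  sb <- render_frames(busy, rc, frames_per_bin = 5, seed = 7)
  expect_identical(sa$series$frames, sb$series$frames)

  expect_error(render_config(blob_radius = 200), "exceeds")
})

test_that("night bins render dimmer (IR palette)", {
  cfg <- schedule_config(start = "2016-03-05", end = "2016-03-05")
  sched <- make_schedule(cfg)
  night_bin <- sched[2, , drop = FALSE]    # 00:10, night
  day_bin <- sched[70, , drop = FALSE]     # 11:30, day
  rc <- render_config(noise_sd = 0)
  sn <- render_frames(night_bin, rc, frames_per_bin = 2, seed = 4)
  sd_ <- render_frames(day_bin, rc, frames_per_bin = 2, seed = 4)
  expect_lt(mean(sn$series$frames[[1]]), 0.6 * mean(sd_$series$frames[[1]]))
})

test_that("simulate_pressure: AR(1) stationary spread, determinism, limits", {
  const <- simulate_pressure(as.Date("2016-03-01") + 0:9, innovation_sd = 0,
                             seed = 1)
  expect_true(all(const$p == 985))
  expect_true(all(delta_series(const)$delta_p[-1] == 0))

  p1 <- simulate_pressure(as.Date("2016-03-01") + 0:30, seed = 5)
  p2 <- simulate_pressure(as.Date("2016-03-01") + 0:30, seed = 5)
  expect_identical(p1$p, p2$p)

  long <- simulate_pressure(as.Date("2000-01-01") + 0:4999, mean_hpa = 1000,
                            ar_coeff = 0.8, innovation_sd = 3, seed = 6)
  target <- 3 / sqrt(1 - 0.8^2)
  expect_lt(abs(sd(long$p) - target) / target, 0.15)

  expect_error(simulate_pressure(Sys.Date() + 0:3, ar_coeff = 1), "ar_coeff")
})

test_that("ground-truth round trip: injected effect signs are recovered", {
  cfg <- calibrate_schedule_config()
  dates <- seq(cfg$start, cfg$end, by = "day")
  set.seed(31)
  hits <- replicate(40, {
    ps <- simulate_pressure(dates)
    sched <- make_schedule(cfg, delta_p = delta_series(ps))
    sim <- simulate_A1_series(sched)
    res <- run_study_analysis(sim$daily, ps)
    c(step = res$estimate[res$period == "prenatal_vs_postnatal"] > 0,
      trend = res$estimate[res$test_name == "trend_slope" &
                             res$period == "dst"] > 0,
      coupling = res$estimate[res$period == "A1_vs_delta_p"] > 0)
  })
  expect_gte(mean(hits["step", ]), 0.9)
  expect_gte(mean(hits["trend", ]), 0.9)
  expect_gte(mean(hits["coupling", ]), 0.9)
})
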