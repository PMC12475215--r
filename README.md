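# motact

Video-based quantification of **group motor activity** in a fixed animal
enclosure, with the downstream chronobiology analysis that such recordings
feed: sunrise-linked activity onset, period comparisons around a birth and
around the daylight-saving clock change, and correlation of activity with
day-to-day atmospheric-pressure changes. It is aimed at researchers in zoo
animal welfare and chronobiology who have (or want to emulate) continuous
overhead camera footage of a small animal group.

## The statistic at its core

For each grayscale frame $x$ scored against the per-pixel mean $\mu$ and
standard deviation $\sigma$ of the preceding $W = 28$ frames (~2 s at
14 Hz), the one-dimensional Mahalanobis distance $d = |x - \mu| / \sigma$
marks pixels with $d > k$ (default $k = 3$) as *active*. The fraction of
active pixels is the frame's **A index**; within a bin (10 min or 1 day)

$$\mathrm{A1} = \frac{\#\{\text{frames with } A > 0.01\}}{\#\{\text{frames}\}}$$

is the fraction of time the group showed noticeable movement. Everything
downstream — actograms, OLS trends with slope t-tests, pooled/Welch mean
comparisons, F variance tests, Pearson correlations with pressure and
$\Delta p_i = p_i - p_{i-1}$ — operates on A1. A NOAA-method solar
calculator supplies sunrise/sunset for the activity gate, and a synthetic
generator (schedule → binomial A1 series, or schedule → rendered
moving-blob video) provides ground truth for validation. See the methods
vignette (`vignettes/motact-methods.Rmd`) for conventions and design
rationale.

## Worked example

Simulate the two-month study (ephemeris-gated activity with a parturition
step, post-clock-change drift, pressure coupling) and run the full
analysis:

```r
library(motact)
cfg   <- calibrate_schedule_config()          # world calibrated to the study's printed targets
ps    <- simulate_pressure(seq(cfg$start, cfg$end, by = "day"), seed = 1)
sched <- make_schedule(cfg, delta_p = delta_series(ps))
sim   <- simulate_A1_series(sched, seed = 2)
run_study_analysis(sim$daily, ps)
```

```
       test_name                period  estimate       se statistic   df df2  p_value
1    trend_slope         standard_time -0.000703 1.68e-04    -4.186 22.0  NA 3.83e-04
2    trend_slope                   dst  0.000305 7.95e-05     3.839 32.0  NA 5.49e-04
3      mean_diff prenatal_vs_postnatal  0.010206 1.86e-03     5.502 52.0  NA 1.16e-06
4      mean_diff  standard_time_vs_dst  0.003149 1.95e-03     1.613 36.2  NA 1.15e-01
5 variance_ratio  standard_time_vs_dst  2.417195       NA     2.417 23.0  33 2.01e-02
6      pearson_R               A1_vs_p  0.147556       NA     1.116 56.0  NA 2.69e-01
7      pearson_R         A1_vs_delta_p -0.024707       NA    -0.183 55.0  NA 8.55e-01
```

Reading it: daily A1 *falls* through the standard-time period (slope
−7.0e-4/day, p < 0.001 — the parturition drop lands inside this window),
*rises* again under DST (+3.1e-4/day), and the prenatal mean exceeds the
postnatal one by ~0.010 (t = 5.5, df = 52). In this particular seeded
world the pressure correlations are null draws — single 60-day studies
frequently miss a coupling of this size, which is exactly the kind of
statement the generator exists to make. Two directly recomputable study
numbers:

```r
sunrise_sunset("2016-03-01", 50.30, 18.95, 1)
#> 2016-03-01 @ (50.30, 18.95) UTC+1: sunrise 06:27, sunset 17:27, day 660 min

compare_means_summary(0.0512, 0.0053, 10, 0.0419, 0.0068, 44, "pooled")
#> t_pooled: estimate 0.0093 (se 0.0023), t = 4.044, df = 52, p = 0.0001747 (two-sided)
```

## Command line

```sh
Rscript inst/exec/motact simulate   --out runs/sim --seed 7
Rscript inst/exec/motact compute-a1 --input runs/sim/frames --out runs/a1
Rscript inst/exec/motact analyze    --a1 runs/sim/a1_10min.csv --pressure runs/sim/pressure.csv --out runs/res
Rscript inst/exec/motact ephemeris  --out sun.csv --start 2016-03-01 --end 2016-04-29
```

All subcommands accept `--config file.json` plus per-key flag overrides and
`--show-config`; every output directory gets a manifest with the seed and
config hash. Frames are read/written as plain-text PGM (PNG read if the
`png` package is installed), tables as CSV with documented headers.

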