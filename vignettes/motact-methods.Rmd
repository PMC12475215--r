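---
title: "Quantifying group motor activity from enclosure video: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying group motor activity from enclosure video: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motact)
```

## The measurement model

`motact` quantifies the motor activity of a *group* of animals filmed by a
fixed enclosure camera, without tracking individuals. The measurement chain
is deliberately simple and fully transparent:

1. **Grayscale.** Colour daylight frames and gray infrared night frames are
   put on one intensity scale; colour input is collapsed with the ITU-R
   BT.601 luma weights (0.299, 0.587, 0.114), rounded to integers.
2. **Background model.** Each frame is scored against the per-pixel mean
   and standard deviation of the *preceding* 28 frames (a sliding window of
   about 2 s at the nominal 14 Hz; the scored frame never contributes to
   its own background).
3. **Distance.** In one dimension the Mahalanobis distance reduces to
   `d = |x - mean| / sd`: the deviation of each pixel in background-SD
   units.
4. **Mask and A index.** Pixels with `d > k` (default `k = 3`, the 3-sigma
   rule) are "active"; the **A index** of a frame is the fraction of active
   pixels, in `[0, 1]`.
5. **A1 index.** Within a time bin (10 minutes for actograms, one day for
   trend analyses), **A1** is the fraction of frames whose A index strictly
   exceeds `a_threshold = 0.01`. A1 is therefore "the fraction of time the
   group was noticeably moving".

### Numerical conventions that matter

* **Population SD in the background model** (divide by `W = 28`), with a
  floor of `sd_floor = 2` intensity levels so that perfectly static pixels
  (whose empirical SD collapses to zero under 8-bit quantisation) cannot
  blow the distance up. The statistics module, by contrast, uses sample
  SDs (`n - 1`) throughout; both conventions are fixed and tested.
* **Strict inequalities at both thresholds** (`d > k`, `A > 0.01`): a value
  exactly at a threshold does not count.
* **Warm-up**: the first `W` frames yield no A sample (missing, not zero).
* **Coverage**: a bin whose frame count falls below 50% of `fps x
  bin_length` is reported missing (`NA`), never zero; empty bins inside the
  covered span likewise.
* **Clock**: all internal timestamps live on fixed local standard time
  (UTC+1). Civil daylight-saving labels are display-only; actogram columns
  are always winter-clock columns. (On systems without a tz database the
  package falls back to parsing fixed-offset zone names; see `R/zzz.R`.)

### A property of this detector worth knowing

Under the sliding-window background model, a *sustained* whole-frame change
does not keep every pixel active: the window variance absorbs it. For an
alternating full-inversion video the per-pixel distance is exactly 1
(deviation 127.5 over SD 127.5), independent of amplitude — so "full change
implies A = 1" holds for any `k < 1` and provably cannot hold for `k >= 1`.
What the default `k = 3` detects is *fresh* change against a recently
stable background, which is precisely what animal movement looks like. The
test suite pins both facts (and an echo effect: a blob that moves after a
long rest leaves its vacated pixels active for a couple of frames, until
the window catches up).

## Ephemeris

Sunrise and sunset come from the standard NOAA solar-position method:
Julian century, solar mean anomaly and ecliptic longitude, declination and
equation of time, then the hour angle at zenith 90.833 degrees (0.833
degrees of refraction plus the solar half-disc). Declination and the
equation of time are evaluated at solar noon and refined once at the
provisional event time; results are rounded to the nearest minute, matching
the web calculator's display. Polar-circle dates raise an error rather than
pretending. The implementation agrees with an independent altitude-crossing
oracle within 3 minutes for latitudes up to 60 degrees and reproduces the
study's four printed sun events within the +-4 minutes that within-city
coordinate uncertainty allows (the site is taken as 50.30 N, 18.95 E).

## Pressure

Daily mean station pressure `p` is the arithmetic mean of all available
observations of a calendar day (the exports this is designed for do not
state which synoptic hours the original analysis used, so all observations
are used); `delta_p[i] = p[i] - p[i-1]` is defined only where both days
have a mean — the first day and any day after a gap are missing. Values
outside 870–1085 hPa are flagged, not dropped.

## The statistical stage

The analysis report contains exactly seven results, mirroring the study
design: OLS trend slopes of daily A1 (with slope t-tests, `df = n - 2`)
within the standard-time and DST periods; the prenatal/postnatal mean
comparison; the standard-time/DST mean and variance comparisons; and
Pearson correlations of daily A1 with `p` and with `delta_p`. Conventions:

* two-sided p-values everywhere (the original reporting does not state
  sidedness); no multiple-testing correction;
* mean comparisons default to pooled Student's t, switching to Welch when
  an F test rejects variance equality at alpha = 0.05 (both variants are
  always available directly);
* `F = s_a^2 / s_b^2` with `p` twice the smaller tail area (swap-invariant,
  identical to `var.test`);
* correlations use pairwise-complete deletion across the recording gap;
  with the full study range this yields 57 complete pairs for `delta_p`
  (58 analysis days minus the first day, whose `delta_p` is undefined);
* the default period table — prenatal 2016-03-04..03-13 (10 days),
  postnatal 03-17..04-29 (44), standard time 03-01..03-26 (24 after
  exclusions), DST 03-27..04-29 (34), excluded 03-14/15 — is data, not
  code, and can be overridden.

## The synthetic world

No recordings of the original study are deposited, so the package carries a
generator whose outputs have known ground truth at every stage.

**Schedule.** For each 10-minute bin the true probability that the group is
noticeably active is

```
p = baseline x gate x step^(date >= parturition)
      x (1 + trend x days_since_dst) x (1 + coupling x delta_p)
```

clamped to `[0, 1]`. The gate opens at sunrise + 5 min (the observed onset
follows dawn) and closes at 17:00 standard time (the species' rest onset;
also lights-off). Defaults state the emulated study: 1 Mar–29 Apr 2016,
parturition 14 Mar, clock change 27 Mar, pressure coupling 0.008 per hPa.

**Calibration.** Because the gate lengthens through a northern spring and
the drift acts multiplicatively, the *nominal* step and trend parameters do
not equal the *realized* period means and slope. `calibrate_schedule_config()`
solves — deterministically, from the ephemeris alone — for the baseline,
step and drift that make the generated world match its observable targets:
prenatal mean daily A1 0.0512, postnatal 0.0419, DST-period slope
+2.57e-4/day. The raw step parameter comes out near 0.71 rather than the
naive 0.0419/0.0512 = 0.82: the behavioural suppression must overcome the
photoperiod growth. This is a statement about the world being emulated, not
a tuning knob, and it is fixed before any test sees data.

**Series simulation.** A1 is a per-bin fraction of threshold exceedances,
so each bin draws `Binomial(8400, p)/8400` (8400 = 14 Hz x 600 s), plus
clamped Gaussian observation noise (`noise_sd = 0.005`). Within-day
binomial noise at that frame count is far too small to explain the
day-to-day spread of daily A1, so a shared per-day multiplicative lognormal
effect is added, with CV 0.10 identified from the prenatal window of the
emulated study (SD/mean = 0.0053/0.0512 = 0.104) — the only period free of
step, drift and gate confounds. The postnatal spread then *emerges* from
the day effect plus the trend and gate variation, close to the 0.0068
printed there.

**Rendering.** Frames are a seeded coarse-grained background texture plus
nine disc "animals" (ten from the parturition date) of radius 11 px at
352 x 288 — about 25 cm at this enclosure-to-camera scale, so one group
move changes roughly 3% of the frame, comfortably above the 1% A
threshold. In an active frame every blob takes one step of its own
diameter plus one (so old and new discs are disjoint) in a uniform random
direction, reflecting off the walls; in inactive frames everything
freezes. Night bins are rendered at half gain on a gray palette (IR);
Gaussian sensor noise (SD 1 intensity level) is added last. The truth
table records each frame's activity state and the exact changed-pixel
fraction between clean frames.

What the renderer does *not* model — photorealism, occlusion, identity,
keeper and visitor events — is deliberate: a green end-to-end test
establishes that the measurement chain recovers a known activity schedule
from moving-texture video, not that it would survive every artefact of a
zoo pavilion.

**Scale.** A full day of continuous 14 Hz video is ~1.2 million frames,
far beyond a desk-scale test budget. The end-to-end check therefore
renders a contiguous 10-second segment per 10-minute bin (28 warm-up + 140
scored frames) and estimates each bin's A1 from it — an unbiased sample of
the bin — with the schedule correlation still computed across all 144 bins
of a day. `simulate_video_A1()` streams bin by bin so memory stays bounded;
rendering full bins is supported by configuration.

**Pressure.** Daily station pressure is a stationary AR(1) around 985 hPa
(a mid-altitude station level) with `ar = 0.8` and innovation SD 3 hPa,
giving a synoptic-scale stationary SD of 5 hPa and a `delta_p` SD near
3 hPa.

## Known limitations

* The original pixel threshold `k` and SD convention are not published;
  `k = 3`, population SD and `sd_floor = 2` are declared package defaults,
  and every bound/monotonicity property is tested across `k`.
* The within-day activity profile beyond "onset follows sunrise, rest from
  17:00" is a declared simplification (a flat gate).
* The echo effect above means video-derived A1 overestimates the per-frame
  activity probability by a bin-constant factor; correlation-based
  recovery is unaffected, absolute recovery is calibrated only at the
  series (binomial) level.
* The ephemeris handles neither polar latitudes nor twilight phases, by
  design.
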