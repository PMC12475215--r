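Package: motact
Title: Group Motor Activity Quantification from Enclosure Video
Version: 1.0.0
Authors@R:
    person("motact", "developers", email = "motact@example.org", role = c("aut", "cre"))
Description: Quantifies the motor activity of a group of animals from fixed-camera
    video of an enclosure. Each frame is scored against a sliding-window background
    model by a per-pixel one-dimensional Mahalanobis distance; the fraction of
    "active" pixels gives the per-frame A index and the fraction of frames whose A
    index exceeds a noise threshold gives the binned A1 activity index. Downstream
    chronobiology tooling covers sunrise/sunset ephemerides (NOAA solar algorithm),
    daily atmospheric-pressure means and day-to-day changes, period-wise linear
    trends, mean/variance comparisons and Pearson correlations, plus a synthetic
    study generator (schedule-driven activity, rendered moving-blob video, AR(1)
    station pressure) with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
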