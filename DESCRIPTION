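Package: pamscape
Title: Passive Acoustic Monitoring Soundscapes: Presence Time Series,
    Audible-Area Estimation and Community Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing duty-cycled passive acoustic monitoring
    (PAM) deployments in seasonally ice-covered seas. Converts manual
    call-annotation logs into hourly, daily and monthly acoustic-presence
    time series; computes calibrated Welch ambient-noise spectra from
    hydrophone recordings; models range-dependent transmission loss with a
    simplified two-dimensional ray tracer and grids it around the recorder;
    derives daily audible-area masks (signal-to-noise ratio above
    threshold) and ice-constrained environmental covariates (sea-ice
    proportion, mean SST and SSH, bathymetric coefficient of variation);
    and fits the community statistics from first principles: constrained
    correspondence analysis, variance-inflation-factor screening, and
    quasi-binomial penalized thin-plate-spline presence models with REML
    smoothness selection. A seeded synthetic-scene generator (bathymetry,
    ice and temperature fields, guild-structured call schedules, calibrated
    audio) makes the whole pipeline testable end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    geosphere,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv,
    vegan,
    car
Config/testthat/edition: 3
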