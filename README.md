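# pamscape

Analysis tools for duty-cycled passive acoustic monitoring (PAM) of
marine mammals in seasonally ice-covered seas — from manual
call-annotation logs to acoustic-presence time series, detection-range
("audible area") estimation, ice-constrained environmental covariates,
and community statistics. It is written for bioacousticians and
quantitative ecologists working with single moored recorders (e.g. an
AURAL-class instrument on a polar shelf) who want the whole chain —
signal level, propagation, and ecology — in one tested, reproducible
pipeline.

## What it computes

**Presence series.** Annotation logs (Raven/Ishmael-style selection
tables) plus deployment metadata become hourly binary presence per
species (an hour counts if it holds at least one confident, non-chorus
call), daily percentages `100 * positive hours / recorded hours`, and
monthly positive-hour totals, with duty-cycle audits against a time
mark.

**Soundscape.** Calibrated Welch ambient-noise spectra per recording
(counts → µPa through sensitivity/gain/ADC, Hamming window, 50 %
overlap, density scaling) and noise levels NL at each species'
call frequency.

**Audible area.** A simplified two-dimensional ray tracer (range-marched
fan, refraction by the sound-speed profile, lossy Rayleigh-style bottom,
incoherent flux accumulation) replaces an external beam tracer; slices
around the recorder are gridded in polar coordinates to a lat-lon mesh.
The audible area for a species with source level SL is

```
SNR = SL − TL − NL ,   audible area = { cells : SNR > 5 dB } .
```

**Constrained covariates.** Inside each daily mask: the proportion of
area with sea-ice concentration above 30 % (SIC), mean SST and SSH over
the open-water part, and the coefficient of variation of depth
(`vBAT = sd(depth)/mean(depth)`), plus mean SIC within 25 and 100 km of
the recorder.

**Community models, from first principles.** Variance inflation factors
`VIF_j = 1/(1 − R²_j)`; constrained correspondence analysis (CCA) of the
day × species positive-hour matrix on month, SST, SSH, vBAT and SIC via
chi-square standardization, row-weighted projection and SVD; and
quasi-binomial penalized-spline additive models of daily presence
proportions — low-rank thin-plate-type bases, penalized IRLS with a
logit link, REML-type smoothing-parameter selection, dispersion from
Pearson residuals — with the classic S3 modelling interface
(`pgam()`, `summary`, `predict`, `plot`, `spline_effect`).

A seeded synthetic-scene generator (shelf/trough/basin bathymetry,
seasonal logistic ice front with an optional El Niño-like anomaly year,
guild-structured Bernoulli call schedules, calibrated synthetic audio)
makes every stage testable end to end without external data.

## Worked example

```r
library(pamscape)
res <- run_scene_pipeline(config = scene_config(seed = 1,
                                                year_mode = "anomaly"))
res$cca
#> Constrained correspondence analysis
#> Total inertia: 0.5709; constrained: 0.5099 (89.3%)
#> Constrained eigenvalues:
#>   CCA1   CCA2   CCA3   CCA4   CCA5
#> 0.4644 0.0443 0.0011 0.0001 0.0000
round(res$vif, 2)
#>  month    sst    ssh   vbat    sic
#>   8.27   6.18   3.17 284.15 296.21
str(res$guild_contrast[c("separation", "sic_points_to_ice_affiliated")])
#> List of 2
#>  $ separation                  : num 1.84
#>  $ sic_points_to_ice_affiliated: logi TRUE
res$gams$AMW
#> Quasi-binomial penalized-spline additive model (logit link)
#> cbind(pos, rec - pos) ~ s(sic) + s(sst) + s(ssh) + s(vbat) + s(month)
#> Smooth terms: s(sic) edf=2.30, s(sst) edf=1.99, s(ssh) edf=1.00,
#>   s(vbat) edf=3.67, s(month) edf=1.00
#> n = 184, dispersion = 1.039, deviance explained = 87.4%
```

The first CCA axis carries 78–89 % of the constrained inertia and
separates the ice-affiliated cluster (minke whale, seals) from the
ice-avoiding one (fin, humpback), with the SIC arrow pointing at the
ice-affiliated side — the seasonal guild turnover the pipeline is built
to resolve. The very large vBAT/SIC inflation factors are a property of
this synthetic scene (ice covering the shelf drives both covariates);
field data sit much lower. The minke-whale spline model recovers an
increasing SIC effect with near-binomial dispersion.

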