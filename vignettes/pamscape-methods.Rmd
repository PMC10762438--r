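---
title: "Methods: from detection logs to audible areas and community models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from detection logs to audible areas and community models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pamscape analyses a single duty-cycled moored recorder in a seasonally
ice-covered sea. This vignette explains the models and procedures the
package implements, the assumptions behind them, the parameters that
matter, and the choices made where the design was genuinely open. The
worked numbers quoted in the README are produced by the test suite and
by `scripts/acceptance.R`; nothing here claims results beyond what those
compute.

## 1. Presence time series

Manual annotation logs are treated as ground truth about what an analyst
heard, not about how many animals called. An hour scores presence for a
species if at least one *confident*, non-chorus annotation of that
species falls in the hour's recording; all further detections in the
hour are ignored (presence-only data). Uncertain annotations are dropped
at ingest — they reflect calls that could not be confidently assigned —
but `drop_uncertain = FALSE` retains them for sensitivity analyses.
Chorus-band annotations (the continuous low-frequency band produced by
distant baleen whales) are always excluded, because the target quantity
is local habitat use.

Three aggregation choices are deliberate:

* **Daily denominator.** The daily percentage uses the hours *actually
  recorded* that day, not 24. Deployments start and end mid-day; a
  fixed-24 denominator would silently deflate the first and last days.
* **Hour bins** are half-open `[h, h+1)` UTC, aligned to the start of
  the duty cycle; an hour counts as covered only when its full ON window
  lies inside the deployment.
* **Monthly totals** distinguish a recorded month with zero detections
  (0) from a month with no recording at all (`NA`) — the distinction
  between absence of evidence and absence of recordings.

The duty-cycle audit (`duty_cycle_audit()`) counts, per species, files
in which every detection falls after a time mark (default 8 min): these
are the files a shorter duty cycle would have missed. A file with any
pre-mark detection counts as before-mark.

`n_recording_days()` is the inclusive day count of a recording period —
the sample size of any daily-response model fitted to a deployment. The
shipped example metadata (10 February to 12 October) spans 245 days.

## 2. Calibration and noise spectra

The calibration chain is multiplicative in linear units:
`µPa = counts · (V_fs / 2^(bits−1)) / (10^(gain/20) · 10^(sens/20))`,
with defaults sensitivity −165 dB re 1 V/µPa, gain 16 dB, 16-bit ADC and
a 5 V full scale. The full-scale voltage of autonomous recorders is
rarely reported; 5 V is a typical value and configurable. The chain
round-trips to machine precision, and a 1 V-RMS tone at the ADC maps to
a received level of 149 dB re 1 µPa — a closed-form check the tests
assert.

Ambient noise is estimated by Welch's method on the first 8 minutes of
each recording (the ON window of an 8/60 duty cycle): Hamming window,
50 % segment overlap, per-segment mean removal, one-sided *density*
scaling so that integrating the estimate over frequency recovers the
signal variance. The default FFT size is 65536 (0.5 Hz bins at
32 768 Hz); tests use smaller sizes for speed, which changes resolution
but not calibration. The noise level NL at a species frequency is the
*single nearest bin* (ties to the lower bin), because detection-range
estimation needs the density at the call frequency; a band average
(`band > 0`) is available. Whether a band level would be more
appropriate than a spectral density is genuinely ambiguous; density is
the default and both are supported.

## 3. Transmission loss: a deliberate simplification

The audible-area model needs transmission loss TL on a ~500 km disc at
tens-of-metres depth resolution, for several frequencies and many days.
The package uses an *incoherent ray-flux* model instead of a coherent
beam tracer:

* a fan of rays (default 181 launch angles in ±80°) leaves the recorder
  depth — by acoustic reciprocity the resulting field is the loss from
  any point of the slice to the recorder;
* rays refract through the piecewise-linear sound-speed profile
  (`dθ/dr = −(1/c)·dc/dz`, exact for range-marching), reflect specularly
  and losslessly at the surface, and reflect at the bottom with a
  Rayleigh coefficient for the lossless sediment contrast (default
  density 1200 kg m⁻³, speed 1450 m s⁻¹) *plus* an additive
  sediment-absorption term per interaction (default 1 dB per wavelength,
  scaled by the sine of the grazing angle, since steeper rays penetrate
  further). The additive form keeps per-bounce loss monotone in the
  absorption parameter; embedding absorption in a complex wavenumber
  does not, near the intromission angle of a slow sediment;
* each ray deposits `w · Δs` into every range-depth cell it crosses
  (`w` its remaining solid-angle-weighted power, `Δs` its path length in
  the cell); cell intensity is that flux divided by the annulus volume
  `2π r Δr Δz`, and `TL = −10 log₁₀(I / I_ref(1 m))`.

The estimator is exact in the two limits that matter for audible areas:
spherical spreading (`20 log₁₀ r`) in a free field and cylindrical
spreading (10 dB/decade) in a lossless waveguide; the tests assert both
(±1.5 dB over 100 m–10 km, slope in [9, 12] dB/decade over 50–400 km)
and mean reciprocity error below 0.5 dB. What it gives up is phase: no
convergence zones, no modal interference, no coherent surface-image
effect. For daily masks thresholded at a 5 dB SNR these interference
details average out; that is the modelling bet, stated openly.

Numerical details: rays steeper than 88° or exceeding the bottom-bounce
budget (default 20) are dropped — the budget approximates the death of
steep multipath in a lossy waveguide, and idealized lossless tests raise
it. A steep ray can cross both boundaries within one range step; the
marcher folds the end position into the water column and counts the
boundary crossings, so no energy piles up at either boundary. Cells no
ray reaches carry an infinite-TL sentinel, which propagates to
`SNR = −∞` (never audible). Thorp volume absorption is included by
default; it is negligible below 200 Hz.

Slices every 1° (configurable; the synthetic pipeline uses 15°) are
gridded by bilinear interpolation in polar (bearing, range) coordinates,
with wrap-around in bearing; a finite neighbour wins over a sentinel so
coastline edges do not bleed infinities into open water. Mesh cells
beyond the slice length, or on land, get the sentinel. Sound speed uses
the Mackenzie nine-term formula; out-of-domain inputs extrapolate with a
warning.

One printed bottom-density value in the literature this design follows
is dimensionally inconsistent (a surface density); the package treats it
as 1200 kg m⁻³, configurable in `bottom_spec()`.

## 4. Audible areas and constrained covariates

`SNR = SL − TL − NL` cellwise; the audible mask is the *strict*
inequality `SNR > 5 dB`, and its area sums latitude-dependent cell
areas. Per-recording masks of one day are averaged and binarized at
occupancy ≥ 0.5 — the averaging rule is not dictated by anything
external, so the continuous occupancy field is retained alongside.

Covariates inside a mask follow three rules: (i) the SIC proportion is
the area-weighted fraction of the mask with SIC strictly above 30 %
(area-weighted rather than cell-counted, since cells shrink poleward);
(ii) cells above 30 % SIC are removed before computing mean SST, mean
SSH and vBAT — the assumption is that detectable, vocalizing animals
occupy the open-water part of the audible area; (iii)
`vBAT = sd(depth)/mean(depth)` with the *population* standard deviation
(the cells are the full population of the mask, not a sample). An
all-ice or empty mask yields `NA` covariates; days with any missing
covariate are dropped listwise before modelling, with a reported count.
Ice advance can only shrink the eligible set, so NA propagation is
monotone in ice cover. Fields on foreign grids are co-registered by
nearest-neighbour resampling (bilinear available).

The pipeline extracts one *shared* covariate set from a mid-band
reference run (50 Hz, 170 dB source level) rather than per-species sets:
the covariates describe the environment around the recorder, and a
mid-band mask keeps them comparable across species; per-species masks
remain available through the same functions.

## 5. Community statistics

All three statistics are implemented from their definitions; `vegan`,
`car` and `mgcv` appear only in the test suite as independent
cross-checks.

**VIF.** `1/(1 − R²)` from regressing each predictor on the others with
intercept; exact collinearity reports `Inf` with a warning rather than a
crash, so a screening loop can drop the offender.

**CCA.** With `P` the community matrix scaled to unit total and `r`,
`c` its margins, the chi-square residual matrix is
`Q = D_r^{−1/2}(P − rcᵀ)D_c^{−1/2}`; `Q`'s rows are projected onto the
predictor space by `r`-weighted least squares and the projection is
decomposed by SVD. Constrained eigenvalues are squared singular values;
the projection residual carries the unconstrained ones, and the two sets
sum to the total inertia `ΣQ²` exactly (orthogonality of the
projection) — asserted at 1e−8 alongside equivalence with a brute-force
eigen-decomposition oracle on random tables. Scores use a
species-focused (type-2) scaling; biplot arrows are `r`-weighted
correlations of predictors with the constrained site scores. All-zero
rows or columns are a hard error naming the offender (the chi-square
metric is undefined for them); month enters as a numeric predictor, as
a single seasonal direction in the ordination.

**Quasi-binomial penalized-spline models.** `pgam()` follows the classic
R modelling idiom: a formula with `s()` smooth markers, a classed fit,
and `summary`/`coef`/`predict`/`residuals`/`plot` methods. Internals:

* *Basis.* Each smooth gets the 1-D thin-plate radial basis
  `|x − x_k|³/12` on up to `max(20, 2k)` quantile knots, eigen-truncated
  to rank `k` (default 10), with the null-space constraint absorbed and
  the penalty reparameterized to the identity on the `k − 2` penalized
  columns. The linear trend is an unpenalized column, so the reported
  *nonlinear* edf of a smooth is 0 when it shrinks to a straight line —
  that is the number to read when judging whether a term is effectively
  linear.
* *Fitting.* Penalized IRLS with a logit link; covariates are
  standardized internally, which makes fits invariant to affine
  rescaling of predictors (asserted at 1e−6).
* *Smoothness.* Outer optimization (golden-section for one smooth,
  Nelder–Mead otherwise) of a REML-type criterion of the converged
  working model, with the scale profiled out and log-smoothing
  parameters boxed at ±18 via a soft barrier; a saturated or constant
  response drives the criterion flat toward the upper bound, i.e.
  maximal smoothing, which is the sensible degenerate behaviour.
* *Dispersion* is the Pearson statistic over `n − edf`, the
  quasi-likelihood estimate; binomially simulated data land near 1.
* *Intervals* come from the Bayesian posterior covariance
  `(XᵀWX + S_λ)⁻¹ φ̂`. `spline_effect()` reports the contrast
  `f(x) − f(x̄)`, so the effect at the covariate mean is exactly zero
  and its interval has zero width there — the centering is part of the
  estimand, not a cosmetic shift.
* *Selection.* `pgam_select()` does backward elimination by quasi-AIC
  (`deviance/φ + 2·edf`, with φ fixed at the full model's), mirroring
  "keep only terms that improve the fit". Non-convergence of the IRLS is
  an error with the iteration count; a very large linear predictor
  triggers a separation warning.

The model matches an established GAM implementation to correlation
> 0.999 in fitted values on shared simulations, but exact numerical
replication of another package is a non-goal. Models carry no random
effects or autocorrelation term by default; daily presence proportions
with trial weights equal to recorded hours are the response, and an
observation-level AR structure can be explored by the user downstream.

## 6. The synthetic scene: what it does and does not emulate

The generator defines the study conditions under which everything is
tested: a 7° × 6° domain at 0.25°, 10 February–12 October (245 days), a
southern shelf (~320 m) cut by a trough at the recorder (~660 m) falling
to a ~3500 m northern basin; SST as a meridional gradient plus a
seasonal sinusoid (amplitude 1.6 °C, peak mid-February, floor −1.9 °C)
with smooth noise; sea ice as a 1-D logistic front in latitude whose
position follows day of year, advancing north through austral winter —
the simplest field that reproduces a moving ice edge. Anomaly mode
delays the seasonal ice cycle by 30 days and raises summer SST by
0.7 °C, an El Niño-like year. Six species span three guilds with
hourly calling probability `logit p = a + b·SIC + c·SST + d·SSH` at the
recorder cell: ice-avoiding (fin, humpback; `b < 0`), ice-affiliated
(minke, leopard and crabeater seals; `b > 0`) and a resident (blue
whale; `b = 0`). Coefficients were chosen once to give realistic
presence rates (roughly 35–65 % of hours) and clear guild contrast;
`a = −Inf` is the documented "never vocalizes" sentinel.

Because presence is driven by the *recorder-cell* covariate, the
pipeline's mask-constrained covariate extraction is a nontrivial
estimator of the generator's truth — the tests require correlation
above 0.95 with the true SST on ice-free days, rather than identity.

What the scene does not contain: ocean dynamics, krill, animal movement,
realistic call structure (calls are Hann-windowed tones — downstream
stages only need energy at a known frequency), interference-driven TL
fine structure, or recorder self-noise. Passing tests therefore show
that the *estimators* are correct and coherently coupled, not that the
ecological effect sizes transfer to field data. One visible consequence:
ice covering the shelf drives SIC and vBAT together, so the synthetic
scene's inflation factors are far larger than the 1–3 range typical of
field covariates.

## 7. Problem sizes and degenerate inputs

The shipped tests and acceptance script run at desk scale by choice:
free-field propagation on a 10 km slice at 10 m steps with 16 001 rays,
waveguides at 500 m steps with 721–2001 rays, Welch checks at 4 kHz
sampling, spline recovery at n = 400 days × 24 trials (25 replicates in
the acceptance script, since single-draw pointwise coverage over a
correlated grid is nearly all-or-nothing), CCA oracles on 100 random
5 × 8 tables, and the full pipeline on the default scene with 24 slices.

Degenerate inputs are handled explicitly rather than by accident: empty
annotation logs (all-zero presence), out-of-window annotations (rejected
with a report), masks with no eligible cells (NA covariates), a
constant CCA predictor (zero constrained inertia), zero-rank projections,
ADC clipping (error), recordings shorter than the Welch segment (used
whole, with a warning), and slices truncated by land.

## 8. Known limitations

Incoherent propagation (no convergence zones or modal structure); a
single sound-speed snapshot per TL run rather than per-day fields; WAV
I/O limited to mono 16-bit PCM; grids serialized as self-describing
plain text rather than a binary raster format; GeoJSON export of masks
is not provided (boolean grids serve the same purpose downstream); and
the GAM's REML criterion is a working-model approximation — adequate for
smoothing-parameter selection, not a likelihood for model comparison
across families.
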