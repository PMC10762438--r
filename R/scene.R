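## Synthetic-scene generator: a seeded, fully reproducible stand-in for a
## high-latitude PAM study system (shelf/trough/basin bathymetry, seasonal
## ice and temperature fields, guild-structured call schedules).

#' Default species registry for the synthetic scene
#'
#' One row per species: acoustic parameters (call frequency and source
#' level, dB re 1 uPa at 1 m) and logit-scale coefficients linking hourly
#' calling probability to the environmental covariates at the recorder
#' cell: `logit p = a + b * SIC + c * SST + d * SSH` with SIC as a
#' proportion (0-1), SST in deg C and SSH in m.
#'
#' The default community spans the three guilds of a Southern Ocean
#' krill-predator assemblage: ice-avoiding migrants (fin and humpback
#' whales) whose calling declines with ice cover, ice-affiliated species
#' (minke whale, leopard and crabeater seals) whose calling rises with it,
#' and a resident (blue whale) insensitive to the covariates. Frequencies
#' and source levels for the four baleen whales follow values typical of
#' the literature (20 Hz / 189 dB for the large balaenopterids, 100 Hz /
#' 163 dB for minke, 200 Hz / 163 dB for humpback).
#'
#' @return data.frame with columns `species`, `guild`, `freq_hz`, `sl_db`,
#'   `a`, `b_sic`, `c_sst`, `d_ssh`.
#' @export
species_registry <- function() {
  data.frame(
    species = c("FW", "ABW", "HW", "AMW", "LS", "CS"),
    guild = c("ice-avoiding", "resident", "ice-avoiding",
              "ice-affiliated", "ice-affiliated", "ice-affiliated"),
    freq_hz = c(20, 20, 200, 100, 300, 350),
    sl_db = c(189, 189, 163, 163, 153, 153),
    a = c(-0.5, 0.5, -1.0, -2.5, -3.0, -3.5),
    b_sic = c(-4, 0, -4, 4, 5, 5),
    c_sst = c(1.2, 0, 1.5, -0.5, 0, 0),
    d_ssh = c(0, 0, -2, 2, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Synthetic-scene configuration
#'
#' Bundles everything the scene generator needs: spatial extent and
#' resolution, the date range, the climate mode (`"normal"` or
#' `"anomaly"`, the latter an El Nino-like year with delayed ice advance
#' and warmer summer surface water), the species registry and the recorder
#' position. Defaults describe a South-Orkney-like scene: a 7 x 6 degree
#' domain with a southern shelf, a trough at the recorder and a deep
#' northern basin, observed 10 February - 12 October.
#'
#' @param seed integer RNG seed; every generator output is a pure function
#'   of the config (same seed, same scene).
#' @param lat_range,lon_range extent in degrees (south/west negative).
#' @param res grid resolution in degrees.
#' @param dates vector of consecutive `Date`s the daily fields cover.
#' @param year_mode `"normal"` or `"anomaly"`.
#' @param registry species registry, see [species_registry()].
#' @param recorder `c(lat, lon)` of the moored recorder.
#' @param flat_depth if non-`NULL`, bathymetry is this constant depth (m);
#'   used for idealized propagation tests.
#' @param sst_summer_offset summer SST increase (deg C) in anomaly mode.
#' @param ice_delay_days delay (days) of the seasonal ice advance in
#'   anomaly mode.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(seed = 1L,
                         lat_range = c(-63, -56),
                         lon_range = c(-49, -43),
                         res = 0.25,
                         dates = seq(as.Date("2017-02-10"),
                                     as.Date("2017-10-12"), by = "day"),
                         year_mode = c("normal", "anomaly"),
                         registry = species_registry(),
                         recorder = c(-60.405, -45.972),
                         flat_depth = NULL,
                         sst_summer_offset = 0.7,
                         ice_delay_days = 30) {
  year_mode <- match.arg(year_mode)
  if (diff(lat_range) <= 0 || diff(lon_range) <= 0)
    stopf("degenerate extent: lat_range/lon_range must be increasing")
  if (res <= 0) stopf("resolution must be > 0")
  if (!length(dates)) stopf("empty date range")
  need <- c("species", "guild", "freq_hz", "sl_db", "a", "b_sic", "c_sst",
            "d_ssh")
  miss <- setdiff(need, names(registry))
  if (length(miss)) stopf("registry lacks columns: %s",
                          paste(miss, collapse = ", "))
  co <- as.matrix(registry[, c("b_sic", "c_sst", "d_ssh")])
  if (any(!is.finite(co))) stopf("registry slope coefficients must be finite")
  ## a = -Inf is the documented "never vocalizes" sentinel
  if (any(is.nan(registry$a)) || any(registry$a == Inf))
    stopf("registry intercepts must be finite or -Inf")
  if (recorder[1] < lat_range[1] || recorder[1] > lat_range[2] ||
      recorder[2] < lon_range[1] || recorder[2] > lon_range[2])
    stopf("recorder must lie inside the extent")
  structure(list(
    seed = as.integer(seed), lat_range = lat_range, lon_range = lon_range,
    res = res, dates = dates, year_mode = year_mode, registry = registry,
    recorder = recorder, flat_depth = flat_depth,
    sst_summer_offset = sst_summer_offset,
    ice_delay_days = ice_delay_days
  ), class = "scene_config")
}

scene_axes <- function(config) {
  list(
    lat = seq(config$lat_range[1] + config$res / 2, config$lat_range[2],
              by = config$res),
    lon = seq(config$lon_range[1] + config$res / 2, config$lon_range[2],
              by = config$res)
  )
}

## 2-D moving-average smoother (reflective edges) used for field noise
smooth2d <- function(m, k = 5) {
  if (nrow(m) < k || ncol(m) < k) return(m)
  ker <- rep(1 / k, k)
  pad <- (k - 1) / 2
  sm_rows <- function(x) {
    n <- nrow(x)
    xp <- rbind(x[pad:1, , drop = FALSE], x,
                x[n:(n - pad + 1), , drop = FALSE])
    f <- apply(xp, 2, function(col) stats::filter(col, ker, sides = 2))
    f[(pad + 1):(pad + n), , drop = FALSE]
  }
  t(sm_rows(t(sm_rows(m))))
}

#' Synthetic bathymetry
#'
#' Deterministic (seeded) depth grid with the three structural elements
#' the covariate extraction cares about: a shallow shelf band in the
#' south (~300-500 m), a trough cutting the shelf at the recorder
#' longitude, and a deep basin (~3000-4000 m) in the north. Depth is
#' positive down, in metres.
#'
#' @param config a [scene_config()].
#' @return a [pam_grid] of depths (m).
#' @export
make_bathymetry <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  ax <- scene_axes(config)
  if (!is.null(config$flat_depth)) {
    return(pam_grid(ax$lat, ax$lon,
                    matrix(config$flat_depth, length(ax$lat), length(ax$lon))))
  }
  nlat <- length(ax$lat); nlon <- length(ax$lon)
  ramp <- plogis((ax$lat - (-59)) / 0.5)        # shelf -> basin transition
  base <- 320 + (3500 - 320) * ramp
  z <- matrix(base, nlat, nlon)
  ## trough: deepens the shelf near the recorder longitude
  south_w <- plogis(((-59.5) - ax$lat) / 0.3)
  trough <- outer(south_w, exp(-((ax$lon - config$recorder[2]) / 0.5)^2)) * 160
  z <- z + trough
  z <- z + with_seed(config$seed + 101L, {
    20 * smooth2d(matrix(rnorm(nlat * nlon), nlat, nlon))
  })
  pam_grid(ax$lat, ax$lon, pmax(z, 50))
}

day_of_year <- function(d) as.POSIXlt(d)$yday + 1

#' Synthetic daily environmental fields
#'
#' Generates co-registered daily SST (deg C), SSH anomaly (m) and sea-ice
#' concentration (percent, 0-100) grids plus the static bathymetry. SST is
#' a meridional gradient plus a seasonal sinusoid and smooth noise; SIC is
#' a one-dimensional logistic ice front whose latitude follows day of
#' year, advancing north through austral winter. In anomaly mode the
#' seasonal ice cycle is delayed by `ice_delay_days` and summer SST raised
#' by `sst_summer_offset` (default 0.7 deg C), emulating an El Nino-like
#' year.
#'
#' @param config a [scene_config()].
#' @return object of class `env_fields`: `lat`, `lon`, `dates`, `bathy`
#'   ([pam_grid]), and arrays `sst`, `ssh`, `sic` of dim
#'   `[lat, lon, day]`.
#' @export
make_env_fields <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  ax <- scene_axes(config)
  nlat <- length(ax$lat); nlon <- length(ax$lon)
  nd <- length(config$dates)
  doy <- day_of_year(config$dates)
  anomaly <- config$year_mode == "anomaly"

  noise <- with_seed(config$seed + 202L, {
    spat <- smooth2d(matrix(rnorm(nlat * nlon), nlat, nlon))
    ar1 <- function(n, phi = 0.85, sd = 1) {
      x <- numeric(n); e <- rnorm(n, sd = sd)
      x[1] <- e[1]
      for (t in seq_len(n)[-1]) x[t] <- phi * x[t - 1] + e[t]
      x
    }
    list(spat = spat, t_sst = ar1(nd, sd = 0.25), t_ssh = ar1(nd, sd = 0.02),
         t_front = ar1(nd, sd = 0.06))
  })

  season <- cos(2 * pi * (doy - 45) / 365.25)   # peaks mid-February
  summer_w <- pmax(season, 0)
  sst_off <- if (anomaly) config$sst_summer_offset * summer_w else
    numeric(nd)
  m_lat <- -0.2 + 0.35 * (ax$lat - config$lat_range[1])

  ## ice front latitude: southernmost in summer, far north by late winter
  adv_doy <- if (anomaly) doy - config$ice_delay_days else doy
  s_ice <- (1 + cos(2 * pi * (adv_doy - 260) / 365.25)) / 2
  front <- -64.5 + 8 * s_ice + noise$t_front

  sst <- array(0, c(nlat, nlon, nd))
  ssh <- array(0, c(nlat, nlon, nd))
  sic <- array(0, c(nlat, nlon, nd))
  for (t in seq_len(nd)) {
    f <- m_lat + 1.6 * season[t] + sst_off[t] + noise$t_sst[t]
    sst[, , t] <- pmax(matrix(f, nlat, nlon) + 0.4 * noise$spat, -1.9)
    ssh[, , t] <- 0.05 * cos(2 * pi * (doy[t] - 100) / 365.25) +
      noise$t_ssh[t] + 0.05 * noise$spat +
      (if (anomaly) 0.08 * summer_w[t] else 0)
    conc <- 100 * plogis((front[t] - ax$lat) / 0.4)
    sic[, , t] <- pmin(pmax(matrix(conc, nlat, nlon), 0), 100)
  }
  structure(list(lat = ax$lat, lon = ax$lon, dates = config$dates,
                 bathy = make_bathymetry(config),
                 sst = sst, ssh = ssh, sic = sic, config = config),
            class = "env_fields")
}

## index of the grid cell containing the recorder
recorder_cell <- function(env, config = env$config) {
  c(which.min(abs(env$lat - config$recorder[1])),
    which.min(abs(env$lon - config$recorder[2])))
}

#' Daily covariates at the recorder cell
#'
#' The generator's ground truth: SIC proportion (0-1), SST and SSH at the
#' single grid cell containing the recorder, one row per day. Downstream
#' covariate extraction (audible-area constrained means) is an estimator
#' of these values.
#'
#' @param env an `env_fields` object.
#' @return data.frame with `date`, `sic_prop`, `sst`, `ssh`.
#' @export
recorder_covariates <- function(env) {
  ij <- recorder_cell(env)
  data.frame(
    date = env$dates,
    sic_prop = env$sic[ij[1], ij[2], ] / 100,
    sst = env$sst[ij[1], ij[2], ],
    ssh = env$ssh[ij[1], ij[2], ]
  )
}

#' Hourly calling schedule per species
#'
#' Draws hourly Bernoulli presence for each registry species with
#' `logit p = a + b * SIC + c * SST + d * SSH`, covariates taken at the
#' recorder cell (daily resolution). Seeded and reproducible.
#'
#' @param config a [scene_config()].
#' @param env matching `env_fields` (must cover `config$dates`).
#' @return object of class `call_schedule`: `time` (hourly POSIXct UTC),
#'   `presence` (0/1 matrix hours x species), `daily` covariate truth from
#'   [recorder_covariates()], `p_daily` (matrix days x species).
#' @export
make_call_schedule <- function(config, env) {
  stopifnot(inherits(config, "scene_config"), inherits(env, "env_fields"))
  if (!all(config$dates %in% env$dates))
    stopf("env fields do not cover the configured date range")
  reg <- config$registry
  cov <- recorder_covariates(env)
  cov <- cov[match(config$dates, env$dates), ]
  eta <- outer(rep(1, nrow(cov)), reg$a) +
    cbind(cov$sic_prop, cov$sst, cov$ssh) %*%
      t(as.matrix(reg[, c("b_sic", "c_sst", "d_ssh")]))
  p <- plogis(eta)                       # days x species
  time <- seq(as.POSIXct(paste(config$dates[1], "00:00:00"), tz = "UTC"),
              by = "hour", length.out = 24 * length(config$dates))
  day_idx <- rep(seq_along(config$dates), each = 24)
  pres <- with_seed(config$seed + 303L, {
    matrix(rbinom(length(time) * nrow(reg), 1, p[day_idx, ]),
           nrow = length(time), ncol = nrow(reg))
  })
  colnames(pres) <- reg$species
  colnames(p) <- reg$species
  structure(list(time = time, presence = pres, daily = cov, p_daily = p,
                 registry = reg),
            class = "call_schedule")
}

#' Annotation log implied by a calling schedule
#'
#' Pipeline plumbing: converts a generated schedule into the selection
#' table an analyst would have produced, one confident annotation per
#' species-positive hour, placed uniformly within the duty-cycle ON
#' window of that hour. Only hours inside the deployment are emitted.
#'
#' @param schedule a `call_schedule`.
#' @param deployment a [deployment_spec()].
#' @param seed RNG seed for the within-file placement.
#' @return data.frame in the annotation-log dialect of
#'   [read_annotations()].
#' @export
schedule_to_annotations <- function(schedule, deployment, seed = 1L) {
  stopifnot(inherits(schedule, "call_schedule"))
  hrs <- deployment_hours(deployment)
  keep <- schedule$time %in% hrs
  tm <- schedule$time[keep]
  pres <- schedule$presence[keep, , drop = FALSE]
  reg <- schedule$registry
  idx <- which(pres == 1, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(file = character(), start_s = numeric(),
                      end_s = numeric(), low_hz = numeric(),
                      high_hz = numeric(), species = character(),
                      certainty = character(), chorus = logical()))
  }
  on_s <- deployment$duty_on * 60
  start <- with_seed(seed + 404L, runif(nrow(idx), 0, max(on_s - 3, 1)))
  sp <- reg$species[idx[, 2]]
  f <- reg$freq_hz[idx[, 2]]
  data.frame(
    file = format(tm[idx[, 1]], "%Y%m%dT%H%M%S", tz = "UTC"),
    start_s = start, end_s = start + 2,
    low_hz = 0.8 * f, high_hz = 1.2 * f,
    species = sp, certainty = "confident", chorus = FALSE,
    stringsAsFactors = FALSE
  )
}
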