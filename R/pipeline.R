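## End-to-end synthetic-scene pipeline: generator -> annotation log ->
## presence series -> noise spectra -> TL -> daily audible-area
## covariates -> community statistics.

#' Run the full pipeline on a synthetic scene
#'
#' Generates a scene (fields + call schedules), converts the schedule
#' into an annotation log and runs it through every analysis stage:
#' hourly/daily presence, one synthetic calibrated recording per day with
#' its Welch noise level, ray-traced transmission loss gridded around
#' the recorder, daily audible-area masks and ice-constrained
#' covariates, variance inflation factors, and a constrained
#' correspondence analysis of the day x species presence matrix against
#' month, SST, SSH, vBAT and SIC. Optionally fits presence splines for
#' selected species.
#'
#' The shared covariate set is extracted from a mid-band reference
#' audible area (`ref_freq`, `ref_sl`), one TL run reused for all days;
#' only the daily noise level and ice state move the mask from day to
#' day.
#'
#' @param config a [scene_config()]; default: the standard scene in
#'   anomaly mode (two guilds, El Nino-like year).
#' @param seed seed used when `config` is `NULL` and for the recording
#'   noise.
#' @param bearing_step slice spacing, degrees.
#' @param slice_km,range_step slice length (km) and node spacing (m).
#' @param ref_freq,ref_sl reference frequency (Hz) and source level (dB)
#'   of the shared audible-area run.
#' @param n_rays ray-fan size per slice.
#' @param gam_species species to fit presence splines for (`NULL` =
#'   none).
#' @param quiet suppress progress messages.
#' @return list: `config`, `env`, `schedule`, `deployment`,
#'   `annotations`, `hourly`, `daily`, `community` (day x species
#'   matrix), `noise` (daily NL), `tl` (`tl_grid`), `covariates` (daily
#'   data.frame), `vif`, `cca` (a `pam_cca`), `guild_contrast`, `gams`.
#' @export
run_scene_pipeline <- function(config = NULL, seed = 1L,
                               bearing_step = 15, slice_km = 200,
                               range_step = 500, ref_freq = 50,
                               ref_sl = 170, n_rays = 121,
                               gam_species = c("AMW", "FW"),
                               quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  if (is.null(config)) config <- scene_config(seed = seed,
                                              year_mode = "anomaly")
  say("generating fields and schedules ...")
  env <- make_env_fields(config)
  schedule <- make_call_schedule(config, env)
  deployment <- deployment_spec(
    paste(min(config$dates), "00:00:00"),
    paste(max(config$dates) + 1, "00:00:00"),
    duty_on = 8, fs = 32768,
    lat = config$recorder[1], lon = config$recorder[2])
  annotations <- schedule_to_annotations(schedule, deployment,
                                         seed = config$seed)
  hp <- hourly_presence(annotations, deployment,
                        species = config$registry$species)
  dp <- daily_presence(hp)
  Y <- community_matrix(dp)

  say("daily ambient noise ...")
  truth <- schedule$daily
  nd <- length(config$dates)
  nl_base <- with_seed(config$seed + 606L,
                       63 - 8 * truth$sic_prop + rnorm(nd, sd = 1))
  nl <- vapply(seq_len(nd), function(t) {
    wav <- synth_recording(character(), config$registry,
                           noise_psd_db = nl_base[t],
                           duration_s = 20, fs = 2048,
                           seed = config$seed + 7000L + t)
    psd <- welch_psd(wav, nfft = 512, segment_s = 20)
    noise_at_frequency(psd, ref_freq)
  }, numeric(1))

  say("transmission loss (%d slices at %g Hz) ...",
      length(seq(0, 360 - bearing_step, by = bearing_step)), ref_freq)
  sst_feb <- pam_grid(env$lat, env$lon, env$sst[, , 1])
  slices <- lapply(seq(0, 360 - bearing_step, by = bearing_step),
                   function(b) {
    se <- extract_slice(env$bathy, config$recorder, b,
                        length_km = slice_km, range_step = range_step,
                        sst = sst_feb)
    trace_tl(se, ref_freq, receiver_depth = min(280, se$depth[1] - 10),
             n_rays = n_rays)
  })
  tl <- grid_tl(slices, config$recorder,
                mesh = list(lat = env$lat, lon = env$lon),
                bathy = env$bathy)

  say("daily audible areas and constrained covariates ...")
  areas <- cell_areas_km2(env$lat, env$lon)
  cov <- do.call(rbind, lapply(seq_len(nd), function(t) {
    sg <- snr_grid(tl, ref_sl, nl[t])
    mask <- audible_mask(sg, threshold = 5, areas = areas)
    cs <- constrained_stats(mask, env$sic[, , t], env$sst[, , t],
                            env$ssh[, , t], env$bathy$z)
    cs$sic25 <- radius_sic(pam_grid(env$lat, env$lon, env$sic[, , t]),
                           config$recorder, 25)
    cs$sic100 <- radius_sic(pam_grid(env$lat, env$lon, env$sic[, , t]),
                            config$recorder, 100)
    cs
  }))
  cov <- cbind(data.frame(date = config$dates,
                          month = as.integer(format(config$dates, "%m")),
                          nl = nl), cov)

  say("community statistics ...")
  X <- data.frame(month = cov$month, sst = cov$sst_mean,
                  ssh = cov$ssh_mean, vbat = cov$vbat,
                  sic = cov$sic_prop)
  keep <- complete.cases(X) & rowSums(Y) > 0 &
    as.character(cov$date) %in% rownames(Y)
  Yk <- Y[as.character(cov$date)[keep], , drop = FALSE]
  Yk <- Yk[, colSums(Yk) > 0, drop = FALSE]
  Xk <- X[keep, , drop = FALSE]
  vifs <- vif(Xk)
  cca <- cca_fit(Yk, Xk)

  ## guild contrast on axis 1: do ice-affiliated and ice-avoiding species
  ## separate, and does the SIC arrow point at the ice-affiliated side?
  reg <- config$registry
  g <- reg$guild[match(rownames(cca$species_scores), reg$species)]
  ax1 <- cca$species_scores[, 1]
  mean_aff <- mean(ax1[g == "ice-affiliated"])
  mean_avd <- mean(ax1[g == "ice-avoiding"])
  sic_arrow <- cca$biplot["sic", 1]
  contrast <- list(
    mean_axis1_ice_affiliated = mean_aff,
    mean_axis1_ice_avoiding = mean_avd,
    separation = abs(mean_aff - mean_avd),
    sic_arrow_axis1 = sic_arrow,
    sic_points_to_ice_affiliated =
      sign(sic_arrow) == sign(mean_aff - mean_avd),
    guilds_fully_separated =
      max(ax1[g == "ice-affiliated"]) < min(ax1[g == "ice-avoiding"]) ||
      min(ax1[g == "ice-affiliated"]) > max(ax1[g == "ice-avoiding"])
  )

  gams <- list()
  for (sp in intersect(gam_species %||% character(), colnames(Yk))) {
    dat <- data.frame(pos = Yk[, sp],
                      rec = dp$recorded_hours[match(rownames(Yk),
                                                    as.character(dp$date))],
                      Xk)
    gams[[sp]] <- pgam(cbind(pos, rec - pos) ~ s(sic) + s(sst) + s(ssh) +
                         s(vbat) + s(month), data = dat)
  }

  list(config = config, env = env, schedule = schedule,
       deployment = deployment, annotations = annotations, hourly = hp,
       daily = dp, community = Y, noise = data.frame(date = config$dates,
                                                     nl = nl),
       tl = tl, covariates = cov, vif = vifs, cca = cca,
       guild_contrast = contrast, gams = gams)
}
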