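## Audible-area masks (SNR > threshold) and the spatially constrained
## environmental covariates extracted inside them.

## coerce a covariate field onto the mask mesh: pam_grid -> nearest-
## neighbour (or bilinear) resample; bare matrix -> must match dims
as_field <- function(x, lat, lon, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  if (inherits(x, "pam_grid")) {
    if (length(x$lat) == length(lat) && length(x$lon) == length(lon) &&
        max(abs(x$lat - lat)) < 1e-9 && max(abs(x$lon - lon)) < 1e-9)
      return(x$z)
    if (method == "nearest") {
      i <- nearest_idx(x$lat, lat); j <- nearest_idx(x$lon, lon)
      return(x$z[i, j, drop = FALSE])
    }
    return(matrix(bilinear(x, rep(lat, times = length(lon)),
                           rep(lon, each = length(lat))),
                  nrow = length(lat)))
  }
  x <- as.matrix(x)
  if (nrow(x) != length(lat) || ncol(x) != length(lon))
    stopf("field is %d x %d but the mask mesh is %d x %d",
          nrow(x), ncol(x), length(lat), length(lon))
  x
}

#' Signal-to-noise ratio grid
#'
#' `SNR = SL - TL - NL` elementwise: source level minus modelled
#' transmission loss minus the measured noise level at the call
#' frequency. Unreachable cells (infinite TL) get `-Inf`.
#'
#' @param tl a `tl_grid`.
#' @param sl source level, dB re 1 uPa at 1 m.
#' @param nl noise level, dB re 1 uPa^2/Hz (scalar).
#' @return object of class `snr_grid`: `lat`, `lon`, `snr` matrix.
#' @export
snr_grid <- function(tl, sl, nl) {
  stopifnot(inherits(tl, "tl_grid"))
  snr <- sl - tl$tl - nl
  snr[!is.finite(tl$tl)] <- -Inf
  structure(list(lat = tl$lat, lon = tl$lon, snr = snr, freq = tl$freq,
                 sl = sl, nl = nl),
            class = "snr_grid")
}

#' Audible-area mask
#'
#' Cells where the SNR strictly exceeds the detection threshold
#' (default 5 dB), with the area summed from latitude-dependent cell
#' areas.
#'
#' @param snr an `snr_grid`.
#' @param threshold dB (strict inequality).
#' @param areas optional cell-area matrix (km^2); default
#'   [cell_areas_km2()] on the mesh.
#' @return object of class `audible_mask`: `lat`, `lon`, logical `mask`,
#'   `area_km2`, `occupancy` (here 0/1).
#' @export
audible_mask <- function(snr, threshold = 5, areas = NULL) {
  stopifnot(inherits(snr, "snr_grid"))
  if (!is.finite(threshold)) stopf("threshold must be finite")
  if (is.null(areas)) areas <- cell_areas_km2(snr$lat, snr$lon)
  m <- is.finite(snr$snr) & snr$snr > threshold
  structure(list(lat = snr$lat, lon = snr$lon, mask = m,
                 occupancy = m * 1, area_km2 = sum(areas[m]),
                 areas = areas, freq = snr$freq),
            class = "audible_mask")
}

#' @export
print.audible_mask <- function(x, ...) {
  cat(sprintf("<audible_mask> %d / %d cells, %.0f km^2\n",
              sum(x$mask), length(x$mask), x$area_km2))
  invisible(x)
}

#' Daily mask from per-recording masks
#'
#' Averages the boolean masks of one day's recordings: a cell is in the
#' daily audible area when it was audible in at least half the
#' recordings (occupancy >= 0.5). The continuous occupancy field is
#' retained alongside the binarized mask.
#'
#' @param masks list of `audible_mask` objects on a common mesh.
#' @return an `audible_mask` with `occupancy` the recording-mean.
#' @export
daily_mask <- function(masks) {
  if (!length(masks)) stopf("need at least one recording mask")
  stopifnot(all(vapply(masks, inherits, logical(1), "audible_mask")))
  occ <- Reduce(`+`, lapply(masks, function(m) m$mask * 1)) / length(masks)
  m1 <- masks[[1]]
  m <- occ >= 0.5
  structure(list(lat = m1$lat, lon = m1$lon, mask = m, occupancy = occ,
                 area_km2 = sum(m1$areas[m]), areas = m1$areas,
                 freq = m1$freq),
            class = "audible_mask")
}

#' Sea-ice proportion of the audible area
#'
#' Area-weighted proportion of the mask classified ice-covered, a cell
#' counting as ice-covered when its SIC strictly exceeds 30 percent.
#' `NA` for an empty mask.
#'
#' @param mask an `audible_mask`.
#' @param sic SIC field in percent (matrix on the mask mesh or
#'   [pam_grid], resampled nearest-neighbour).
#' @param ice_threshold percent (default 30, strict).
#' @return proportion in `[0, 1]`, or `NA`.
#' @export
sic_proportion <- function(mask, sic, ice_threshold = 30) {
  stopifnot(inherits(mask, "audible_mask"))
  s <- as_field(sic, mask$lat, mask$lon)
  if (!any(mask$mask)) return(NA_real_)
  a <- mask$areas[mask$mask]
  sum(a[s[mask$mask] > ice_threshold]) / sum(a)
}

#' Ice-constrained covariates inside the audible area
#'
#' Statistics over the eligible cells: inside the audible mask and not
#' ice-covered (SIC <= 30 percent), mirroring the assumption that
#' detectable animals sit in the open-water part of the audible area.
#' Returns the daily mean SST and SSH, the coefficient of variation of
#' depth (`vbat = sd(depth) / mean(depth)`, population sd), the SIC
#' proportion of the full mask, and the mask area. All statistics are
#' `NA` when no cell is eligible.
#'
#' @param mask an `audible_mask`.
#' @param sic,sst,ssh,bathy covariate fields (matrix on the mask mesh or
#'   [pam_grid]).
#' @param ice_threshold percent (default 30).
#' @return one-row data.frame: `sic_prop`, `sst_mean`, `ssh_mean`,
#'   `vbat`, `area_km2`, `n_cells`.
#' @export
constrained_stats <- function(mask, sic, sst, ssh, bathy,
                              ice_threshold = 30) {
  stopifnot(inherits(mask, "audible_mask"))
  s <- as_field(sic, mask$lat, mask$lon)
  elig <- mask$mask & s <= ice_threshold
  out <- data.frame(sic_prop = sic_proportion(mask, s, ice_threshold),
                    sst_mean = NA_real_, ssh_mean = NA_real_,
                    vbat = NA_real_, area_km2 = mask$area_km2,
                    n_cells = sum(elig))
  if (!any(elig)) return(out)
  dep <- as_field(bathy, mask$lat, mask$lon)[elig]
  psd <- function(x) sqrt(mean((x - mean(x))^2))   # population sd
  out$sst_mean <- mean(as_field(sst, mask$lat, mask$lon)[elig])
  out$ssh_mean <- mean(as_field(ssh, mask$lat, mask$lon)[elig])
  out$vbat <- psd(dep) / mean(dep)
  out
}

#' Mean SIC within a radius of the recorder
#'
#' Area-weighted mean sea-ice concentration over cells whose centers lie
#' within a geodesic radius of the recorder (the short- and long-range
#' ice context of a detection, typically 25 and 100 km).
#'
#' @param sic a [pam_grid] of SIC in percent.
#' @param center `c(lat, lon)`.
#' @param radius_km radius, km.
#' @return mean SIC, percent.
#' @export
radius_sic <- function(sic, center, radius_km) {
  stopifnot(inherits(sic, "pam_grid"))
  pts <- as.matrix(expand.grid(lon = sic$lon, lat = sic$lat))
  d <- geosphere::distGeo(c(center[2], center[1]), pts) / 1000
  inside <- t(matrix(d <= radius_km, nrow = length(sic$lon)))
  if (!any(inside)) stopf("no cell centers within %g km", radius_km)
  a <- cell_areas_km2(sic$lat, sic$lon)
  sum(sic$z[inside] * a[inside]) / sum(a[inside])
}
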