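## Radial slice environments for the 2-D transmission-loss model.

#' Seabed acoustic properties
#'
#' @param density sediment density, kg/m^3 (default 1200).
#' @param speed compressional sound speed in the sediment, m/s (default
#'   1450).
#' @param absorption_db_lambda sediment absorption, dB per wavelength
#'   (default 1).
#' @param perfect if `TRUE` the bottom reflects losslessly (idealized
#'   waveguide tests).
#' @return object of class `bottom_spec`.
#' @export
bottom_spec <- function(density = 1200, speed = 1450,
                        absorption_db_lambda = 1, perfect = FALSE) {
  if (min(density, speed) <= 0 || absorption_db_lambda < 0)
    stopf("bottom parameters must be positive")
  structure(list(density = density, speed = speed,
                 absorption_db_lambda = absorption_db_lambda,
                 perfect = perfect),
            class = "bottom_spec")
}

#' Slice environment constructor
#'
#' A 2-D range-depth environment along one bearing: bathymetry profile
#' and sound-speed field sampled at fixed depth nodes for each range
#' node.
#'
#' @param bearing bearing, degrees clockwise from true north.
#' @param ranges range nodes, m, ascending from 0.
#' @param depth water depth (m) at each range node (positive down).
#' @param z_nodes depth nodes (m) of the sound-speed field.
#' @param c_field matrix `[z_node, range_node]` of sound speed (m/s), or
#'   a single profile (recycled across range).
#' @param bottom a [bottom_spec()].
#' @return object of class `slice_env`.
#' @export
slice_environment <- function(bearing, ranges, depth, z_nodes, c_field,
                              bottom = bottom_spec()) {
  if (ranges[1] != 0 || is.unsorted(ranges, strictly = TRUE))
    stopf("ranges must ascend from 0")
  if (any(depth <= 0)) stopf("depths must be positive over the slice")
  if (is.null(dim(c_field)))
    c_field <- matrix(c_field, nrow = length(z_nodes), ncol = length(ranges))
  if (nrow(c_field) != length(z_nodes) || ncol(c_field) != length(ranges))
    stopf("c_field must be length(z_nodes) x length(ranges)")
  if (any(c_field < 1400 | c_field > 1600))
    stopf("sound speeds outside [1400, 1600] m/s")
  structure(list(bearing = bearing, ranges = ranges, depth = depth,
                 z_nodes = z_nodes, c_field = c_field, bottom = bottom),
            class = "slice_env")
}

#' Extract a slice environment from gridded fields
#'
#' Samples depth and sound speed along a great-circle transect from the
#' recorder: nodes every `range_step` m out to `length_km`, positions by
#' geodesic projection, depth by bilinear interpolation of the bathymetry
#' grid. Temperature decays from the surface field to a deep value with
#' an e-folding scale `thermocline_m`; salinity is constant. A node on
#' land (depth <= 0) truncates the slice there.
#'
#' @param bathy bathymetry [pam_grid], depth m positive down.
#' @param origin `c(lat, lon)` of the recorder.
#' @param bearing degrees clockwise from north.
#' @param length_km slice length (default 500).
#' @param range_step node spacing, m.
#' @param sst surface temperature: a [pam_grid] or a single value (deg C).
#' @param t_deep deep-water temperature, deg C.
#' @param salinity psu.
#' @param thermocline_m e-folding depth of the surface layer, m.
#' @param z_step depth-node spacing of the sound-speed field, m.
#' @param bottom a [bottom_spec()].
#' @return a `slice_env`.
#' @export
extract_slice <- function(bathy, origin, bearing, length_km = 500,
                          range_step = 1000, sst = 1, t_deep = 0.5,
                          salinity = 34, thermocline_m = 150,
                          z_step = 50, bottom = bottom_spec()) {
  stopifnot(inherits(bathy, "pam_grid"))
  if (origin[1] < min(bathy$lat) || origin[1] > max(bathy$lat) ||
      origin[2] < min(bathy$lon) || origin[2] > max(bathy$lon))
    stopf("origin outside the bathymetry grid")
  ranges <- seq(0, length_km * 1000, by = range_step)
  pts <- geosphere::destPoint(c(origin[2], origin[1]), bearing, ranges)
  lat <- pts[, 2]; lon <- pts[, 1]
  depth <- bilinear(bathy, lat, lon)
  if (depth[1] <= 0) stopf("slice origin is on land")
  if (any(depth <= 0)) {            # land truncates the slice
    cut <- which(depth <= 0)[1] - 1L
    ranges <- ranges[1:cut]; depth <- depth[1:cut]
    lat <- lat[1:cut]; lon <- lon[1:cut]
  }
  t0 <- if (inherits(sst, "pam_grid")) bilinear(sst, lat, lon) else
    rep(sst, length(ranges))
  z_nodes <- seq(0, max(depth) + z_step, by = z_step)
  tz <- t_deep + outer(exp(-z_nodes / thermocline_m), t0 - t_deep)
  cf <- suppressWarnings(
    sound_speed(tz, salinity, matrix(z_nodes, nrow = length(z_nodes),
                                     ncol = length(ranges))))
  env <- slice_environment(bearing, ranges, depth, z_nodes, cf, bottom)
  env$lat <- lat; env$lon <- lon
  env
}
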