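# Shared fixtures, all generated in code.

tiny_config <- function(seed = 1,
                        dates = seq(as.Date("2017-02-10"),
                                    as.Date("2017-10-12"), by = "day"),
                        ...) {
  scene_config(seed = seed,
               lat_range = c(-62, -58), lon_range = c(-48, -44),
               res = 0.5, dates = dates, ...)
}

# deployment covering a handful of days, 12/60 duty
tiny_deployment <- function(start = "2017-07-01 00:00:00",
                            end = "2017-07-05 00:00:00", duty_on = 12) {
  deployment_spec(start, end, duty_on = duty_on)
}

# one annotation row
ann <- function(file, start_s, species = "FW", end_s = start_s + 2,
                low = 15, high = 30, certainty = "confident",
                chorus = FALSE) {
  data.frame(file = file, start_s = start_s, end_s = end_s,
             low_hz = low, high_hz = high, species = species,
             certainty = certainty, chorus = chorus,
             stringsAsFactors = FALSE)
}

# iso-velocity slice: constant depth, constant sound speed
iso_slice <- function(depth = 1000, length_m = 4e5, dr = 500, c0 = 1500,
                      bottom = bottom_spec(perfect = TRUE), bearing = 0) {
  ranges <- seq(0, length_m, by = dr)
  slice_environment(bearing, ranges, rep(depth, length(ranges)),
                    z_nodes = c(0, depth * 2),
                    c_field = matrix(c0, 2, length(ranges)),
                    bottom = bottom)
}

# synthetic tl_grid with prescribed TL values
fake_tl_grid <- function(tl, lat = seq(-61, -59, by = 0.5),
                         lon = seq(-47, -45, by = 0.5), freq = 100) {
  if (length(tl) == 1) tl <- matrix(tl, length(lat), length(lon))
  structure(list(lat = lat, lon = lon, tl = tl, freq = freq),
            class = "tl_grid")
}
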