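test_that("Mackenzie sound speed behaves physically", {
  c0 <- sound_speed(0, 34, 0)
  expect_gt(c0, 1440); expect_lt(c0, 1460)
  ## faster when deeper (pressure) and warmer
  expect_gt(sound_speed(0, 34, 1000), c0)
  expect_gt(sound_speed(2, 34, 0), c0)
  expect_warning(sound_speed(50, 34, 0), "domain")
})

test_that("slice extraction samples depth along the geodesic", {
  cfg <- tiny_config(flat_depth = 1000)
  b <- make_bathymetry(cfg)
  sl <- extract_slice(b, cfg$recorder, 45, length_km = 100,
                      range_step = 10000)
  expect_true(all(sl$depth == 1000))
  ## node positions agree with an independent geodesic inverse: the last
  ## node must be 100 km from the origin at the requested bearing
  d <- geosphere::distGeo(c(cfg$recorder[2], cfg$recorder[1]),
                          c(sl$lon[11], sl$lat[11]))
  expect_lt(abs(d - 100000), 1000)
  b0 <- geosphere::bearing(c(cfg$recorder[2], cfg$recorder[1]),
                           c(sl$lon[11], sl$lat[11]))
  expect_lt(abs(b0 - 45), 0.5)

  ## mirror symmetry: a bathymetry symmetric in longitude about the
  ## origin gives mirror-image profiles east and west
  lat <- seq(-61, -59.5, by = 0.25); lon <- seq(-47, -45, by = 0.25)
  z <- outer(rep(1, length(lat)), 500 + 100 * abs(lon + 46))
  bs <- pam_grid(lat, lon, z)
  e <- extract_slice(bs, c(-60.25, -46), 90, length_km = 50,
                     range_step = 5000)
  w <- extract_slice(bs, c(-60.25, -46), 270, length_km = 50,
                     range_step = 5000)
  expect_equal(e$depth, w$depth, tolerance = 0.01)

  ## land truncates; origin on land errors
  zl <- z; zl[, lon > -45.5] <- -10
  bl <- pam_grid(lat, lon, zl)
  sl2 <- extract_slice(bl, c(-60.25, -46), 90, length_km = 100,
                       range_step = 5000)
  expect_lt(max(sl2$ranges), 100000)
  expect_error(extract_slice(bl, c(-60.25, -45.2), 90), "land")
})

test_that("free-field TL follows spherical spreading", {
  ## deep iso-velocity water, receiver far from the boundaries; a lossy
  ## bottom absorbs the few steep rays that do reach the seabed
  env <- iso_slice(depth = 20000, length_m = 10000, dr = 10,
                   bottom = bottom_spec())
  tl <- trace_tl(env, 100, source_depth = 10000, receiver_depth = 10000,
                 n_rays = 16001, dz = 50, thorp = FALSE)
  sel <- tl$r >= 100 & tl$r <= 10000
  err <- tl$tl_source[sel] - 20 * log10(tl$r[sel])
  expect_true(all(abs(err) < 1.5))
  ## TL non-decreasing in range (smoothed against counting noise)
  sm <- stats::filter(tl$tl_source[sel], rep(1 / 5, 5))
  expect_true(all(diff(sm[!is.na(sm)]) > -0.5))
  ## energy sanity: no cell exceeds the 1 m reference intensity
  expect_gte(min(tl$tl), 0)
})

test_that("a lossless waveguide shows cylindrical spreading", {
  env <- iso_slice(depth = 1000, length_m = 4e5, dr = 500)
  tl <- trace_tl(env, 100, source_depth = 15, receiver_depth = 280,
                 n_rays = 721, dz = 100, thorp = FALSE,
                 max_bottom_bounce = 1e6)
  sel <- tl$r >= 5e4 & tl$r <= 4e5
  fit <- lm(tl$tl_source[sel] ~ log10(tl$r[sel]))
  expect_gt(coef(fit)[2], 9)
  expect_lt(coef(fit)[2], 12)
})

test_that("the simplified model is reciprocal in a waveguide", {
  env <- iso_slice(depth = 1000, length_m = 4e5, dr = 500)
  a <- trace_tl(env, 100, source_depth = 15, receiver_depth = 280,
                n_rays = 2001, dz = 100, thorp = FALSE,
                max_bottom_bounce = 1e6)
  b <- trace_tl(env, 100, source_depth = 280, receiver_depth = 15,
                n_rays = 2001, dz = 100, thorp = FALSE,
                max_bottom_bounce = 1e6)
  sel <- a$r >= 5e4
  expect_lt(mean(abs(a$tl_source[sel] - b$tl_source[sel])), 0.5)
})

test_that("a more absorbing bottom never reduces TL after bounces", {
  mk <- function(absorb) {
    env <- iso_slice(depth = 500, length_m = 1e5, dr = 250,
                     bottom = bottom_spec(absorption_db_lambda = absorb))
    trace_tl(env, 100, source_depth = 15, receiver_depth = 280,
             n_rays = 721, dz = 100, thorp = FALSE,
             max_bottom_bounce = 1e6)
  }
  t1 <- mk(1); t3 <- mk(3)
  ## beyond a few water depths every arrival has touched the bottom
  sel <- t1$r > 2e4
  d <- t3$tl[, sel] - t1$tl[, sel]
  d <- d[is.finite(d)]
  expect_true(all(d > -1e-6))
  expect_gt(mean(d), 0.01)
})

test_that("deeper receiver is rejected when below the seabed", {
  env <- iso_slice(depth = 200, length_m = 1e4, dr = 100)
  expect_error(trace_tl(env, 100, receiver_depth = 300), "seabed")
})

test_that("gridding radial slices preserves symmetry and slice values", {
  origin <- c(-60.4, -46)
  ranges <- seq(0, 100000, by = 1000)
  mk_slice <- function(bearing, tlfun) {
    r <- (ranges[-1] + ranges[-length(ranges)]) / 2
    structure(list(bearing = bearing, r = r, z = 15,
                   tl = matrix(tlfun(r), 1), tl_source = tlfun(r),
                   freq = 100), class = "tl_slice")
  }
  slices <- lapply(seq(0, 350, by = 10), mk_slice,
                   tlfun = function(r) 20 * log10(r))
  mesh <- list(lat = seq(-60.9, -59.9, by = 0.05),
               lon = seq(-47, -45, by = 0.05))
  g <- grid_tl(slices, origin, mesh = mesh)
  ## bearing-independent slices: field depends on range only
  pts <- as.matrix(expand.grid(lon = mesh$lon, lat = mesh$lat))
  d <- geosphere::distGeo(c(origin[2], origin[1]), pts)
  dmat <- t(matrix(d, nrow = length(mesh$lon)))
  ok <- is.finite(g$tl) & dmat > 2000 & dmat < 90000
  resid <- g$tl[ok] - 20 * log10(dmat[ok])
  expect_lt(max(abs(resid)), 0.1)
  ## linear-in-range TL: midpoint interpolation is exact
  slices2 <- lapply(seq(0, 350, by = 10), mk_slice,
                    tlfun = function(r) 0.001 * r)
  g2 <- grid_tl(slices2, origin, mesh = mesh)
  expect_equal(g2$tl[ok], 0.001 * dmat[ok], tolerance = 1e-5)
  ## beyond the slice length: sentinel
  expect_true(all(!is.finite(g$tl[dmat > 101000])))
  ## missing bearings are an error naming the gap
  expect_error(grid_tl(slices[-c(10:13)], origin, mesh = mesh), "gaps")
})

test_that("Thorp absorption is tiny at 100 Hz and grows with frequency", {
  expect_lt(thorp_absorption(100), 0.01)
  expect_gt(thorp_absorption(10000), thorp_absorption(1000))
})
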