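test_that("SNR = SL - TL - NL with sentinel propagation", {
  g <- fake_tl_grid(120)
  expect_equal(unique(as.vector(snr_grid(g, 189, 60)$snr)), 9)
  expect_equal(unique(as.vector(snr_grid(g, 163, 60)$snr)), -17)
  g0 <- fake_tl_grid(0)
  expect_true(all(snr_grid(g0, 80, 80)$snr == 0))
  gi <- fake_tl_grid(120); gi$tl[2, 2] <- Inf
  s <- snr_grid(gi, 189, 60)
  expect_identical(s$snr[2, 2], -Inf)
})

test_that("audible mask applies a strict 5 dB threshold", {
  g49 <- fake_tl_grid(100)
  m49 <- audible_mask(snr_grid(g49, 100 + 100 + 4.9, 100))  # SNR = 4.9
  expect_false(any(m49$mask))
  expect_equal(m49$area_km2, 0)
  m51 <- audible_mask(snr_grid(g49, 100 + 100 + 5.1, 100))  # SNR = 5.1
  expect_true(all(m51$mask))
  expect_equal(m51$area_km2, sum(cell_areas_km2(m51$lat, m51$lon)))
})

test_that("louder noise can only shrink the audible area", {
  set.seed(77)
  g <- fake_tl_grid(matrix(runif(25, 80, 140), 5, 5))
  m1 <- audible_mask(snr_grid(g, 189, 60))
  m2 <- audible_mask(snr_grid(g, 189, 70))
  expect_true(all(m2$mask <= m1$mask))      # cellwise subset
  expect_lte(m2$area_km2, m1$area_km2)
  ## and a higher threshold likewise
  m3 <- audible_mask(snr_grid(g, 189, 60), threshold = 15)
  expect_true(all(m3$mask <= m1$mask))
})

test_that("daily masks binarize mean occupancy at one half", {
  g <- fake_tl_grid(100)
  m_in <- audible_mask(snr_grid(g, 220, 60))    # all audible
  m_out <- audible_mask(snr_grid(g, 100, 60))   # none audible
  expect_identical(daily_mask(list(m_in, m_in))$mask, m_in$mask)
  d13 <- daily_mask(c(rep(list(m_in), 13), rep(list(m_out), 11)))
  expect_true(all(d13$mask))                    # 13/24 >= 0.5
  d11 <- daily_mask(c(rep(list(m_in), 11), rep(list(m_out), 13)))
  expect_false(any(d11$mask))                   # 11/24 < 0.5
  expect_equal(unique(as.vector(d13$occupancy)), 13 / 24)
  expect_error(daily_mask(list()), "at least one")
})

test_that("sea-ice proportion uses the strict 30 percent rule", {
  ## split by longitude so the two halves have equal area at every lat
  ## (even column count so alternating halves balance exactly)
  lat <- seq(-61, -59, by = 0.5); lon <- seq(-48, -44.5, by = 0.5)
  g <- fake_tl_grid(100, lat = lat, lon = lon)
  m <- audible_mask(snr_grid(g, 220, 60))
  sic <- matrix(0, length(lat), length(lon))
  sic[, lon < -46] <- 80
  expect_equal(sic_proportion(m, sic),
               sum(m$areas[, lon < -46]) / sum(m$areas))
  sic_half <- matrix(rep(c(80, 0), length.out = length(lon)),
                     length(lat), length(lon), byrow = TRUE)
  expect_equal(sic_proportion(m, sic_half), 0.5, tolerance = 1e-6)
  expect_equal(sic_proportion(m, matrix(20, length(lat), length(lon))), 0)
  expect_equal(sic_proportion(m, matrix(31, length(lat), length(lon))), 1)
  ## empty mask: undefined
  m0 <- audible_mask(snr_grid(g, 100, 60))
  expect_true(is.na(sic_proportion(m0, sic)))
})

test_that("constrained covariates: means, vBAT and NA propagation", {
  lat <- seq(-61, -59, by = 0.5); lon <- seq(-48, -44.5, by = 0.5)
  g <- fake_tl_grid(100, lat = lat, lon = lon)
  m <- audible_mask(snr_grid(g, 220, 60))
  nlat <- length(lat); nlon <- length(lon)
  sic0 <- matrix(0, nlat, nlon)
  sst <- matrix(1.5, nlat, nlon)
  ssh <- matrix(-0.2, nlat, nlon)
  ## uniform depth: vBAT = 0
  cs <- constrained_stats(m, sic0, sst, ssh, matrix(1000, nlat, nlon))
  expect_equal(cs$sst_mean, 1.5)
  expect_equal(cs$ssh_mean, -0.2)
  expect_equal(cs$vbat, 0)
  ## two depths in equal proportion: population sd / mean
  dep <- matrix(rep(c(1000, 3000), length.out = nlon), nlat, nlon,
                byrow = TRUE)
  cs2 <- constrained_stats(m, sic0, sst, ssh, dep)
  ## hand-computed: mean 2000, population sd 1000 -> CV 0.5
  expect_equal(cs2$vbat, 0.5, tolerance = 1e-3)
  ## ice cover shrinks the eligible set; full cover gives NA stats
  sic_all <- matrix(90, nlat, nlon)
  cs3 <- constrained_stats(m, sic_all, sst, ssh, dep)
  expect_true(is.na(cs3$sst_mean) && is.na(cs3$vbat))
  expect_equal(cs3$n_cells, 0)
  sic_part <- sic0; sic_part[, 1:4] <- 90
  cs4 <- constrained_stats(m, sic_part, sst, ssh, dep)
  expect_lt(cs4$n_cells, cs$n_cells)
})

test_that("radius SIC means are area-weighted over the geodesic disc", {
  cfg <- tiny_config()
  ax <- list(lat = seq(-61, -59.75, by = 0.025),
             lon = seq(-46.6, -45.3, by = 0.05))
  center <- c(-60.4, -45.97)
  all_ice <- pam_grid(ax$lat, ax$lon,
                      matrix(100, length(ax$lat), length(ax$lon)))
  expect_equal(radius_sic(all_ice, center, 25), 100)
  none <- pam_grid(ax$lat, ax$lon,
                   matrix(0, length(ax$lat), length(ax$lon)))
  expect_equal(radius_sic(none, center, 25), 0)
  ## half-disc split by the meridian through the center
  z <- matrix(0, length(ax$lat), length(ax$lon))
  z[, ax$lon < center[2]] <- 100
  half <- pam_grid(ax$lat, ax$lon, z)
  expect_equal(radius_sic(half, center, 25), 50, tolerance = 0.04)
})
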