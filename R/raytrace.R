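## Simplified 2-D ray tracer: range-marched fan with refraction by the
## piecewise-linear sound-speed profile, specular surface reflection,
## lossy bottom reflection, and incoherent intensity accumulation on a
## range-depth lattice. Deliberately replaces coherent Gaussian-beam
## modelling: the target quantities are audible-area scale spreading laws
## (spherical at short range, cylindrical in a waveguide), not phase
## structure.

## Reflection loss (dB per bounce) for a fluid sediment half-space:
## Rayleigh coefficient from the lossless impedance contrast, plus an
## additive sediment-absorption term per interaction, scaled by the
## grazing angle (steeper rays penetrate further into the bottom). The
## additive form keeps the per-bounce loss monotone in the absorption
## parameter, which a complex-wavenumber coefficient is not near the
## intromission/critical angles.
rayleigh_loss_db <- function(grazing, f, bottom, c_water, rho_water = 1025) {
  if (bottom$perfect) return(rep(0, length(grazing)))
  g <- pmin(pmax(grazing, 1e-3), pi / 2)
  k1 <- 2 * pi * f / c_water
  k2 <- 2 * pi * f / bottom$speed
  kz1 <- k1 * sin(g)
  kz2 <- sqrt(as.complex(k2^2 - (k1 * cos(g))^2))
  kz2 <- ifelse(Im(kz2) < 0, -kz2, kz2)
  R <- (bottom$density * kz1 - rho_water * kz2) /
       (bottom$density * kz1 + rho_water * kz2)
  -20 * log10(pmax(Mod(R), 1e-12)) + bottom$absorption_db_lambda * sin(g)
}

#' Transmission loss along a slice by incoherent ray tracing
#'
#' Launches a fan of rays from the recorder depth at range 0 (using
#' acoustic reciprocity, so the returned field is the loss from a source
#' anywhere on the slice to the recorder) and marches them in range.
#' Rays refract through the piecewise-linear sound-speed field, reflect
#' specularly (losslessly) at the surface and with a Rayleigh-style
#' coefficient plus sediment absorption at the bottom, and are dropped
#' after `max_bottom_bounce` bottom interactions or when steeper than 88
#' degrees. Each ray carries the solid-angle share of a unit source and
#' deposits energy flux into every range-depth cell it crosses; cell
#' intensity is flux per annulus volume and
#' `TL = -10 log10(I / I_ref(1 m))`. Cells no ray reaches get an
#' infinite-TL sentinel.
#'
#' @param env a `slice_env`.
#' @param frequency Hz (controls bottom loss and seawater absorption).
#' @param source_depth depth (m) whose TL curve is extracted (default
#'   15 m, a near-surface vocalizing animal).
#' @param receiver_depth recorder depth (m), the ray-fan origin; must be
#'   less than the water depth at range 0.
#' @param n_rays number of launch angles.
#' @param max_angle half-aperture of the fan, degrees.
#' @param dz depth-cell size, m.
#' @param max_bottom_bounce bounce budget per ray.
#' @param thorp include Thorp seawater absorption?
#' @return object of class `tl_slice`: `r`, `z` (cell centers), `tl`
#'   (matrix `[z, r]`, dB), `tl_source` (TL curve at `source_depth`),
#'   plus the call parameters.
#' @export
trace_tl <- function(env, frequency, source_depth = 15,
                     receiver_depth = 280, n_rays = 181, max_angle = 80,
                     dz = 20, max_bottom_bounce = 20, thorp = TRUE) {
  stopifnot(inherits(env, "slice_env"))
  if (receiver_depth >= env$depth[1])
    stopf("receiver depth (%g m) must be above the seabed at range 0 (%g m)",
          receiver_depth, env$depth[1])
  ranges <- env$ranges
  nseg <- length(ranges) - 1L
  if (nseg < 1) stopf("slice needs at least two range nodes")
  zmax <- max(env$depth)
  nzc <- max(1L, ceiling(zmax / dz))
  acc <- matrix(0, nzc, nseg)

  th <- seq(-max_angle, max_angle, length.out = n_rays) * pi / 180
  dth <- th[2] - th[1]
  pw0 <- cos(th) * dth / 2           # solid-angle share of a unit source
  z <- rep(receiver_depth, n_rays)
  loss <- numeric(n_rays)
  nb <- integer(n_rays)
  alive <- rep(TRUE, n_rays)

  zn <- env$z_nodes
  dzn <- zn[2] - zn[1]
  alpha_km <- if (thorp) thorp_absorption(frequency) else 0
  th_max <- 88 * pi / 180

  for (i in seq_len(nseg)) {
    if (!any(alive)) break
    dr <- ranges[i + 1] - ranges[i]
    ccol <- env$c_field[, min(i, ncol(env$c_field))]
    gcol <- diff(ccol) / dzn
    a <- which(alive)
    ## sound speed and its vertical gradient at each ray depth
    k <- pmin(pmax(floor(z[a] / dzn) + 1L, 1L), length(zn) - 1L)
    cz <- ccol[k] + (z[a] - zn[k]) * gcol[k]
    dcdz <- gcol[k]
    ## deposit flux in this range column
    ds <- dr / pmax(cos(th[a]), 0.05)
    w <- pw0[a] * 10^(-loss[a] / 10) * ds
    zb <- pmin(pmax(floor(z[a] / dz) + 1L, 1L), nzc)
    dep <- rowsum(w, zb)
    acc[as.integer(rownames(dep)), i] <- acc[as.integer(rownames(dep)), i] +
      dep[, 1]
    loss[a] <- loss[a] + alpha_km * ds / 1000
    ## advance (unfolded), then reflect at the boundaries: fold the end
    ## position into [0, D], counting surface and bottom crossings so a
    ## steep ray can bounce several times within one range step
    th_new <- th[a] - (dcdz / cz) * dr
    D1 <- env$depth[i + 1]
    beta <- atan((env$depth[i + 1] - env$depth[i]) / dr)
    z0 <- pmin(z[a], D1 - 1e-9)
    zu <- z0 + tan((th[a] + th_new) / 2) * dr
    n_bot <- abs(floor((zu - D1) / (2 * D1)) - floor((z0 - D1) / (2 * D1)))
    n_sur <- abs(floor(zu / (2 * D1)) - floor(z0 / (2 * D1)))
    m <- zu %% (2 * D1)
    refl <- m > D1
    z_new <- ifelse(refl, 2 * D1 - m, m)
    th_fold <- ifelse(refl, -th_new, th_new)
    ## sloping bottom: exact specular update for the common single-bounce
    ## case (multi-bounce steep rays use the flat fold)
    one_bot <- n_bot == 1L & n_sur == 0L
    th_fold[one_bot] <- 2 * beta - th_new[one_bot]
    hit <- n_bot > 0L
    if (any(hit)) {
      graz <- pmax(abs(abs(th_new[hit]) - beta), 1e-3)
      loss[a][hit] <- loss[a][hit] + n_bot[hit] *
        rayleigh_loss_db(graz, frequency, env$bottom, cz[hit])
      nb[a][hit] <- nb[a][hit] + n_bot[hit]
    }
    th[a] <- th_fold
    z[a] <- z_new
    alive[a] <- abs(th_fold) < th_max & nb[a] <= max_bottom_bounce
  }

  r_mid <- (ranges[-1] + ranges[-length(ranges)]) / 2
  dr_all <- diff(ranges)
  vol <- 2 * pi * outer(rep(dz, nzc), r_mid * dr_all)
  intensity <- acc / vol
  tl <- -10 * log10(4 * pi * intensity)   # ref: unit source at 1 m
  tl[!is.finite(tl)] <- Inf
  zc <- (seq_len(nzc) - 0.5) * dz
  izs <- which.min(abs(zc - source_depth))
  structure(list(bearing = env$bearing, r = r_mid, z = zc, tl = tl,
                 tl_source = tl[izs, ], freq = frequency,
                 source_depth = source_depth,
                 receiver_depth = receiver_depth, n_rays = n_rays),
            class = "tl_slice")
}

#' @export
print.tl_slice <- function(x, ...) {
  fin <- x$tl[is.finite(x$tl)]
  cat(sprintf(
    "<tl_slice> bearing %g deg, %g Hz, %d x %d cells, TL [%.1f, %.1f] dB\n",
    x$bearing, x$freq, nrow(x$tl), ncol(x$tl),
    if (length(fin)) min(fin) else NA, if (length(fin)) max(fin) else NA))
  invisible(x)
}

#' @export
plot.tl_slice <- function(x, ...) {
  tl <- x$tl
  tl[!is.finite(tl)] <- NA
  image(x$r / 1000, x$z, t(tl), ylim = rev(range(x$z)),
        xlab = "range (km)", ylab = "depth (m)",
        main = sprintf("TL, %g Hz, bearing %g", x$freq, x$bearing), ...)
  invisible(x)
}
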