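## Gridding radial TL slices onto a lat-lon mesh.

#' Lat-lon mesh around the recorder
#'
#' Cell-centered regular mesh spanning `radius_km` in every direction
#' from the origin (default 218 x 464 cells, latitude ascending).
#'
#' @param origin `c(lat, lon)`.
#' @param radius_km mesh half-extent, km.
#' @param nlat,nlon mesh dimensions.
#' @return list with `lat` and `lon` cell-center vectors.
#' @export
tl_mesh <- function(origin, radius_km = 500, nlat = 218, nlon = 464) {
  dlat <- radius_km / 111.2
  dlon <- radius_km / (111.2 * cos(origin[1] * pi / 180))
  list(lat = seq(origin[1] - dlat, origin[1] + dlat, length.out = nlat),
       lon = seq(origin[2] - dlon, origin[2] + dlon, length.out = nlon))
}

#' Grid TL slices onto a lat-lon mesh
#'
#' Linear interpolation in polar (bearing, range) coordinates of the
#' source-depth TL curves of a set of slices onto mesh cells. Cells
#' beyond the slice length get the infinite-TL sentinel; cells on land
#' (optional bathymetry with depth <= 0) likewise. Bearing coverage must
#' be complete: a gap larger than 1.5 times the median bearing spacing
#' (including the wrap-around) is an error.
#'
#' @param slices list of `tl_slice` objects (any bearing order).
#' @param origin recorder `c(lat, lon)`.
#' @param mesh list with `lat`, `lon` vectors (see [tl_mesh()]).
#' @param bathy optional [pam_grid]; mesh cells with depth <= 0 are
#'   marked land.
#' @return object of class `tl_grid`: `lat`, `lon`, `tl` matrix
#'   `[lat, lon]` (dB, `Inf` = unreachable/land), `freq`.
#' @export
grid_tl <- function(slices, origin, mesh = tl_mesh(origin), bathy = NULL) {
  brg <- vapply(slices, function(s) s$bearing %% 360, numeric(1))
  ord <- order(brg)
  slices <- slices[ord]; brg <- brg[ord]
  if (anyDuplicated(brg)) stopf("duplicated slice bearings")
  gaps <- diff(c(brg, brg[1] + 360))
  med <- median(gaps)
  bad <- which(gaps > 1.5 * med)
  if (length(bad))
    stopf("bearing coverage has gaps after: %s deg",
          paste(round(brg[bad], 1), collapse = ", "))
  freq <- slices[[1]]$freq
  rmax <- min(vapply(slices, function(s) max(s$r), numeric(1)))

  pts <- as.matrix(expand.grid(lon = mesh$lon, lat = mesh$lat))
  b <- geosphere::bearing(c(origin[2], origin[1]), pts) %% 360
  d <- geosphere::distGeo(c(origin[2], origin[1]), pts)

  ## wrap-around: duplicate the first slice at +360
  brg_w <- c(brg, brg[1] + 360)
  idx_w <- c(seq_along(slices), 1L)
  b[b < brg_w[1]] <- b[b < brg_w[1]] + 360

  j1 <- findInterval(b, brg_w, rightmost.closed = TRUE)
  j1[j1 < 1] <- 1L; j1[j1 >= length(brg_w)] <- length(brg_w) - 1L
  wb <- (b - brg_w[j1]) / (brg_w[j1 + 1] - brg_w[j1])
  wb <- pmin(pmax(wb, 0), 1)

  interp_curve <- function(s, dd) {
    ## linear in range with sentinel handling: a finite neighbour wins
    r <- s$r; v <- s$tl_source
    i <- findInterval(dd, r)
    i[i < 1] <- 1L; i[i >= length(r)] <- length(r) - 1L
    wr <- (dd - r[i]) / (r[i + 1] - r[i])
    wr <- pmin(pmax(wr, 0), 1)
    v0 <- v[i]; v1 <- v[i + 1]
    out <- v0 * (1 - wr) + v1 * wr
    only0 <- is.finite(v0) & !is.finite(v1)
    only1 <- !is.finite(v0) & is.finite(v1)
    out[only0] <- v0[only0]
    out[only1] <- v1[only1]
    out
  }
  va <- numeric(length(d)); vb <- numeric(length(d))
  for (j in unique(j1)) {
    sel <- j1 == j
    va[sel] <- interp_curve(slices[[idx_w[j]]], d[sel])
    vb[sel] <- interp_curve(slices[[idx_w[j + 1]]], d[sel])
  }
  tlv <- va * (1 - wb) + vb * wb
  onlya <- is.finite(va) & !is.finite(vb)
  onlyb <- !is.finite(va) & is.finite(vb)
  tlv[onlya] <- va[onlya]
  tlv[onlyb] <- vb[onlyb]
  tlv[d > rmax] <- Inf
  tlv[!is.finite(tlv)] <- Inf

  tl <- matrix(tlv, nrow = length(mesh$lon), ncol = length(mesh$lat))
  tl <- t(tl)                         # -> [lat, lon]
  if (!is.null(bathy)) {
    dep <- matrix(bilinear(bathy, rep(mesh$lat, times = length(mesh$lon)),
                           rep(mesh$lon, each = length(mesh$lat))),
                  nrow = length(mesh$lat))
    tl[dep <= 0] <- Inf
  }
  structure(list(lat = mesh$lat, lon = mesh$lon, tl = tl, freq = freq),
            class = "tl_grid")
}

#' @export
print.tl_grid <- function(x, ...) {
  fin <- x$tl[is.finite(x$tl)]
  cat(sprintf("<tl_grid> %d x %d, %g Hz, %.1f%% reachable, TL [%.1f, %.1f] dB\n",
              length(x$lat), length(x$lon), x$freq,
              100 * mean(is.finite(x$tl)),
              if (length(fin)) min(fin) else NA,
              if (length(fin)) max(fin) else NA))
  invisible(x)
}
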