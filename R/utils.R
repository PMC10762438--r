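## Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code with a private RNG stream so generators are deterministic
## without clobbering the caller's random state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Regular latitude-longitude grid
#'
#' Light container for a single 2-D field on a regular lat-lon mesh.
#' Latitudes are cell centers in ascending order; the value matrix is
#' indexed `[lat, lon]`.
#'
#' @param lat,lon numeric vectors of cell-center coordinates (degrees);
#'   `lat` must be strictly ascending.
#' @param z numeric matrix, `length(lat)` rows by `length(lon)` columns.
#' @return an object of class `pam_grid`.
#' @export
pam_grid <- function(lat, lon, z) {
  z <- as.matrix(z)
  if (length(lat) < 1 || length(lon) < 1) stopf("empty grid extent")
  if (is.unsorted(lat, strictly = TRUE)) stopf("lat must be strictly ascending")
  if (nrow(z) != length(lat) || ncol(z) != length(lon))
    stopf("z must be %d x %d, got %d x %d",
          length(lat), length(lon), nrow(z), ncol(z))
  structure(list(lat = as.numeric(lat), lon = as.numeric(lon), z = z),
            class = "pam_grid")
}

#' @export
print.pam_grid <- function(x, ...) {
  cat(sprintf("<pam_grid> %d x %d cells, lat [%.3f, %.3f], lon [%.3f, %.3f]\n",
              length(x$lat), length(x$lon),
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  fin <- x$z[is.finite(x$z)]
  if (length(fin))
    cat(sprintf("  values: [%.4g, %.4g]\n", min(fin), max(fin)))
  invisible(x)
}

#' Latitude-dependent cell areas
#'
#' Areas (km^2) of the cells of a regular lat-lon mesh, using the
#' spherical approximation A = R^2 dlat dlon cos(lat).
#'
#' @param lat,lon cell-center coordinates in degrees (regular spacing).
#' @return matrix `[lat, lon]` of areas in km^2.
#' @export
cell_areas_km2 <- function(lat, lon) {
  R <- 6371.0088
  dlat <- if (length(lat) > 1) abs(stats::median(diff(lat))) else 1
  dlon <- if (length(lon) > 1) abs(stats::median(diff(lon))) else 1
  a <- R^2 * (dlat * pi / 180) * (dlon * pi / 180) * cos(lat * pi / 180)
  matrix(a, nrow = length(lat), ncol = length(lon))
}

#' Write / read a grid as plain text
#'
#' Serializes a [pam_grid] as a small self-describing text file: comment
#' header lines carrying the axes, then the value matrix in CSV form
#' (rows = latitudes ascending).
#'
#' @param g a `pam_grid`.
#' @param path file path.
#' @return `write_grid` returns `path` invisibly; `read_grid` a `pam_grid`.
#' @export
write_grid <- function(g, path) {
  stopifnot(inherits(g, "pam_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# pamscape grid v1",
    paste0("# lat: ", paste(format(g$lat, digits = 10), collapse = ",")),
    paste0("# lon: ", paste(format(g$lon, digits = 10), collapse = ","))
  ), con)
  utils::write.table(g$z, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  ln <- readLines(path, n = 3)
  if (!startsWith(ln[1], "# pamscape grid"))
    stopf("%s is not a pamscape grid file", path)
  ax <- function(s) as.numeric(strsplit(sub("^# l(at|on): ", "", s), ",")[[1]])
  z <- as.matrix(utils::read.table(path, sep = ",", comment.char = "#"))
  dimnames(z) <- NULL
  pam_grid(ax(ln[2]), ax(ln[3]), z)
}

## nearest index in a sorted vector
nearest_idx <- function(x, v) {
  vapply(v, function(vi) which.min(abs(x - vi)), integer(1))
}

## bilinear interpolation of grid g at (lat, lon) points; clamps to edges
bilinear <- function(g, lat, lon) {
  fi <- approx(g$lat, seq_along(g$lat), xout = pmin(pmax(lat, min(g$lat)),
                                                    max(g$lat)))$y
  fj <- approx(g$lon, seq_along(g$lon), xout = pmin(pmax(lon, min(g$lon)),
                                                    max(g$lon)))$y
  i0 <- pmin(floor(fi), length(g$lat) - 1L); i0 <- pmax(i0, 1L)
  j0 <- pmin(floor(fj), length(g$lon) - 1L); j0 <- pmax(j0, 1L)
  wi <- fi - i0; wj <- fj - j0
  z <- g$z
  z[cbind(i0, j0)] * (1 - wi) * (1 - wj) +
    z[cbind(i0 + 1L, j0)] * wi * (1 - wj) +
    z[cbind(i0, j0 + 1L)] * (1 - wi) * wj +
    z[cbind(i0 + 1L, j0 + 1L)] * wi * wj
}
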