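## Presence time series: annotation logs + deployment metadata -> hourly
## binary presence, daily percentages, monthly positive-hour totals.

#' Standard species labels
#'
#' The eight detection categories used in the annotation logs: Antarctic
#' blue whale (ABW), fin whale (FW), humpback whale (HW), southern right
#' whale (SRW), Antarctic minke whale (AMW), odontocetes (O), leopard
#' seal (LS) and crabeater seal (CS).
#' @return character vector of labels.
#' @export
species_labels <- function() c("ABW", "FW", "HW", "SRW", "AMW", "O", "LS", "CS")

#' Deployment specification
#'
#' Metadata for one duty-cycled recorder deployment: recording window,
#' minutes recorded per 60-min cycle, sampling rate, position and depth.
#'
#' @param start,end deployment window (UTC `POSIXct`, or strings parsed as
#'   UTC).
#' @param duty_on minutes recorded at the top of each hour (0 < on <= 60).
#' @param fs sampling rate, Hz.
#' @param lat,lon recorder position (degrees).
#' @param depth recorder depth, m.
#' @return object of class `deployment_spec`.
#' @export
deployment_spec <- function(start, end, duty_on, fs = 32768,
                            lat = -60.405, lon = -45.972, depth = 286) {
  start <- as.POSIXct(start, tz = "UTC")
  end <- as.POSIXct(end, tz = "UTC")
  if (is.na(start) || is.na(end) || start >= end)
    stopf("deployment start must precede end")
  if (duty_on <= 0 || duty_on > 60)
    stopf("duty_on must be in (0, 60] minutes")
  structure(list(start = start, end = end, duty_on = duty_on, fs = fs,
                 lat = lat, lon = lon, depth = depth),
            class = "deployment_spec")
}

#' Read / write deployment specs as YAML
#' @param path YAML file; for `read_deployments` a file holding a list of
#'   named deployment entries.
#' @return `read_deployments` returns a named list of [deployment_spec()].
#' @export
read_deployments <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(d) {
    deployment_spec(d$start, d$end, d$duty_on, d$fs %||% 32768,
                    d$lat %||% -60.405, d$lon %||% -45.972,
                    d$depth %||% 286)
  })
}

#' Clock hours covered by a deployment
#'
#' Recordings start at the top of each hour (start-of-cycle); an hour is
#' covered when its full ON window lies inside the deployment.
#'
#' @param deployment a [deployment_spec()].
#' @return `POSIXct` vector of covered hour starts (UTC).
#' @export
deployment_hours <- function(deployment) {
  h0 <- as.POSIXct(ceiling(as.numeric(deployment$start) / 3600) * 3600,
                   tz = "UTC", origin = "1970-01-01")
  hs <- seq(h0, deployment$end, by = "hour")
  hs[as.numeric(hs) + deployment$duty_on * 60 <= as.numeric(deployment$end)]
}

#' Inclusive day count of a recording period
#'
#' Number of calendar dates from first to last recording day, both
#' included; this is the sample size of daily-response models fitted to a
#' deployment (e.g. a 10 February - 12 October period spans 245 days).
#'
#' @param start,end `Date`s (or strings) of the first and last recording
#'   day, or a [deployment_spec()] as `start`.
#' @return integer day count.
#' @export
n_recording_days <- function(start, end = NULL) {
  if (inherits(start, "deployment_spec")) {
    end <- as.Date(start$end, tz = "UTC")
    start <- as.Date(start$start, tz = "UTC")
  } else {
    start <- as.Date(start); end <- as.Date(end)
  }
  as.integer(end - start) + 1L
}

#' Read an annotation log
#'
#' Reads a CSV selection table with one row per manually annotated call:
#' `file` (recording id `YYYYMMDDTHHMMSS`), `start_s`/`end_s` (seconds
#' into the file), `low_hz`/`high_hz` (frequency bounds), `species`,
#' `certainty` (`"confident"` or `"uncertain"`), `chorus` (logical; part
#' of a distant continuous chorus band rather than a local call).
#'
#' @param path CSV file.
#' @param labels allowed species labels (default [species_labels()]).
#' @return validated data.frame of annotations.
#' @export
read_annotations <- function(path, labels = species_labels()) {
  a <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_annotations(a, labels)
}

validate_annotations <- function(a, labels = NULL) {
  need <- c("file", "start_s", "end_s", "low_hz", "high_hz", "species",
            "certainty", "chorus")
  miss <- setdiff(need, names(a))
  if (length(miss)) stopf("annotation log lacks columns: %s",
                          paste(miss, collapse = ", "))
  if (any(a$start_s >= a$end_s)) stopf("annotation start_s must be < end_s")
  if (any(a$low_hz >= a$high_hz)) stopf("annotation low_hz must be < high_hz")
  if (!is.null(labels) && nrow(a)) {
    bad <- setdiff(unique(a$species), labels)
    if (length(bad)) stopf("unknown species label(s): %s",
                           paste(bad, collapse = ", "))
  }
  a$chorus <- as.logical(a$chorus)
  a
}

annotation_hour <- function(file_id) {
  as.POSIXct(strptime(file_id, "%Y%m%dT%H%M%S", tz = "UTC"))
}

#' Hourly binary acoustic presence
#'
#' An hour scores 1 for a species iff at least one confidently identified,
#' non-chorus annotation of that species falls in the hour's recording;
#' detections are presence-only, so counts beyond the first are ignored.
#' Uncertain annotations are dropped at ingest (set
#' `drop_uncertain = FALSE` to retain them for sensitivity analysis);
#' chorus-band annotations are always excluded. Annotations whose file
#' does not map to a covered deployment hour are rejected and reported.
#'
#' @param annotations data.frame in the [read_annotations()] dialect.
#' @param deployment a [deployment_spec()].
#' @param species species columns for the output (default: the standard
#'   labels restricted to those present, plus any extra seen in the log).
#' @param drop_uncertain drop `certainty != "confident"` rows?
#' @return object of class `hourly_presence`: `hours` (covered hour
#'   starts), `species`, `mat` (0/1 matrix hours x species), `rejected`
#'   (the dropped out-of-window annotations).
#' @export
hourly_presence <- function(annotations, deployment, species = NULL,
                            drop_uncertain = TRUE) {
  annotations <- validate_annotations(annotations)
  hours <- deployment_hours(deployment)
  if (is.null(species)) {
    species <- unique(c(intersect(species_labels(),
                                  unique(annotations$species)),
                        setdiff(unique(annotations$species),
                                species_labels())))
    if (!length(species)) species <- species_labels()
  }
  a <- annotations
  if (drop_uncertain) a <- a[a$certainty == "confident", , drop = FALSE]
  a <- a[!a$chorus, , drop = FALSE]
  hr <- annotation_hour(a$file)
  ok <- !is.na(hr) & (hr %in% hours)
  rejected <- a[!ok, , drop = FALSE]
  if (nrow(rejected))
    warnf("%d annotation(s) outside the deployment window were rejected",
          nrow(rejected))
  a <- a[ok, , drop = FALSE]; hr <- hr[ok]
  mat <- matrix(0L, nrow = length(hours), ncol = length(species),
                dimnames = list(NULL, species))
  if (nrow(a)) {
    i <- match(hr, hours)
    j <- match(a$species, species)
    keep <- !is.na(j)
    mat[cbind(i[keep], j[keep])] <- 1L
  }
  structure(list(hours = hours, species = species, mat = mat,
                 deployment = deployment, rejected = rejected),
            class = "hourly_presence")
}

#' @export
print.hourly_presence <- function(x, ...) {
  cat(sprintf("<hourly_presence> %d hours x %d species (%s to %s)\n",
              length(x$hours), length(x$species),
              format(min(x$hours)), format(max(x$hours))))
  print(colSums(x$mat))
  invisible(x)
}

#' Daily acoustic presence
#'
#' Aggregates hourly presence to days: positive hours, recorded hours and
#' the percentage of recorded hours with presence. The denominator is the
#' number of hours actually recorded that day, so partially recorded
#' first/last days are handled naturally; dates with no recording are
#' absent from the output.
#'
#' @param hourly an `hourly_presence` object.
#' @return data.frame (long): `date`, `species`, `positive_hours`,
#'   `recorded_hours`, `percentage`.
#' @export
daily_presence <- function(hourly) {
  stopifnot(inherits(hourly, "hourly_presence"))
  date <- as.Date(hourly$hours, tz = "UTC")
  rec <- as.vector(table(date))
  udate <- as.Date(names(table(date)))
  pos <- rowsum(hourly$mat, group = as.character(date))
  out <- data.frame(
    date = rep(udate, times = length(hourly$species)),
    species = rep(hourly$species, each = length(udate)),
    positive_hours = as.vector(pos),
    recorded_hours = rep(rec, times = length(hourly$species)),
    stringsAsFactors = FALSE
  )
  out$percentage <- 100 * out$positive_hours / out$recorded_hours
  out[order(out$date, out$species), ]
}

#' Day x species community matrix
#'
#' Reshapes [daily_presence()] output into the wide counts matrix used as
#' the ordination response: rows are days, columns species, entries daily
#' positive hours (0-24).
#'
#' @param daily output of [daily_presence()].
#' @return integer matrix with dates as rownames.
#' @export
community_matrix <- function(daily) {
  sp <- unique(daily$species)
  dt <- sort(unique(daily$date))
  m <- matrix(0L, length(dt), length(sp),
              dimnames = list(as.character(dt), sp))
  m[cbind(match(daily$date, dt), match(daily$species, sp))] <-
    as.integer(daily$positive_hours)
  m
}

#' Duty-cycle audit against a time mark
#'
#' Checks whether shortening the duty cycle would have cost detections:
#' for each species, counts annotated files where at least one detection
#' starts before `mark_minutes` versus files where every detection falls
#' after the mark (detections the shorter cycle would have missed).
#'
#' @param annotations annotation data.frame.
#' @param deployment a [deployment_spec()]; file duration is its ON time.
#' @param mark_minutes the mark, minutes into the file (default 8).
#' @return data.frame: `species`, `n_files`, `before_mark`,
#'   `only_after_mark`.
#' @export
duty_cycle_audit <- function(annotations, deployment, mark_minutes = 8) {
  annotations <- validate_annotations(annotations)
  if (mark_minutes > deployment$duty_on)
    stopf("mark (%g min) exceeds file duration (%g min)",
          mark_minutes, deployment$duty_on)
  a <- annotations[annotations$certainty == "confident" & !annotations$chorus,
                   , drop = FALSE]
  if (!nrow(a)) {
    return(data.frame(species = character(), n_files = integer(),
                      before_mark = integer(), only_after_mark = integer()))
  }
  key <- interaction(a$species, a$file, drop = TRUE)
  first_before <- tapply(a$start_s < mark_minutes * 60, key, any)
  sp <- sub("\\..*$", "", names(first_before))
  out <- data.frame(
    species = sort(unique(sp)),
    stringsAsFactors = FALSE
  )
  out$n_files <- as.vector(table(sp)[out$species])
  bm <- tapply(first_before, sp, sum)
  out$before_mark <- as.vector(bm[out$species])
  out$only_after_mark <- out$n_files - out$before_mark
  out
}

#' Monthly positive-hour totals
#'
#' Number of recorded hours per calendar month containing at least one
#' detection of each species. Months inside the reporting span but with
#' no recording at all are `NA` (recorder off), distinguishing them from
#' recorded months with zero detections.
#'
#' @param hourly an `hourly_presence` object.
#' @param months optional character vector `"YYYY-MM"` defining the
#'   reporting span; default: all months of the calendar years touched by
#'   the deployment.
#' @return matrix species x month of positive-hour counts (`NA` = no
#'   recording).
#' @export
monthly_hours <- function(hourly, months = NULL) {
  stopifnot(inherits(hourly, "hourly_presence"))
  mo <- format(hourly$hours, "%Y-%m")
  if (is.null(months)) {
    yrs <- unique(format(hourly$hours, "%Y"))
    months <- as.vector(outer(yrs, sprintf("%02d", 1:12), paste, sep = "-"))
    months <- sort(months)
  }
  out <- matrix(NA_integer_, nrow = length(hourly$species),
                ncol = length(months),
                dimnames = list(hourly$species, months))
  pos <- rowsum(hourly$mat, group = mo)
  hit <- intersect(rownames(pos), months)
  out[, hit] <- t(pos[hit, , drop = FALSE])
  out
}
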