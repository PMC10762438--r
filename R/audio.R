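## Synthetic calibrated recordings and minimal 16-bit PCM WAV I/O.

#' Synthesize a calibrated recording
#'
#' Gaussian ambient noise at a requested (white) spectral density plus one
#' windowed call per scheduled species at its registry frequency, scaled
#' so the received level at the hydrophone equals `received_level_db`.
#' The pressure series is passed through the calibration chain into ADC
#' counts, as a real recorder would store it. Calls are Hann-windowed
#' tones (or linear down-sweeps when the registry has
#' `call_type == "sweep"`); no attempt is made to imitate real call
#' structure, downstream stages only need energy at a known frequency.
#'
#' @param species_present character vector of registry species calling in
#'   this recording (may be empty: ambient noise only).
#' @param registry species registry with `species`, `freq_hz` (and
#'   optionally `call_type`) columns.
#' @param noise_psd_db ambient spectral density, dB re 1 uPa^2/Hz
#'   (flat).
#' @param calib a [calibration_spec()].
#' @param duration_s recording length, s.
#' @param fs sampling rate, Hz (must exceed twice the highest scheduled
#'   call frequency).
#' @param received_level_db RMS received level of each call, dB re 1 uPa.
#' @param seed RNG seed.
#' @return object of class `pam_wave`: integer `counts`, `fs`, `calib`.
#' @export
synth_recording <- function(species_present = character(),
                            registry = species_registry(),
                            noise_psd_db = 70,
                            calib = calibration_spec(),
                            duration_s = 60, fs = 4096,
                            received_level_db = 120, seed = 1L) {
  sp <- registry[match(species_present, registry$species), , drop = FALSE]
  if (any(is.na(sp$species)))
    stopf("species not in registry: %s",
          paste(setdiff(species_present, registry$species), collapse = ", "))
  if (nrow(sp) && fs < 2 * max(sp$freq_hz))
    stopf("fs = %g Hz is below twice the maximum call frequency (%g Hz)",
          fs, max(sp$freq_hz))
  n <- round(duration_s * fs)
  sigma <- sqrt(10^(noise_psd_db / 10) * fs / 2)   # flat density -> variance
  p <- with_seed(seed + 505L, rnorm(n, sd = sigma))
  t <- seq_len(n) / fs
  if (nrow(sp)) {
    dur <- min(5, duration_s / 2)
    nd <- round(dur * fs)
    for (k in seq_len(nrow(sp))) {
      i0 <- round((k / (nrow(sp) + 1)) * (n - nd))
      idx <- i0 + seq_len(nd)
      win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nd) / (nd + 1))  # Hann
      f <- sp$freq_hz[k]
      type <- if ("call_type" %in% names(sp)) sp$call_type[k] else "tone"
      ph <- if (identical(type, "sweep")) {
        tt <- seq_len(nd) / fs
        2 * pi * (1.2 * f * tt - (0.4 * f / (2 * dur)) * tt^2)
      } else {
        2 * pi * f * t[idx]
      }
      ## amplitude so that the windowed call has the requested RMS level
      a <- sqrt(2) * 10^(received_level_db / 20) / sqrt(mean(win^2))
      p[idx] <- p[idx] + a * win * sin(ph)
    }
  }
  counts <- round(pressure_to_counts(p, calib))
  fsc <- 2^(calib$bits - 1L) - 1
  if (max(abs(counts)) > fsc)
    stopf("requested levels exceed ADC full scale (max |counts| = %g > %g); clipping",
          max(abs(counts)), fsc)
  structure(list(counts = as.integer(counts), fs = fs, calib = calib),
            class = "pam_wave")
}

#' @export
print.pam_wave <- function(x, ...) {
  cat(sprintf("<pam_wave> %d samples @ %g Hz (%.1f s), %d-bit\n",
              length(x$counts), x$fs, length(x$counts) / x$fs,
              x$calib$bits))
  invisible(x)
}

#' Minimal 16-bit PCM WAV writer / reader
#'
#' Plain RIFF/WAVE, mono, 16-bit signed PCM; sufficient to round-trip the
#' synthetic recordings through the on-disk format a recorder produces.
#'
#' @param wave a `pam_wave` (16-bit).
#' @param path output path.
#' @return `write_wav` returns `path` invisibly; `read_wav` a `pam_wave`
#'   (with the supplied calibration attached).
#' @export
write_wav <- function(wave, path) {
  stopifnot(inherits(wave, "pam_wave"))
  if (wave$calib$bits != 16L) stopf("only 16-bit PCM is supported")
  n <- length(wave$counts)
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36 + 2 * n)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16)
  w16(1); w16(1)                      # PCM, mono
  w32(wave$fs); w32(wave$fs * 2)      # byte rate
  w16(2); w16(16)                     # block align, bits
  writeChar("data", con, eos = NULL); w32(2 * n)
  writeBin(as.integer(wave$counts), con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @param calib calibration to attach to the waveform read back.
#' @export
read_wav <- function(path, calib = calibration_spec()) {
  con <- file(path, "rb")
  on.exit(close(con))
  r32 <- function() readBin(con, "integer", size = 4, endian = "little")
  r16 <- function() readBin(con, "integer", size = 2, endian = "little")
  if (readChar(con, 4) != "RIFF") stopf("%s: not a RIFF file", path)
  r32()
  if (readChar(con, 4) != "WAVE") stopf("%s: not a WAVE file", path)
  fs <- NA_real_; counts <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!length(id) || nchar(id) < 4) break
    sz <- r32()
    if (id == "fmt ") {
      fmt <- r16(); nch <- r16(); fs <- r32(); r32(); r16()
      bits <- r16()
      if (fmt != 1 || nch != 1 || bits != 16)
        stopf("%s: only mono 16-bit PCM is supported", path)
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (id == "data") {
      counts <- readBin(con, "integer", n = sz / 2, size = 2,
                        endian = "little", signed = TRUE)
      break
    } else {
      readBin(con, "raw", sz)
    }
  }
  if (is.null(counts)) stopf("%s: no data chunk found", path)
  structure(list(counts = counts, fs = fs, calib = calib),
            class = "pam_wave")
}
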