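## Welch power spectral density of calibrated pressure series and noise
## level extraction at species frequencies.

#' Welch power spectral density
#'
#' One-sided Welch estimate from the first `segment_s` seconds of a
#' pressure series (default 8 min, matching a duty-cycled recorder's ON
#' window): Hamming-windowed segments of `nfft` samples with 50% overlap,
#' per-segment mean removal, density scaling such that integrating the
#' estimate over frequency recovers the signal variance.
#'
#' @param pressure pressure series (uPa) or a `pam_wave` (converted via
#'   its calibration).
#' @param fs sampling rate Hz (ignored for `pam_wave` input).
#' @param nfft FFT/segment size (default 65536).
#' @param overlap fractional segment overlap (default 0.5).
#' @param segment_s portion of the recording used, seconds; shorter
#'   recordings are used whole with a warning.
#' @return object of class `pam_psd`: `freq` (Hz), `psd` (uPa^2/Hz),
#'   `psd_db` (dB re 1 uPa^2/Hz), `nfft`, `fs`, `n_segments`.
#' @export
welch_psd <- function(pressure, fs = NULL, nfft = 65536, overlap = 0.5,
                      segment_s = 480) {
  if (inherits(pressure, "pam_wave")) {
    fs <- pressure$fs
    pressure <- counts_to_pressure(pressure$counts, pressure$calib)
  }
  if (is.null(fs)) stopf("fs is required for a bare pressure series")
  n_use <- round(segment_s * fs)
  if (length(pressure) < n_use) {
    warnf("recording shorter than %g s; using all %.1f s",
          segment_s, length(pressure) / fs)
    n_use <- length(pressure)
  }
  x <- pressure[seq_len(n_use)]
  if (nfft > length(x)) {
    nfft <- 2^floor(log2(length(x)))
    warnf("segment longer than data; nfft reduced to %d", nfft)
  }
  w <- 0.54 - 0.46 * cos(2 * pi * seq_len(nfft) / (nfft - 1))  # Hamming
  step <- max(1, round(nfft * (1 - overlap)))
  starts <- seq(1, length(x) - nfft + 1, by = step)
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nfft %/% 2 + 1)]
    acc <- acc + Re(X * Conj(X))
  }
  scale <- 1 / (fs * sum(w^2))
  psd <- acc / length(starts) * scale
  one <- rep(2, length(psd)); one[1] <- 1
  if (nfft %% 2 == 0) one[length(psd)] <- 1
  psd <- psd * one
  structure(list(freq = (seq_along(psd) - 1) * fs / nfft,
                 psd = psd, psd_db = 10 * log10(pmax(psd, 1e-300)),
                 nfft = nfft, fs = fs, n_segments = length(starts)),
            class = "pam_psd")
}

#' @export
print.pam_psd <- function(x, ...) {
  cat(sprintf("<pam_psd> %d bins, df = %.4g Hz, %d segment(s)\n",
              length(x$freq), x$fs / x$nfft, x$n_segments))
  invisible(x)
}

#' @export
plot.pam_psd <- function(x, ..., log_f = TRUE) {
  f <- x$freq
  keep <- if (log_f) f > 0 else rep(TRUE, length(f))
  plot(f[keep], x$psd_db[keep], type = "l", log = if (log_f) "x" else "",
       xlab = "frequency (Hz)", ylab = "PSD (dB re 1 uPa^2/Hz)", ...)
  invisible(x)
}

#' Noise level at a frequency
#'
#' Spectral level at the bin nearest to `f` (ties resolved to the lower
#' bin). With `band > 0` a band average over `2*band + 1` bins (power
#' mean, returned in dB) is used instead.
#'
#' @param psd a `pam_psd`.
#' @param f frequency, Hz; must lie in `[0, fs/2]`.
#' @param band half-width of the averaging band in bins (0 = single bin).
#' @return noise level, dB re 1 uPa^2/Hz.
#' @export
noise_at_frequency <- function(psd, f, band = 0L) {
  stopifnot(inherits(psd, "pam_psd"))
  if (f < 0 || f > psd$fs / 2)
    stopf("frequency %g Hz outside [0, %g]", f, psd$fs / 2)
  i <- which.min(abs(psd$freq - f))   # first minimum = lower bin on ties
  if (band > 0) {
    idx <- max(1, i - band):min(length(psd$freq), i + band)
    10 * log10(mean(psd$psd[idx]))
  } else {
    psd$psd_db[i]
  }
}

#' Band-integrated power
#'
#' Integral of the one-sided density over `[f_lo, f_hi]` by the
#' rectangle rule; for a sine of amplitude A contained in the band this
#' recovers A^2/2.
#'
#' @param psd a `pam_psd`.
#' @param f_lo,f_hi band edges, Hz.
#' @return band power, uPa^2.
#' @export
band_power <- function(psd, f_lo, f_hi) {
  stopifnot(inherits(psd, "pam_psd"))
  df <- psd$fs / psd$nfft
  idx <- psd$freq >= f_lo & psd$freq <= f_hi
  sum(psd$psd[idx]) * df
}
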