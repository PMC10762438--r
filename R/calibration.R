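## Calibration chain: ADC counts <-> volts <-> acoustic pressure (uPa).

#' Hydrophone calibration specification
#'
#' @param sensitivity hydrophone receiving sensitivity, dB re 1 V/uPa
#'   (negative; default -165).
#' @param gain recorder gain, dB (default 16).
#' @param full_scale_v ADC full-scale voltage (default 5 V, typical of
#'   autonomous moored recorders; the value is rarely reported and is
#'   configurable).
#' @param bits ADC bit depth (default 16).
#' @return object of class `calibration_spec`.
#' @export
calibration_spec <- function(sensitivity = -165, gain = 16,
                             full_scale_v = 5, bits = 16L) {
  if (sensitivity >= 0) stopf("sensitivity must be negative (dB re 1 V/uPa)")
  if (gain < 0) stopf("gain must be >= 0 dB")
  structure(list(sensitivity = sensitivity, gain = gain,
                 full_scale_v = full_scale_v, bits = as.integer(bits)),
            class = "calibration_spec")
}

#' Convert ADC counts to acoustic pressure
#'
#' `uPa = counts * (full_scale_v / 2^(bits-1)) / (10^(gain/20) *
#' 10^(sensitivity/20))`: counts to volts at the ADC, undo the gain, then
#' the hydrophone sensitivity.
#'
#' @param counts integer/numeric waveform in ADC counts.
#' @param calib a [calibration_spec()].
#' @return numeric pressure series, uPa.
#' @export
counts_to_pressure <- function(counts, calib) {
  if (!inherits(calib, "calibration_spec")) stopf("missing calibration spec")
  v <- counts * (calib$full_scale_v / 2^(calib$bits - 1L))
  v / (10^(calib$gain / 20) * 10^(calib$sensitivity / 20))
}

#' @rdname counts_to_pressure
#' @param pressure pressure series in uPa.
#' @export
pressure_to_counts <- function(pressure, calib) {
  if (!inherits(calib, "calibration_spec")) stopf("missing calibration spec")
  v <- pressure * 10^(calib$gain / 20) * 10^(calib$sensitivity / 20)
  v / (calib$full_scale_v / 2^(calib$bits - 1L))
}
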