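## Sound speed and seawater absorption.

#' Sound speed in seawater (Mackenzie nine-term equation)
#'
#' c(T, S, z) in m/s from temperature (deg C), salinity (psu) and depth
#' (m). Inputs outside the formula's fitted domain (T in \[-2, 30\], S in
#' \[25, 40\], z in \[0, 8000\]) are extrapolated with a warning.
#'
#' @param temp temperature, deg C.
#' @param sal salinity, psu.
#' @param z depth, m (positive down).
#' @return sound speed, m/s.
#' @export
sound_speed <- function(temp, sal = 34, z = 0) {
  if (any(temp < -2 | temp > 30) || any(sal < 25 | sal > 40) ||
      any(z < 0 | z > 8000))
    warnf("sound_speed: inputs outside fitted domain; extrapolating")
  1448.96 + 4.591 * temp - 5.304e-2 * temp^2 + 2.374e-4 * temp^3 +
    1.340 * (sal - 35) + 1.630e-2 * z + 1.675e-7 * z^2 -
    1.025e-2 * temp * (sal - 35) - 7.139e-13 * temp * z^3
}

#' Seawater volume absorption (Thorp)
#'
#' Low-frequency attenuation in dB/km; negligible below ~200 Hz but kept
#' on by default in the ray tracer.
#'
#' @param f frequency, Hz.
#' @return absorption, dB/km.
#' @export
thorp_absorption <- function(f) {
  fk <- f / 1000
  0.11 * fk^2 / (1 + fk^2) + 44 * fk^2 / (4100 + fk^2) +
    2.75e-4 * fk^2 + 0.003
}
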