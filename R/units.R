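# Unit helpers shared across the acoustic and thermal modules.
# Internal length unit is mm; acoustic pressure Pa; intensity W/cm2 unless
# a function documents otherwise.

#' Convert an attenuation coefficient from dB/cm to Np/m
#'
#' @param alpha_db_cm attenuation in dB/cm (at the frequency of interest).
#' @return attenuation in Np/m.
#' @export
db_cm_to_np_m <- function(alpha_db_cm) alpha_db_cm * log(10) / 20 * 100

# Np/mm, convenient for kernels working in mm
db_cm_to_np_mm <- function(alpha_db_cm) db_cm_to_np_m(alpha_db_cm) / 1000

#' Acoustic wavelength in millimetres
#'
#' @param c sound speed, m/s.
#' @param f_mhz frequency, MHz.
#' @return wavelength, mm.
#' @export
wavelength_mm <- function(c, f_mhz) c / (f_mhz * 1000)

#' Round half away from zero
#'
#' Presentation rounding used for reported indices: one-decimal,
#' half-away-from-zero (so 80.25 -> 80.3 and -2.65 -> -2.7), as opposed to
#' [base::round()]'s round-half-even. Internal computations always keep full
#' precision; this is applied only when values are displayed or reported.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return rounded numeric vector.
#' @export
round_half_out <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
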