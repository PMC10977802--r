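# Acoustic and thermal tissue property containers.
#
# Acoustic attenuation follows a power law alpha(f) = alpha1 * f^eta with
# alpha1 in dB/cm at 1 MHz; only a configurable fraction of the attenuated
# energy is absorbed (converted to heat), the rest is scattered out of the
# beam.

#' Homogeneous acoustic medium
#'
#' @param c sound speed, m/s.
#' @param rho density, kg/m3.
#' @param alpha attenuation coefficient at 1 MHz, dB/cm.
#' @param alpha_exponent power-law frequency exponent.
#' @param absorption_fraction fraction of attenuation converted to heat,
#'   in (0, 1].
#' @return an object of class `acoustic_medium`.
#' @examples
#' water_medium()
#' acoustic_medium(c = 1540, rho = 1050, alpha = 0.5)
#' @export
acoustic_medium <- function(c = 1482, rho = 994, alpha = 0.002,
                            alpha_exponent = 1.1, absorption_fraction = 0.9) {
  if (c <= 0 || rho <= 0) stop("sound speed and density must be positive")
  if (alpha < 0) stop("attenuation coefficient must be non-negative")
  if (absorption_fraction <= 0 || absorption_fraction > 1)
    stop("absorption_fraction must lie in (0, 1]")
  structure(list(c = c, rho = rho, alpha = alpha,
                 alpha_exponent = alpha_exponent,
                 absorption_fraction = absorption_fraction),
            class = "acoustic_medium")
}

#' Degassed water at body-contact temperature
#' @param lossless if TRUE, set attenuation to zero (oracle comparisons).
#' @return an `acoustic_medium`.
#' @export
water_medium <- function(lossless = FALSE) {
  acoustic_medium(c = 1482, rho = 994,
                  alpha = if (lossless) 0 else 0.002,
                  alpha_exponent = 2, absorption_fraction = 1)
}

# attenuation of a medium at frequency f (MHz), Np/mm
attenuation_np_mm <- function(medium, f_mhz) {
  db_cm_to_np_mm(medium$alpha * f_mhz^medium$alpha_exponent)
}

# absorbed (heat-generating) attenuation at f, Np/m
absorption_np_m <- function(medium, f_mhz) {
  db_cm_to_np_m(medium$alpha * f_mhz^medium$alpha_exponent) *
    medium$absorption_fraction
}

#' Layered beam path from transducer to target
#'
#' A stack of plane-parallel tissue slabs perpendicular to the beam axis.
#' `z_start` gives the depth (mm from the transducer vertex) at which each
#' layer begins; the last layer extends to the end of the domain. The default
#' path is a water standoff, 10 mm subcutaneous fat, 15 mm abdominal muscle,
#' then myometrium containing the focus (literature-typical soft-tissue
#' properties; every value is configurable).
#'
#' @param layers a data.frame with columns `name`, `z_start`, `c`, `rho`,
#'   `alpha`, `alpha_exponent`, `absorption_fraction`.
#' @return an object of class `beam_path`.
#' @export
beam_path <- function(layers = NULL) {
  if (is.null(layers)) {
    layers <- data.frame(
      name    = c("water", "fat", "muscle", "myometrium"),
      z_start = c(0, 90, 100, 115),
      c       = c(1482, 1450, 1580, 1540),
      rho     = c(994, 950, 1050, 1050),
      alpha   = c(0.002, 0.48, 0.74, 0.50),
      alpha_exponent = c(2, 1.1, 1.1, 1.1),
      absorption_fraction = c(1, 0.9, 0.9, 0.9),
      stringsAsFactors = FALSE)
  }
  if (is.unsorted(layers$z_start)) stop("layer z_start must be increasing")
  if (layers$z_start[1] != 0) stop("first layer must start at z = 0")
  structure(layers, class = c("beam_path", "data.frame"))
}

# medium of the layer containing depth z (mm)
medium_at_depth <- function(path, z) {
  i <- findInterval(z, path$z_start)
  i <- max(1L, min(nrow(path), i))
  acoustic_medium(c = path$c[i], rho = path$rho[i], alpha = path$alpha[i],
                  alpha_exponent = path$alpha_exponent[i],
                  absorption_fraction = path$absorption_fraction[i])
}

#' Thermal tissue properties for the Pennes bioheat model
#'
#' The perfusion rate `w_b` is the Pennes blood-flow coefficient; following
#' the modelling premise of the package, fibroid-like tissue is assigned
#' skeletal-muscle perfusion and adenomyotic tissue the (higher) uterine
#' myometrium perfusion. `w_b` may be a scalar or a voxel array.
#'
#' @param k thermal conductivity, W/(m K).
#' @param rho tissue density, kg/m3.
#' @param c_p tissue specific heat, J/(kg K).
#' @param w_b blood perfusion rate, kg/(m3 s); scalar or array.
#' @param c_b blood specific heat, J/(kg K).
#' @param T_a arterial (baseline) temperature, degrees C.
#' @return an object of class `thermal_tissue`.
#' @examples
#' thermal_tissue(w_b = perfusion_defaults()["myometrium"])
#' @export
thermal_tissue <- function(k = 0.56, rho = 1050, c_p = 3600,
                           w_b = 2.5, c_b = 3617, T_a = 37) {
  if (k <= 0 || rho <= 0 || c_p <= 0 || c_b <= 0)
    stop("k, rho, c_p and c_b must be positive")
  if (any(w_b < 0)) stop("perfusion rate w_b must be non-negative")
  if (T_a < 30 || T_a > 40)
    stop("arterial temperature T_a must lie in [30, 40] degrees C")
  structure(list(k = k, rho = rho, c_p = c_p, w_b = w_b, c_b = c_b, T_a = T_a),
            class = "thermal_tissue")
}

#' Default perfusion rates by tissue identification
#'
#' Fibroid tissue is identified with skeletal muscle and adenomyosis with
#' uterine myometrium (the brighter, better-perfused tissue on T2-weighted
#' imaging); the numeric rates are declared, configurable defaults.
#'
#' @return named numeric vector, kg/(m3 s).
#' @export
perfusion_defaults <- function() c(muscle = 0.7, myometrium = 2.5)
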