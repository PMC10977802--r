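# Linear acoustic field computation: Rayleigh-Sommerfeld summation from the
# discretized bowl, and plane-to-plane angular-spectrum propagation.
#
# Time convention exp(+i w t), outgoing waves exp(-i k r); the complex
# wavenumber k - i*alpha folds attenuation into the phase factor.

#' Rayleigh-Sommerfeld pressure at arbitrary target points
#'
#' Sums the Rayleigh-Sommerfeld kernel over the bowl sub-elements:
#' \deqn{p(x) = \frac{i \rho c k}{2\pi} \sum_e u_e A_e
#'   \frac{e^{-i \hat k r_e}}{r_e}}
#' with \eqn{\hat k = k - i\alpha} the complex wavenumber of the
#' (homogeneous) medium and \eqn{u_e, A_e} the element drive and area.
#' The field is linear in the drive. Layered media are handled by the hybrid
#' driver [simulate_field()], which restricts the Rayleigh stage to the first
#' layer.
#'
#' @param geometry a `hifu_array` from [discretize_bowl()].
#' @param medium an `acoustic_medium` (homogeneous along source-target rays).
#' @param targets numeric matrix (n x 3) of target positions, mm.
#' @return complex pressure (Pa) vector of length `nrow(targets)`.
#' @examples
#' bowl <- discretize_bowl(60, 24, 1, max_subelement = 0.74)
#' p <- rs_pressure(bowl, water_medium(lossless = TRUE),
#'                  cbind(0, 0, c(50, 60, 70)))
#' abs(p)
#' @export
rs_pressure <- function(geometry, medium, targets) {
  if (is.numeric(targets) && is.null(dim(targets)) && length(targets) == 3)
    targets <- matrix(targets, 1)
  stopifnot(is.matrix(targets), ncol(targets) == 3)
  el <- geometry$elements
  f <- geometry$center_frequency
  k <- 2 * pi / wavelength_mm(medium$c, f)          # 1/mm
  kc <- complex(real = k, imaginary = -attenuation_np_mm(medium, f))
  pref <- 1i * medium$rho * medium$c * k / (2 * pi)
  w <- geometry$drive * el$area                      # u_e * A_e
  nt <- nrow(targets)
  ne <- nrow(el)
  p <- complex(nt)
  chunk <- max(1L, floor(4e6 / ne))
  for (i0 in seq(1L, nt, by = chunk)) {
    idx <- i0:min(nt, i0 + chunk - 1L)
    dx <- outer(el$x, targets[idx, 1], "-")
    dy <- outer(el$y, targets[idx, 2], "-")
    dz <- outer(el$z, targets[idx, 3], "-")
    r <- sqrt(dx * dx + dy * dy + dz * dz)
    if (any(r < 1e-6))
      stop("singular kernel: a target coincides with an element centre")
    p[idx] <- pref * colSums(w * exp(-1i * kc * r) / r)
  }
  p
}

#' Rayleigh-Sommerfeld pressure on a transverse plane
#'
#' @param geometry a `hifu_array`.
#' @param medium an `acoustic_medium`.
#' @param x,y transverse sample coordinates (mm), regular grids.
#' @param z axial plane position, mm (in front of the source).
#' @return an `acoustic_plane`: list with complex matrix `p` (nx x ny),
#'   coordinates `x`, `y`, scalar `z`, and `frequency` (MHz).
#' @export
rs_plane <- function(geometry, medium, x, y, z) {
  targets <- cbind(rep(x, times = length(y)),
                   rep(y, each = length(x)), z)
  p <- matrix(rs_pressure(geometry, medium, targets),
              nrow = length(x), ncol = length(y))
  structure(list(p = p, x = x, y = y, z = z,
                 frequency = geometry$center_frequency),
            class = "acoustic_plane")
}

# 2*pi*fftfreq for an n-point grid of spacing dx (rad/mm)
k_grid <- function(n, dx) {
  j <- c(seq(0L, floor(n / 2) - 1L), seq(-ceiling(n / 2), -1L))
  2 * pi * j / (n * dx)
}

#' Angular-spectrum propagation of a transverse plane
#'
#' Propagates a monochromatic pressure plane forward by `dz` through a
#' homogeneous medium: the field is decomposed into plane waves with a 2-D
#' FFT, each component advanced by \eqn{e^{-i k_z dz}} with
#' \eqn{k_z = \sqrt{\hat k^2 - k_x^2 - k_y^2}} (complex \eqn{\hat k}
#' carrying attenuation), and recomposed. Evanescent components
#' (\eqn{k_x^2 + k_y^2 > k^2}) are hard-truncated; the grid is zero-padded
#' (factor `pad_factor`) to suppress wraparound. An optional angular
#' restriction filter removes components beyond `max_angle` degrees.
#'
#' @param plane an `acoustic_plane` (from [rs_plane()] or a previous step).
#' @param dz forward step, mm (must be >= 0).
#' @param medium an `acoustic_medium` for the slab being traversed.
#' @param pad_factor zero-padding factor (default 2).
#' @param max_angle optional angular restriction, degrees from the axis
#'   (default `NULL`, off).
#' @return an `acoustic_plane` at `z + dz`.
#' @export
asa_propagate <- function(plane, dz, medium, pad_factor = 2,
                          max_angle = NULL) {
  if (dz < 0) stop("backward propagation (dz < 0) is not supported")
  if (dz == 0) return(plane)
  nx <- length(plane$x); ny <- length(plane$y)
  dx <- plane$x[2] - plane$x[1]; dy <- plane$y[2] - plane$y[1]
  npx <- ceiling(pad_factor * nx); npy <- ceiling(pad_factor * ny)
  pp <- matrix(0i, npx, npy)
  pp[seq_len(nx), seq_len(ny)] <- plane$p
  f <- plane$frequency
  k <- 2 * pi / wavelength_mm(medium$c, f)
  kc <- complex(real = k, imaginary = -attenuation_np_mm(medium, f))
  kx <- k_grid(npx, dx); ky <- k_grid(npy, dy)
  krho2 <- outer(kx^2, ky^2, "+")
  kz2 <- kc^2 - krho2
  H <- exp(-1i * sqrt(kz2) * dz)
  H[Re(kz2) <= 0] <- 0i                     # evanescent truncation
  if (!is.null(max_angle)) {
    kmax <- k * sin(max_angle * pi / 180)
    H[krho2 > kmax^2] <- 0i
  }
  P <- stats::fft(pp) * H
  out <- stats::fft(P, inverse = TRUE) / (npx * npy)
  plane$p <- out[seq_len(nx), seq_len(ny)]
  plane$z <- plane$z + dz
  plane
}

#' Simulate the acoustic field of a bowl in (optionally layered) tissue
#'
#' Hybrid field driver: the Rayleigh-Sommerfeld integral is evaluated once
#' onto an initial transverse plane at `z_plane` (inside the first layer),
#' and the field is then marched plane-by-plane through the volume with the
#' angular spectrum approach, using the local layer's sound speed and
#' attenuation for each step.
#'
#' @param geometry a `hifu_array`.
#' @param medium an `acoustic_medium` for a homogeneous run, or a
#'   `beam_path` of layers.
#' @param z_range axial extent `c(z_min, z_max)` of the output volume, mm.
#' @param lateral_halfwidth transverse half-extent of the output grid, mm.
#' @param spacing grid spacing, mm (isotropic).
#' @param z_plane position of the initial Rayleigh plane, mm; defaults to
#'   `z_range[1]`.
#' @param pad_factor FFT zero-padding factor for the spectral steps.
#' @param max_angle optional angular restriction filter, degrees.
#' @return a `pressure_field`: list with complex array `p` (nx, ny, nz),
#'   coordinate vectors `x`, `y`, `z` (mm) and `frequency` (MHz).
#' @examples
#' bowl <- discretize_bowl(60, 24, 1)
#' fld <- simulate_field(bowl, water_medium(), z_range = c(55, 65),
#'                       lateral_halfwidth = 5, spacing = 0.5)
#' dim(fld$p)
#' @export
simulate_field <- function(geometry, medium = beam_path(),
                           z_range = geometry$focal_length + c(-15, 15),
                           lateral_halfwidth = 10, spacing = 0.5,
                           z_plane = NULL, pad_factor = 2, max_angle = NULL) {
  layered <- inherits(medium, "beam_path")
  if (is.null(z_plane)) z_plane <- z_range[1]
  if (z_plane > z_range[1] + 1e-9)
    stop("z_plane must not lie beyond the start of z_range")
  first_med <- if (layered) medium_at_depth(medium, z_plane) else medium
  x <- seq(-lateral_halfwidth, lateral_halfwidth, by = spacing)
  zs <- seq(z_range[1], z_range[2], by = spacing)
  plane <- rs_plane(geometry, first_med, x, x, z_plane)
  p <- array(0i, c(length(x), length(x), length(zs)))
  for (i in seq_along(zs)) {
    dz <- zs[i] - plane$z
    if (dz > 1e-12) {
      med <- if (layered) medium_at_depth(medium, plane$z + dz / 2) else medium
      plane <- asa_propagate(plane, dz, med, pad_factor = pad_factor,
                             max_angle = max_angle)
    }
    p[, , i] <- plane$p
  }
  structure(list(p = p, x = x, y = x, z = zs,
                 frequency = geometry$center_frequency),
            class = "pressure_field")
}

#' @export
print.pressure_field <- function(x, ...) {
  cat(sprintf(paste0("Complex pressure field: %d x %d x %d grid, ",
                     "spacing %.3g mm\n  peak |p| = %.3g MPa at z = %.1f mm\n"),
              length(x$x), length(x$y), length(x$z), x$x[2] - x$x[1],
              max(abs(x$p)) / 1e6,
              x$z[which(apply(abs(x$p), 3, max) ==
                          max(abs(x$p)))[1]]))
  invisible(x)
}

#' Time-averaged acoustic intensity from a pressure field
#'
#' Plane-wave relation \eqn{I = |p|^2 / (2 \rho c)}, reported in W/cm2.
#'
#' @param field a `pressure_field` or `acoustic_plane`.
#' @param medium an `acoustic_medium` providing rho and c (scalars or arrays
#'   congruent with the grid).
#' @return an `intensity_field`: list with array `I` (W/cm2) and the grid
#'   coordinates of `field`.
#' @export
intensity_field <- function(field, medium) {
  I <- abs(field$p)^2 / (2 * medium$rho * medium$c) / 1e4   # W/m2 -> W/cm2
  structure(list(I = I, x = field$x, y = field$y, z = field$z),
            class = "intensity_field")
}

#' Scale the array drive to a target spatial-peak focal intensity
#'
#' Computes the field around the focus, finds its spatial-peak intensity
#' and rescales every element drive by \eqn{\sqrt{I_{target}/I_{peak}}} so
#' that the recomputed peak equals the target. By linearity the result is
#' exact; the achieved peak is stored in the returned geometry's
#' `calibration` attribute. The target is interpreted as the spatial-peak,
#' pulse-average (on-time) focal intensity in situ.
#'
#' @param geometry a `hifu_array`.
#' @param medium an `acoustic_medium` or `beam_path`.
#' @param target_intensity target spatial-peak intensity, kW/cm2.
#' @param ... grid arguments passed to [simulate_field()].
#' @param field optional precomputed `pressure_field` for this geometry
#'   (avoids recomputation).
#' @return the geometry with scaled `drive`.
#' @export
calibrate_focal_intensity <- function(geometry, medium, target_intensity,
                                      ..., field = NULL) {
  if (target_intensity <= 0) stop("target intensity must be positive")
  if (all(abs(geometry$drive) == 0))
    stop("cannot calibrate: all element drives are zero")
  if (is.null(field)) field <- simulate_field(geometry, medium, ...)
  med <- if (inherits(medium, "beam_path"))
    medium_at_depth(medium, geometry$focal_length) else medium
  peak_kw <- max(intensity_field(field, med)$I) / 1000   # W/cm2 -> kW/cm2
  scale <- sqrt(target_intensity / peak_kw)
  geometry$drive <- geometry$drive * scale
  attr(geometry, "calibration") <-
    list(target_kw_cm2 = target_intensity, scale = scale,
         achieved_kw_cm2 = peak_kw * scale^2)
  geometry
}
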