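# Focused-bowl source discretization.
#
# Coordinate convention: the beam axis is z, the bowl vertex sits at
# (0, 0, 0) and the geometric focus (centre of curvature) at
# (0, 0, focal_length). All positions in mm.

#' Discretize a focused spherical-cap (bowl) transducer
#'
#' Tiles the spherical cap of a focused bowl into quasi-uniform sub-elements
#' arranged in polar rings. Ring areas are computed from the exact
#' spherical-zone formula and divided equally among the ring's elements, so
#' the summed element area equals the analytic cap area
#' \eqn{2\pi R (R - \sqrt{R^2 - a^2})} to machine precision. Every element
#' centre lies exactly on the sphere of radius `focal_length` about the
#' focus; element normals point at the focus.
#'
#' @param focal_length radius of curvature / focal length R, mm.
#' @param aperture_radius bowl rim radius a, mm; must be < `focal_length`.
#' @param center_frequency drive frequency, MHz.
#' @param max_subelement target sub-element pitch, mm. Must not exceed half
#'   a wavelength in water at `center_frequency` (sampling requirement for
#'   the Rayleigh-Sommerfeld summation).
#' @param drive per-element complex drive (normal velocity amplitude, m/s);
#'   scalar recycled to all elements. Default 1.
#' @return an object of class `hifu_array`: list with `focal_length`,
#'   `aperture_radius`, `center_frequency`, `elements` (data.frame
#'   x, y, z, nx, ny, nz, area) and `drive` (complex vector).
#' @examples
#' bowl <- discretize_bowl(130, 64, 1, max_subelement = 0.74)
#' bowl
#' @export
discretize_bowl <- function(focal_length, aperture_radius, center_frequency,
                            max_subelement = NULL, drive = 1) {
  if (!is.numeric(focal_length) || focal_length <= 0 ||
      !is.numeric(aperture_radius) || aperture_radius <= 0)
    stop("invalid geometry: focal_length and aperture_radius must be positive")
  if (aperture_radius >= focal_length)
    stop("invalid geometry: aperture_radius must be smaller than focal_length")
  if (center_frequency <= 0)
    stop("invalid geometry: center_frequency must be positive")
  lam_w <- wavelength_mm(1482, center_frequency)
  if (is.null(max_subelement)) max_subelement <- lam_w / 2
  if (max_subelement > lam_w / 2 + 1e-12)
    stop(sprintf(paste0("max_subelement = %.3f mm is too coarse: it must not",
                        " exceed half a wavelength in water (%.3f mm) at ",
                        "%.2f MHz"), max_subelement, lam_w / 2,
                 center_frequency))

  R <- focal_length
  theta_a <- asin(aperture_radius / R)
  n_rings <- max(1L, ceiling(R * theta_a / max_subelement))
  dth <- theta_a / n_rings
  xs <- ys <- zs <- areas <- vector("list", n_rings)
  for (j in seq_len(n_rings)) {
    th0 <- (j - 1) * dth; th1 <- j * dth
    thc <- (th0 + th1) / 2
    ring_area <- 2 * pi * R^2 * (cos(th0) - cos(th1))  # exact spherical zone
    n_j <- max(1L, round(2 * pi * R * sin(thc) / max_subelement))
    phi <- (seq_len(n_j) - 0.5) * 2 * pi / n_j
    xs[[j]] <- R * sin(thc) * cos(phi)
    ys[[j]] <- R * sin(thc) * sin(phi)
    zs[[j]] <- rep(R - R * cos(thc), n_j)
    areas[[j]] <- rep(ring_area / n_j, n_j)
  }
  x <- unlist(xs); y <- unlist(ys); z <- unlist(zs); area <- unlist(areas)
  # unit normals point from the element towards the focus (0, 0, R)
  nx <- -x / R; ny <- -y / R; nz <- (R - z) / R
  elements <- data.frame(x = x, y = y, z = z, nx = nx, ny = ny, nz = nz,
                         area = area)
  drive <- rep_len(as.complex(drive), nrow(elements))
  structure(list(focal_length = focal_length,
                 aperture_radius = aperture_radius,
                 center_frequency = center_frequency,
                 elements = elements, drive = drive),
            class = "hifu_array")
}

#' @export
print.hifu_array <- function(x, ...) {
  cap <- 2 * pi * x$focal_length *
    (x$focal_length - sqrt(x$focal_length^2 - x$aperture_radius^2))
  cat(sprintf(paste0("Focused bowl array: F = %g mm, a = %g mm, f0 = %g MHz\n",
                     "  %d sub-elements, total area %.1f mm^2 ",
                     "(analytic cap %.1f mm^2)\n"),
              x$focal_length, x$aperture_radius, x$center_frequency,
              nrow(x$elements), sum(x$elements$area), cap))
  invisible(x)
}

# geometric focus position, mm
focus_position <- function(geometry) c(0, 0, geometry$focal_length)
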