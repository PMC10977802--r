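# Voxelized tissue phantom: acoustic + thermal property grids with a
# labelled ellipsoidal lesion.

#' Generate a tissue phantom with an ellipsoidal lesion
#'
#' Builds congruent voxel grids of acoustic and thermal properties on a
#' domain centred at the origin, with an ellipsoidal lesion at the centre.
#' The background is myometrium-like tissue; the lesion's perfusion rate is
#' set by the scenario: `"adenomyosis-myometrium"` assigns the uterine
#' myometrium perfusion default, `"fibroid-muscle"` the skeletal muscle
#' default (see [perfusion_defaults()]). Generation is fully deterministic.
#'
#' @param domain domain edge lengths `c(Lx, Ly, Lz)`, mm.
#' @param voxel isotropic voxel size, mm.
#' @param lesion_semiaxes ellipsoid semi-axes `c(ax, ay, az)`, mm.
#' @param scenario `"adenomyosis-myometrium"` or `"fibroid-muscle"`.
#' @param clearance minimum distance between lesion surface and domain
#'   boundary, mm (default 5).
#' @param background_medium acoustic background, an `acoustic_medium`
#'   (default myometrium-like).
#' @param background_thermal thermal background, a `thermal_tissue` whose
#'   scalar `w_b` is used outside the lesion.
#' @return a `tissue_phantom`: list with coordinate vectors `x`, `y`, `z`
#'   (mm), `voxel`, `acoustic`, `thermal` (with voxel-array `w_b`),
#'   `lesion_mask` (logical array) and `scenario`.
#' @examples
#' ph <- generate_phantom(domain = c(30, 30, 30), voxel = 1,
#'                        lesion_semiaxes = c(8, 8, 8))
#' sum(ph$lesion_mask) * ph$voxel^3 / 1000  # lesion volume, cm3
#' @export
generate_phantom <- function(domain = c(40, 40, 40), voxel = 0.5,
                             lesion_semiaxes = c(10, 10, 10),
                             scenario = c("adenomyosis-myometrium",
                                          "fibroid-muscle"),
                             clearance = 5,
                             background_medium =
                               acoustic_medium(c = 1540, rho = 1050,
                                               alpha = 0.5),
                             background_thermal = thermal_tissue(w_b = 2.5)) {
  scenario <- match.arg(scenario)
  if (any(lesion_semiaxes <= 0)) stop("lesion semi-axes must be positive")
  if (voxel > min(lesion_semiaxes))
    stop("voxel size exceeds the smallest lesion semi-axis; refine the grid")
  if (any(lesion_semiaxes + clearance > domain / 2))
    stop(sprintf("lesion does not fit in the domain with %g mm clearance",
                 clearance))
  ax <- lesion_semiaxes
  coords <- lapply(domain, function(L) {
    n <- 2 * floor(L / (2 * voxel)) + 1          # odd count, voxel at origin
    seq(-(n - 1) / 2, (n - 1) / 2) * voxel
  })
  x <- coords[[1]]; y <- coords[[2]]; z <- coords[[3]]
  d2 <- outer(outer((x / ax[1])^2, (y / ax[2])^2, "+"), (z / ax[3])^2, "+")
  mask <- d2 <= 1
  wb <- perfusion_defaults()
  lesion_wb <- if (scenario == "adenomyosis-myometrium") wb[["myometrium"]]
  else wb[["muscle"]]
  w_b <- array(background_thermal$w_b, dim(mask))
  w_b[mask] <- lesion_wb
  thermal <- background_thermal
  thermal$w_b <- w_b
  structure(list(x = x, y = y, z = z, voxel = voxel,
                 acoustic = background_medium, thermal = thermal,
                 lesion_mask = mask, lesion_semiaxes = ax,
                 scenario = scenario),
            class = "tissue_phantom")
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat(sprintf(paste0("Tissue phantom (%s): %d x %d x %d voxels at %g mm\n",
                     "  lesion: %.1f cm3 (%d voxels), lesion w_b = %g, ",
                     "background w_b = %g kg/(m3 s)\n"),
              x$scenario, length(x$x), length(x$y), length(x$z), x$voxel,
              sum(x$lesion_mask) * x$voxel^3 / 1000, sum(x$lesion_mask),
              x$thermal$w_b[which(x$lesion_mask)[1]],
              x$thermal$w_b[1]))
  invisible(x)
}
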