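# Independent oracles and shared small fixtures for the test suite.

# O'Neil closed-form on-axis pressure magnitude of a uniformly driven
# focused spherical cap (radius of curvature F, rim radius a) in a lossless
# medium. Derived directly from the Rayleigh surface integral over the cap:
# with zeta = z - F, p = rho c u0 (F/zeta) (e^{-ik r_rim} - e^{-ik r_vertex})
# where r_vertex = F + zeta and r_rim is the distance to the cap rim; at the
# focus the limit is rho c u0 k F (1 - cos theta_a). Implemented only here;
# never used by package code.
oneil_axis_pressure <- function(F, a, f_mhz, c, rho, u0, z) {
  k <- 2 * pi / (c / (f_mhz * 1000))     # 1/mm
  th <- asin(a / F)
  vapply(z - F, function(zz) {
    if (abs(zz) < 1e-9) return(rho * c * u0 * k * F * (1 - cos(th)))
    r_rim <- sqrt(F^2 + zz^2 + 2 * F * zz * cos(th))
    abs(rho * c * u0 * (F / zz) *
          (exp(-1i * k * r_rim) - exp(-1i * k * (F + zz))))
  }, numeric(1))
}

# brute-force enumeration of the sonication lattice: triple loop over the
# bounding box, ellipsoid membership, deep-margin slab exclusion, then
# shallow-to-deep / boustrophedon ordering -- written independently of
# plan_grid()
brute_force_plan <- function(center, semiaxes, spacing, margin) {
  zmax <- center[3] + semiaxes[3] - margin
  pts <- list()
  rng <- function(i) center[i] +
    spacing * (-ceiling(semiaxes[i] / spacing)):(ceiling(semiaxes[i] / spacing))
  for (z in sort(rng(3))) {
    if (z > zmax + 1e-9) next
    row_i <- 0
    for (y in sort(rng(2))) {
      xs <- sort(rng(1))
      keep <- c()
      for (x in xs) {
        if (((x - center[1]) / semiaxes[1])^2 +
            ((y - center[2]) / semiaxes[2])^2 +
            ((z - center[3]) / semiaxes[3])^2 <= 1)
          keep <- c(keep, x)
      }
      if (length(keep) == 0) next
      if (row_i %% 2 == 1) keep <- rev(keep)
      row_i <- row_i + 1
      for (x in keep) pts[[length(pts) + 1]] <- c(x, y, z)
    }
  }
  if (length(pts) == 0) return(NULL)
  m <- do.call(rbind, pts)
  data.frame(order = seq_len(nrow(m)), x = m[, 1], y = m[, 2], z = m[, 3])
}

# memoized small fixtures shared across treatment-level tests
.fixture_env <- new.env()

small_template <- function() {
  if (is.null(.fixture_env$tpl))
    .fixture_env$tpl <- focal_intensity_template(
      spacing = 0.5, lateral_halfwidth = 7, axial_halfwidth = 9)
  .fixture_env$tpl
}

small_phantom <- function(scenario = "adenomyosis-myometrium") {
  generate_phantom(domain = c(22, 22, 26), voxel = 0.5,
                   lesion_semiaxes = c(5, 5, 7), scenario = scenario)
}

centre_point_plan <- function(params)
  plan_grid(lesion_ellipsoid(c(1, 1, 1)), params, deep_margin = 0)
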