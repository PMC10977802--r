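med_w <- water_medium(lossless = TRUE)

test_that("on-axis Rayleigh-Sommerfeld pressure matches the O'Neil closed form", {
  bowl <- discretize_bowl(60, 24, 1, max_subelement = 0.37)
  z <- seq(30, 90, length.out = 31)
  p <- abs(rs_pressure(bowl, med_w, cbind(0, 0, z)))
  p_ref <- oneil_axis_pressure(60, 24, 1, med_w$c, med_w$rho, 1, z)
  expect_lt(max(abs(p - p_ref) / p_ref), 0.01)
})

test_that("the field is linear and superposable in the element drive", {
  bowl <- discretize_bowl(40, 15, 1, max_subelement = 0.7)
  targets <- cbind(c(0, 1, -2), c(0, 0.5, 1), c(35, 40, 45))
  p1 <- rs_pressure(bowl, med_w, targets)
  bowl2 <- bowl; bowl2$drive <- bowl$drive * 2
  expect_equal(abs(rs_pressure(bowl2, med_w, targets)), 2 * abs(p1),
               tolerance = 1e-12)
  # superposition of two random drive patterns
  set.seed(11)
  n <- nrow(bowl$elements)
  da <- complex(real = rnorm(n), imaginary = rnorm(n))
  db <- complex(real = rnorm(n), imaginary = rnorm(n))
  ba <- bowl; ba$drive <- da
  bb <- bowl; bb$drive <- db
  bs <- bowl; bs$drive <- da + db
  expect_equal(rs_pressure(bs, med_w, targets),
               rs_pressure(ba, med_w, targets) +
                 rs_pressure(bb, med_w, targets), tolerance = 1e-10)
})

test_that("attenuation strictly reduces focal pressure", {
  bowl <- discretize_bowl(40, 15, 1, max_subelement = 0.7)
  focus <- cbind(0, 0, 40)
  p0 <- abs(rs_pressure(bowl, med_w, focus))
  p1 <- abs(rs_pressure(bowl, acoustic_medium(c = 1482, rho = 994,
                                              alpha = 0.5), focus))
  expect_lt(p1, p0)
})

test_that("a target on an element centre raises a singular-kernel error", {
  bowl <- discretize_bowl(40, 15, 1, max_subelement = 0.7)
  el <- bowl$elements[1, ]
  expect_error(rs_pressure(bowl, med_w, cbind(el$x, el$y, el$z)), "singular")
})

test_that("angular-spectrum propagation: identity, refusal, semigroup", {
  # smooth focused Gaussian beam, compact within the window
  x <- seq(-12, 12, by = 0.5)
  r2 <- outer(x^2, x^2, "+")
  p0 <- exp(-r2 / (2 * 2^2)) + 0i
  pl <- structure(list(p = p0, x = x, y = x, z = 0, frequency = 1),
                  class = "acoustic_plane")
  expect_identical(asa_propagate(pl, 0, med_w)$p, pl$p)
  expect_error(asa_propagate(pl, -1, med_w), "backward")
  one <- asa_propagate(pl, 2, med_w)
  two <- asa_propagate(asa_propagate(pl, 1, med_w), 1, med_w)
  expect_lt(max(abs(one$p - two$p)) / max(abs(one$p)), 1e-6)
})

test_that("intensity follows I = |p|^2 / (2 rho c) in W/cm2", {
  med <- acoustic_medium(c = 1482, rho = 994, alpha = 0)
  fld <- list(p = array(c(0, 1, 2, 1i), c(2, 2, 1)))
  I <- intensity_field(fld, med)$I
  expect_identical(I[1, 1, 1], 0)
  expect_equal(I[2, 1, 1], 1 / (2 * 994 * 1482) / 1e4)   # 1 Pa
  expect_equal(I[1, 2, 1] / I[2, 1, 1], 4)               # doubling p
  expect_equal(I[2, 2, 1], I[2, 1, 1])                   # phase-independent
})

test_that("focal-intensity calibration hits its target and is idempotent", {
  bowl <- discretize_bowl(60, 24, 1, max_subelement = 0.7)
  med <- water_medium()
  args <- list(medium = med, z_range = c(55, 65), lateral_halfwidth = 4,
               spacing = 0.5)
  cal <- do.call(calibrate_focal_intensity,
                 c(list(bowl, target_intensity = 1.0), args["medium"],
                   args[-1]))
  fld <- do.call(simulate_field, c(list(cal), args))
  peak <- max(intensity_field(fld, med)$I) / 1000
  expect_lt(abs(peak - 1.0), 1e-3)
  cal2 <- do.call(calibrate_focal_intensity,
                  c(list(cal, target_intensity = 1.0), args["medium"],
                    args[-1]))
  expect_lt(abs(attr(cal2, "calibration")$scale - 1), 1e-6)
  # square-root amplitude law between the two preset intensities
  cal08 <- do.call(calibrate_focal_intensity,
                   c(list(bowl, target_intensity = 0.8), args["medium"],
                     args[-1]))
  expect_equal(attr(cal08, "calibration")$scale /
                 attr(cal, "calibration")$scale, sqrt(0.8),
               tolerance = 1e-9)
  bowl0 <- bowl; bowl0$drive <- bowl$drive * 0
  expect_error(do.call(calibrate_focal_intensity,
                       c(list(bowl0, target_intensity = 1), args["medium"],
                         args[-1])), "cannot calibrate")
})
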