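test_that("the two protocol presets carry the printed parameter values", {
  a <- sonication_preset("A")
  expect_equal(unlist(a[c("point_interval", "focal_intensity", "duty_cycle",
                          "center_frequency", "prf", "per_point_time",
                          "transition_time")]),
               c(point_interval = 4, focal_intensity = 0.8, duty_cycle = 60,
                 center_frequency = 1.0, prf = 10, per_point_time = 6,
                 transition_time = 3))
  b <- sonication_preset("B")
  expect_equal(unlist(b[c("point_interval", "focal_intensity", "duty_cycle",
                          "center_frequency", "prf", "per_point_time",
                          "transition_time")]),
               c(point_interval = 2, focal_intensity = 1.0, duty_cycle = 70,
                 center_frequency = 1.0, prf = 10, per_point_time = 7,
                 transition_time = 3))
  expect_error(sonication_preset("C"), "valid presets")
  expect_error(sonication_params(4, 0.8, 120, 1, 10, 6, 3), "duty_cycle")
  expect_error(sonication_params(-4, 0.8, 60, 1, 10, 6, 3), "positive")
})

test_that("the planned lattice equals brute-force enumeration", {
  for (case in list(list(ax = c(20, 20, 20), s = 4, m = 10),
                    list(ax = c(1, 1, 1), s = 4, m = 0),
                    list(ax = c(12, 9, 15), s = 2, m = 10))) {
    params <- sonication_params(case$s, 1, 60, 1, 10, 6, 3)
    plan <- plan_grid(lesion_ellipsoid(case$ax), params,
                      deep_margin = case$m)
    ref <- brute_force_plan(c(0, 0, 0), case$ax, case$s, case$m)
    expect_equal(data.frame(order = plan$order, x = plan$x, y = plan$y,
                            z = plan$z), ref)
  }
  # unit sphere at 4 mm spacing holds exactly the centre point
  p1 <- plan_grid(lesion_ellipsoid(c(1, 1, 1)),
                  sonication_params(4, 1, 60, 1, 10, 6, 3), deep_margin = 0)
  expect_equal(nrow(p1), 1L)
  expect_equal(unlist(p1[1, c("x", "y", "z")]), c(x = 0, y = 0, z = 0))
})

test_that("the deep-margin rule excludes the deepest slab of the lesion", {
  plan <- plan_grid(lesion_ellipsoid(c(20, 20, 20)),
                    sonication_preset("A"), deep_margin = 10)
  expect_true(all(plan$z <= 20 - 10 + 1e-9))
  # a lesion thinner than the margin cannot be planned
  expect_error(plan_grid(lesion_ellipsoid(c(10, 10, 4)),
                         sonication_preset("A"), deep_margin = 10),
               "empty plan")
})

test_that("halving the lattice spacing multiplies point count by about 8", {
  les <- lesion_ellipsoid(c(15, 15, 15))
  n4 <- nrow(plan_grid(les, sonication_preset("A"), deep_margin = 0))
  n2 <- nrow(plan_grid(les, sonication_preset("B"), deep_margin = 0))
  expect_gt(n2 / n4, 8 * 0.75)
  expect_lt(n2 / n4, 8 * 1.25)
})

test_that("protocol timing follows n*tp + (n-1)*tt and duty-scaled on-time", {
  tB <- treatment_timing(10, sonication_preset("B"))
  expect_identical(tB$duration_s, 97)
  expect_identical(tB$on_time_s, 49)
  tA <- treatment_timing(5, sonication_preset("A"))
  expect_identical(tA$duration_s, 5 * 6 + 4 * 3)
  expect_identical(tA$on_time_s, 5 * 6 * 0.6)
})

test_that("simulated treatments are deterministic and report timing", {
  ph <- small_phantom()
  tpl <- small_template()
  params <- sonication_preset("B")
  plan <- centre_point_plan(params)
  r1 <- simulate_treatment(plan, params, ph, template = tpl)
  r2 <- simulate_treatment(plan, params, ph, template = tpl)
  expect_identical(r1$dose$cem43, r2$dose$cem43)
  expect_identical(r1$per_point_peak_T, r2$per_point_peak_T)
  expect_equal(r1$duration_s, 7)
  expect_equal(r1$on_time_s, 7 * 0.7)
  expect_lte(r1$on_time_s, r1$duration_s)
  expect_gt(r1$ablated_cm3, 0)
})

test_that("a (near-)zero intensity protocol deposits no dose", {
  ph <- small_phantom()
  params <- sonication_params(4, 1e-12, 60, 1, 10, 6, 3)
  res <- simulate_treatment(centre_point_plan(params), params, ph,
                            template = small_template())
  expect_equal(res$ablated_cm3, 0)
  # only the 37 C baseline accrual remains (0.25^6 equivalent-min per min)
  expect_lt(res$peak_cem43, 1e-3)
})

test_that("longer per-point time strictly increases peak dose", {
  ph <- small_phantom(scenario = "fibroid-muscle")
  tpl <- small_template()
  p6 <- sonication_preset("A")
  p12 <- sonication_params(4, 0.8, 60, 1, 10, 12, 3)
  r6 <- simulate_treatment(centre_point_plan(p6), p6, ph, template = tpl)
  r12 <- simulate_treatment(centre_point_plan(p12), p12, ph, template = tpl)
  expect_gt(r12$peak_cem43, r6$peak_cem43)
})

test_that("explicit PRF pulsing agrees with time-averaged heating", {
  ph <- small_phantom()
  tpl <- small_template()
  params <- sonication_preset("A")
  plan <- centre_point_plan(params)
  ravg <- simulate_treatment(plan, params, ph, template = tpl, dt = 0.02)
  rexp <- simulate_treatment(plan, params, ph, template = tpl,
                             pulsing = "explicit")
  expect_lt(abs(ravg$peak_cem43 - rexp$peak_cem43) / rexp$peak_cem43, 0.05)
  # a step that does not divide the pulse on/off segments is refused
  expect_error(simulate_treatment(plan, params, ph, template = tpl,
                                  pulsing = "explicit", dt = 0.015),
               "incompatible")
})
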