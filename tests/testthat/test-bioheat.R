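test_that("absorption heating converts units correctly", {
  med <- acoustic_medium(c = 1540, rho = 1050, alpha = 1, alpha_exponent = 1,
                         absorption_fraction = 1)
  I <- array(100, c(2, 2, 2))                    # W/cm2
  Q <- heat_source_from_intensity(I, med)
  # alpha = 1 dB/cm -> ln(10)/20 * 100 Np/m; I = 100 W/cm2 = 1e6 W/m2
  expect_equal(Q[1], 2 * (log(10) / 20 * 100) * 1e6)
  expect_true(all(heat_source_from_intensity(array(0, c(2, 2, 2)), med) == 0))
  med2 <- med; med2$absorption_fraction <- 0.5
  expect_equal(heat_source_from_intensity(I, med2)[1], Q[1] / 2)
})

test_that("a source-free domain at arterial temperature stays there", {
  tis <- thermal_tissue(w_b = 2.5)
  h <- pennes_solve(37, 0, tis, h_mm = 0.5, dt = 0.1, duration = 2,
                    dim3 = c(9, 9, 9), stride = 20)
  expect_lt(max(abs(h$final - 37)), 1e-12)
})

test_that("perfusion-only cooling follows the exponential closed form", {
  tis <- thermal_tissue(k = 1e-12, w_b = 2.5)     # conduction switched off
  rate <- tis$w_b * tis$c_b / (tis$rho * tis$c_p)
  t_end <- round(3 / rate)
  h <- pennes_solve(47, 0, tis, h_mm = 1, dt = 0.25, duration = t_end,
                    dim3 = c(7, 7, 7), stride = 1e6)
  num <- h$final[4, 4, 4] - 37
  ana <- 10 * exp(-rate * t_end)
  expect_lt(abs(num - ana) / ana, 1e-3)
})

test_that("conduction spreads a Gaussian with the heat-kernel variance law", {
  tis <- thermal_tissue(w_b = 0)
  alpha <- tis$k / (tis$rho * tis$c_p) * 1e6      # mm2/s
  n <- 41; h_mm <- 0.5; s0 <- 2
  co <- (seq_len(n) - (n + 1) / 2) * h_mm
  r2 <- outer(outer(co^2, co^2, "+"), co^2, "+")
  T0 <- 37 + 5 * exp(-r2 / (2 * s0^2))
  t_d <- round(s0^2 / alpha / 0.1) * 0.1          # one diffusion time
  h <- pennes_solve(T0, 0, tis, h_mm = h_mm, dt = 0.1, duration = t_d,
                    stride = 1e6)
  peak_ana <- 5 * (s0^2 / (s0^2 + 2 * alpha * t_d))^(3 / 2)
  expect_lt(abs(max(h$final) - 37 - peak_ana) / peak_ana, 0.01)
})

test_that("an unstable explicit step is refused with a suggestion", {
  tis <- thermal_tissue()
  dtmax <- 1050 * 3600 / (6 * 0.56 / (0.5e-3)^2 + 2.5 * 3617)
  expect_error(pennes_solve(37, 0, tis, h_mm = 0.5, dt = 2 * dtmax,
                            duration = 1, dim3 = c(5, 5, 5)),
               "unstable.*use dt")
})

test_that("source-free conduction obeys the discrete maximum principle", {
  set.seed(4)
  tis <- thermal_tissue(w_b = 0)
  T0 <- array(37 + runif(11^3, 0, 8), c(11, 11, 11))
  h <- pennes_solve(T0, 0, tis, h_mm = 0.5, dt = 0.01, duration = 0.5,
                    stride = 5)
  for (s in h$snapshots) expect_lte(max(s), max(T0) + 1e-12)
})

test_that("CEM43 matches hand-computed doses and is additive", {
  mk <- function(T, n = 1) replicate(n, array(T, c(2, 2, 2)), simplify = FALSE)
  expect_equal(cem43_accumulate(mk(43), dt_min = 10)$cem43[1], 10)
  expect_equal(cem43_accumulate(mk(44), dt_min = 1)$cem43[1], 2)
  expect_equal(cem43_accumulate(mk(41), dt_min = 4)$cem43[1], 4 * 0.25^2)
  # additivity: dose of a split history equals the whole-history dose
  set.seed(9)
  temps <- lapply(1:6, function(i) array(40 + runif(8, 0, 8), c(2, 2, 2)))
  whole <- cem43_accumulate(temps, dt_min = 0.5)
  part <- cem43_accumulate(temps[4:6], dt_min = 0.5,
                           dose = cem43_accumulate(temps[1:3], dt_min = 0.5))
  expect_identical(part$cem43, whole$cem43)
  expect_error(cem43_accumulate(temps), "dt_min")
})

test_that("ablated volume counts voxels at or above the threshold", {
  dims <- c(10, 10, 10)
  zero <- structure(list(cem43 = array(0, dims), threshold = 240),
                    class = "dose_field")
  expect_equal(ablated_volume(zero, 1), 0)
  full <- zero; full$cem43[] <- 480
  expect_equal(ablated_volume(full, 1), 1.0)          # 1000 mm3 = 1 cm3
  half <- zero
  half$cem43[1:500] <- 240; half$cem43[501:1000] <- 120
  expect_equal(ablated_volume(half, 1), 0.5)          # threshold inclusive
})

test_that("dose grows with source amplitude and shrinks with perfusion", {
  n <- c(15, 15, 15); co <- ((1:15) - 8) * 0.5
  r2 <- outer(outer(co^2, co^2, "+"), co^2, "+")
  Q <- 5e7 * array(exp(-r2 / 2), n)
  run <- function(qs, wb) {
    tis <- thermal_tissue(w_b = wb)
    h <- pennes_solve(37, Q * qs, tis, h_mm = 0.5, dt = 0.05, duration = 3,
                      stride = 1)
    max(cem43_accumulate(h)$cem43)
  }
  expect_gt(run(2, 2.5), run(1, 2.5))
  expect_gt(run(1, 0), run(1, 50))
})
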