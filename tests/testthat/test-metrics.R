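test_that("ellipsoid volume reproduces the imaging worked example", {
  expect_equal(round_half_out(ellipsoid_volume(5.7, 5.1, 4.0)), 60.8)
  expect_equal(ellipsoid_volume(0, 3, 4), 0)
  expect_equal(ellipsoid_volume(1, 1, 1), 0.523)
  # symmetric under axis permutation
  expect_equal(ellipsoid_volume(2, 3, 5), ellipsoid_volume(5, 2, 3))
  expect_error(ellipsoid_volume(-1, 2, 3), ">= 0")
})

test_that("AVSR matches its definition including the sign convention", {
  expect_equal(round_half_out(avsr(60.8, 12.0)), 80.3)
  expect_equal(avsr(55, 55), 0)
  expect_equal(round_half_out(avsr(100, 102.7)), -2.7)   # growth is negative
  expect_equal(avsr(10, 0), 100)
  # strictly decreasing in the follow-up volume
  expect_true(all(diff(avsr(50, c(0, 10, 20, 30))) < 0))
  expect_error(avsr(0, 5), "positive")
})

test_that("NPVR supports both denominator conventions", {
  expect_equal(npvr(0, 50), 0)
  expect_equal(npvr(50, 50), 100)
  # same-timepoint vs original-volume reference for one set of measurements
  expect_equal(round_half_out(npvr(8.3, 12.0)), 69.2)
  expect_equal(round_half_out(npvr(8.3, 60.8)), 13.7)
  expect_error(npvr(5, 0), "positive")
  expect_error(npvr(-1, 10), "non-negative")
})

test_that("clinically effective DII is a score of three or less", {
  expect_true(dii_effective(3))
  expect_false(dii_effective(4))
  expect_true(dii_effective(1))
  expect_equal(dii_effective(c(1, 3, 4, 5)), c(TRUE, TRUE, FALSE, FALSE))
  expect_error(dii_effective(0), "1")
  expect_error(dii_effective(6), "5")
})

test_that("presentation rounding is half-away-from-zero at one decimal", {
  expect_equal(round_half_out(80.25), 80.3)
  expect_equal(round_half_out(-2.65), -2.7)
  expect_equal(round_half_out(0.05), 0.1)
  expect_equal(round_half_out(1.04), 1.0)
})

test_that("cohort summaries report medians, quartiles and DII proportions", {
  one <- data.frame(id = "P1", group = "A", timepoint = "screening",
                    L = 5, W = 4, H = 3, npv = NA, dii = NA)
  s1 <- summarize_cohort(one)
  row <- s1$continuous[s1$continuous$variable == "volume" &
                         s1$continuous$group == "A" &
                         s1$continuous$timepoint == "screening", ]
  expect_equal(row$median, 0.523 * 60)
  expect_equal(row$q1, row$median)
  expect_equal(row$q3, row$median)

  # 15 effective of 20 -> 75.0 with counts 15/20
  co <- data.frame(id = sprintf("P%02d", 1:20), group = "A",
                   timepoint = "1m", L = 5, W = 4, H = 3, npv = NA,
                   dii = c(rep(2, 15), rep(4, 5)))
  base <- co; base$timepoint <- "screening"; base$dii <- NA
  s2 <- summarize_cohort(rbind(base, co))
  d <- s2$effective_dii[s2$effective_dii$timepoint == "1m", ]
  expect_equal(d$percent, 75.0)
  expect_equal(d$counts, "15/20")

  # a group with no data in a cell is flagged missing, not zero
  co$group <- "A"; base$group <- "A"
  two_groups <- rbind(base, co,
                      transform(base, group = "B", id = paste0("B", id)))
  s3 <- summarize_cohort(two_groups)
  bcell <- s3$continuous[s3$continuous$group == "B" &
                           s3$continuous$timepoint == "1m" &
                           s3$continuous$variable == "volume", ]
  expect_true(bcell$missing)
  expect_true(is.na(bcell$median))
  expect_error(summarize_cohort(data.frame()), "empty")
})

test_that("summaries recover the generator's configured medians", {
  cfg <- cohort_config(n_A = 1000, n_B = 1000, seed = 42)
  coh <- generate_cohort(cfg)
  s <- summarize_cohort(coh)
  vol <- s$continuous[s$continuous$variable == "volume" &
                        s$continuous$timepoint == "screening", ]
  for (m in vol$median)
    expect_lt(abs(m - 68.6) / 68.6, 0.05)
})
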