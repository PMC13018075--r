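# Frozen quarterly unit-dose schedules for the three escalation rates
# (months 0..24) and the weight grid of the banded design, as published.
PUBLISHED_SCHEDULE <- list(
  "0.123" = c(0.14, 0.16, 0.18, 0.20, 0.22, 0.25, 0.28, 0.28, 0.28),
  "0.189" = c(0.14, 0.17, 0.20, 0.24, 0.28, 0.28, 0.28, 0.28, 0.28),
  "0.26"  = c(0.14, 0.18, 0.22, 0.28, 0.28, 0.28, 0.28, 0.28, 0.28)
)
PUBLISHED_BANDS <- data.frame(
  strength = seq(2, 5, by = 0.5),
  target = c(14.29, 17.86, 21.43, 25.00, 28.57, 32.14, 35.71),
  lo_wide = c(10.72, 14.29, 17.86, 21.43, 25.00, 28.57, 32.14),
  lo_narrow = c(12.51, 16.08, 19.65, 23.22, 26.79, 30.36, 33.93),
  hi_narrow = c(16.07, 19.64, 23.21, 26.78, 30.35, 33.92, 37.49),
  hi_wide = c(17.86, 21.43, 25.00, 28.57, 32.14, 35.71, 39.28)
)

test_that("up-titration schedules reproduce the published quarterly doses", {
  for (r in c(0.123, 0.189, 0.26)) {
    sched <- uptitration_schedule(titration_plan(rate = r))
    expect_identical(sched$month, seq(0, 24, by = 3))
    expect_equal(sched$unit_dose, PUBLISHED_SCHEDULE[[as.character(r)]],
                 tolerance = 1e-12)
    # non-decreasing and capped
    expect_true(all(diff(sched$unit_dose) >= 0))
    expect_true(all(sched$unit_dose <= 0.28))
  }
  # degenerate: zero rate stays at the start dose
  flat <- uptitration_schedule(titration_plan(rate = 0), 36)
  expect_true(all(flat$unit_dose == 0.14))
})

test_that("cap attainment months are 18, 12 and 9 for the three rates", {
  expect_equal(months_to_cap(titration_plan(rate = 0.123)), 18)
  expect_equal(months_to_cap(titration_plan(rate = 0.189)), 12)
  expect_equal(months_to_cap(titration_plan(rate = 0.260)), 9)
  expect_equal(months_to_cap(titration_plan(start_unit_dose = 0.28)), 0)
  expect_error(months_to_cap(titration_plan(rate = 0), horizon_months = 24),
               "not reached")
})

test_that("band edges reproduce the published weight grid cell for cell", {
  for (i in seq_len(nrow(PUBLISHED_BANDS))) {
    b <- band_edges(PUBLISHED_BANDS$strength[i])
    expect_equal(b$target_wt, PUBLISHED_BANDS$target[i], tolerance = 1e-12)
    expect_equal(b$lo_wide, PUBLISHED_BANDS$lo_wide[i], tolerance = 1e-12)
    expect_equal(b$lo_narrow, PUBLISHED_BANDS$lo_narrow[i], tolerance = 1e-12)
    expect_equal(b$hi_narrow, PUBLISHED_BANDS$hi_narrow[i], tolerance = 1e-12)
    expect_equal(b$hi_wide, PUBLISHED_BANDS$hi_wide[i], tolerance = 1e-12)
  }
})

test_that("strength assignment picks the nearest target, lower on ties", {
  expect_equal(assign_strength(14.29)$strength, 2)
  # 16.07: distances 1.78 vs 1.79 -> still the 2 mg band
  expect_equal(assign_strength(16.07)$strength, 2)
  # exactly equidistant: tie resolves to the lower strength
  expect_equal(assign_strength((14.29 + 17.86) / 2)$strength, 2)
  # narrow-band consistency across the whole grid
  for (i in seq_len(nrow(PUBLISHED_BANDS))) {
    w <- c(PUBLISHED_BANDS$lo_narrow[i] + 0.01, PUBLISHED_BANDS$target[i],
           PUBLISHED_BANDS$hi_narrow[i] - 0.01)
    for (x in w)
      expect_equal(assign_strength(x)$strength, PUBLISHED_BANDS$strength[i])
  }
  expect_warning(assign_strength(5), "outside")
})

test_that("weekly regimens expand schedules with quarterly weight lookup", {
  # flat 0.14 at constant 25 kg: 3.5 mg every 168 h
  sched <- uptitration_schedule(titration_plan(rate = 0))
  reg <- weekly_regimen(sched, 25, horizon_months = 24)
  expect_equal(nrow(reg), 104)
  expect_true(all(diff(reg$time) == 168))
  expect_equal(reg$amount, rep(3.5, 104), tolerance = 1e-12)
  # titrated schedule at constant weight steps exactly at quarter boundaries
  reg2 <- weekly_regimen(uptitration_schedule(titration_plan(rate = 0.26)),
                         25, horizon_months = 12)
  steps <- which(diff(reg2$amount) > 0)
  expect_equal(steps, c(13, 26, 39))
  # fixed 3.5 mg equals 0.14 mg/kg at exactly 25.00 kg
  fix <- weekly_regimen(NULL, horizon_months = 24, strength = 3.5)
  expect_equal(fix$amount, reg$amount)
  expect_identical(attr(fix, "provenance"), "fixed-strength")
  expect_error(weekly_regimen(sched, -5, 24), "weight")
})
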