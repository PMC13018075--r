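test_that("IGF-1 homeostasis, steady states and saturation bounds hold", {
  idr <- nominal_params()$idr
  r0 <- 120
  grid <- seq(0, 2000, by = 1)
  # no drug: stays at baseline to machine precision
  flat <- structure(list(times = grid, conc = rep(0, length(grid))),
                    class = "conc_profile")
  prof <- simulate_igf1(idr, flat, r0)
  expect_lt(max(abs(prof$igf1 - r0)) / r0, 1e-12)
  # constant C = sc50 converges to r0 * (1 + smax/2)
  half <- structure(list(times = grid, conc = rep(idr$sc50, length(grid))),
                    class = "conc_profile")
  prof2 <- simulate_igf1(idr, half, r0)
  expect_equal(tail(prof2$igf1, 1), r0 * (1 + idr$smax / 2), tolerance = 1e-6)
  expect_equal(igf1_steady_state(idr, idr$sc50, r0), r0 * (1 + idr$smax / 2))
  expect_equal(igf1_steady_state(idr, 0, r0), r0)
  # saturation limit and boundedness
  big <- structure(list(times = grid, conc = rep(1e9, length(grid))),
                   class = "conc_profile")
  prof3 <- simulate_igf1(idr, big, r0)
  expect_equal(tail(prof3$igf1, 1), r0 * (1 + idr$smax), tolerance = 1e-6)
  expect_true(all(prof3$igf1 >= r0 - 1e-9 &
                    prof3$igf1 <= r0 * (1 + idr$smax) + 1e-9))
})

test_that("long-horizon ODE oracle matches the closed-form steady state", {
  idr <- nominal_params()$idr
  r0 <- 150
  horizon <- 10 / idr$kout
  grid <- seq(0, horizon, length.out = 2000)
  cprof <- structure(list(times = grid, conc = rep(2, length(grid))),
                     class = "conc_profile")
  ode <- simulate_igf1_ode(idr, cprof, r0)
  expect_equal(tail(ode$igf1, 1), igf1_steady_state(idr, 2, r0),
               tolerance = 1e-3)
  # integrator vs ODE oracle on a fluctuating profile
  par <- nominal_ind()
  conc <- simulate_pk(par, weekly_doses(rep(3.5, 4)), seq(0, 5 * 168, by = 1))
  expect_lt(max(abs(simulate_igf1(idr, conc, r0)$igf1 -
                      simulate_igf1_ode(idr, conc, r0)$igf1) /
                  simulate_igf1_ode(idr, conc, r0)$igf1), 1e-3)
})

test_that("larger exposure gives pointwise larger IGF-1", {
  idr <- nominal_params()$idr
  par <- nominal_ind()
  grid <- seq(0, 8 * 168, by = 2)
  lo <- simulate_pk(par, weekly_doses(rep(2, 8)), grid)
  hi <- simulate_pk(par, weekly_doses(rep(5, 8)), grid)
  expect_true(all(simulate_igf1(idr, hi, 100)$igf1 >=
                    simulate_igf1(idr, lo, 100)$igf1 - 1e-12))
})

test_that("SDS conversion round-trips and is strictly increasing", {
  ref <- igf1_reference()
  mu <- ref$mu_ln[ref$sex == "M" & ref$age == 8]
  sd <- ref$sd_ln[ref$sex == "M" & ref$age == 8]
  expect_equal(igf1_to_sds(exp(mu), 8, "M"), 0)
  expect_equal(igf1_to_sds(exp(mu + 2 * sd), 8, "M"), 2)
  set.seed(7)
  x <- exp(runif(1000, log(20), log(900)))
  ages <- runif(1000, 3, 16)
  sds <- igf1_to_sds(x, ages, "F")
  expect_equal(sds_to_igf1(sds, ages, "F"), x, tolerance = 1e-12)
  expect_true(all(diff(igf1_to_sds(seq(50, 500, by = 5), 10, "M")) > 0))
  expect_error(igf1_to_sds(100, 20, "M"), "outside")
})

test_that("trough series picks pre-dose points and respects monotonicity", {
  idr <- nominal_params()$idr
  grid <- seq(0, 26 * 168, by = 1)
  dose_times <- (0:25) * 168
  # flat profile at the reference median -> all-zero SDS
  med <- sds_to_igf1(0, 8, "M")
  flatp <- list(times = grid, igf1 = rep(med, length(grid)))
  sds <- trough_sds_series(flatp, dose_times, c(0, 3, 6), 8, "M")
  expect_equal(sds, rep(0, 3))
  # baseline visit of a cohort standardised to -1 reads back -1
  basep <- list(times = grid, igf1 = rep(sds_to_igf1(-1, 8, "M"), length(grid)))
  expect_equal(trough_sds_series(basep, dose_times, 0, 8, "M"), -1)
  # monotone rising profile -> non-decreasing trough series
  risep <- list(times = grid, igf1 = med * (1 + grid / max(grid)))
  tr <- trough_igf1_series(risep, dose_times, c(3, 6))
  expect_true(all(diff(tr) >= 0))
  expect_error(trough_igf1_series(risep, dose_times = 1e6, visit_months = 3),
               "before first dose")
})

test_that("proportion above threshold matches normal tail probability", {
  expect_equal(proportion_above(rep(-1, 50)), 0)
  set.seed(123)
  draws <- rnorm(1e6)
  expect_lt(abs(100 * proportion_above(draws, 2) - 2.275), 0.05)
  expect_error(proportion_above(numeric(0)), "empty")
})
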