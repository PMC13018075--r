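test_that("individual parameters follow the allometric/log-normal contract", {
  pop <- nominal_params()$pk
  # identity at reference weight with zero etas
  ind <- individual_pk(pop, pop$wt_ref)
  expect_equal(ind$cl, pop$cl_pop)
  expect_equal(ind$v, pop$v_pop)
  expect_equal(ind$ka, pop$ka_pop)
  # closed-form allometric scaling
  ind2 <- individual_pk(pop, 2 * pop$wt_ref)
  expect_equal(ind2$cl, pop$cl_pop * 2^pop$exp_cl)
  expect_equal(ind2$v, pop$v_pop * 2)
  # Monte-Carlo check of the log-normal between-subject model
  set.seed(42)
  etas <- cbind(rnorm(1e5, 0, pop$omega_cl), 0, 0)
  ind3 <- individual_pk(pop, pop$wt_ref, etas)
  expect_equal(sd(log(ind3$cl)), pop$omega_cl, tolerance = 0.02)
  expect_error(individual_pk(pop, 25, c(NA, 0, 0)), "non-finite")
})

test_that("single-dose concentration matches the ODE oracle and edge cases", {
  par <- nominal_ind()
  expect_equal(conc_single_dose(par, 3.5, 0), 0)
  expect_equal(conc_single_dose(par, 0, c(1, 10, 100)), rep(0, 3))
  grid <- seq(0, 336, by = 1)
  analytic <- conc_single_dose(par, 3.5, grid)
  ode <- simulate_pk_ode(par, dose_events(0, 3.5), grid)
  expect_lt(max(abs(analytic - ode$conc)) / max(analytic), 1e-6)
  # ka == ke limiting form stays finite and positive
  par_eq <- list(cl = 0.035 * 2.5, v = 2.5, ka = 0.035, f = 1)
  lim <- conc_single_dose(par_eq, 3.5, c(1, 24, 100))
  expect_true(all(is.finite(lim) & lim > 0))
})

test_that("multi-dose superposition is linear and reduces correctly", {
  par <- nominal_ind()
  grid <- seq(0, 12 * 168, by = 4)
  single <- simulate_pk(par, dose_events(0, 3.5), grid)
  expect_equal(single$conc, conc_single_dose(par, 3.5, grid))
  empty <- simulate_pk(par, dose_events(numeric(0), numeric(0)), grid)
  expect_true(all(empty$conc == 0))
  # superposition: A+B doses equals sum of profiles
  dA <- dose_events(c(0, 336), c(3.5, 3.5))
  dB <- dose_events(168, 2)
  both <- simulate_pk(par, dose_events(c(0, 168, 336), c(3.5, 2, 3.5)), grid)
  sum_ab <- simulate_pk(par, dA, grid)$conc + simulate_pk(par, dB, grid)$conc
  expect_lt(max(abs(both$conc - sum_ab)), 1e-9 * max(both$conc))
  # dose proportionality
  dbl <- simulate_pk(par, dose_events(c(0, 168, 336), 2 * c(3.5, 2, 3.5)), grid)
  expect_equal(dbl$conc, 2 * both$conc, tolerance = 1e-12)
})

test_that("12 weekly doses accumulate to the analytic steady-state trough", {
  par <- nominal_ind()
  doses <- weekly_doses(rep(3.5, 12))
  trough <- simulate_pk(par, doses, c(0, 12 * 168 - 0.001))$conc[2]
  expect_equal(trough, pk_steady_state(par, 3.5)$trough, tolerance = 0.01)
})

test_that("interval AUC is exact, additive and attains F*D/CL at steady state", {
  par <- nominal_ind()
  doses <- weekly_doses(rep(3.5, 30))
  expect_equal(auc_interval(par, dose_events(numeric(0), numeric(0)), 0, 168), 0)
  # steady-state weekly interval
  auc_ss <- auc_interval(par, doses, 25 * 168, 26 * 168)
  expect_equal(auc_ss, 3.5 / par$cl, tolerance = 0.01)
  # additivity
  a02 <- auc_interval(par, doses, 0, 400)
  expect_equal(auc_interval(par, doses, 0, 150) +
                 auc_interval(par, doses, 150, 400), a02, tolerance = 1e-10)
  # quadrature oracle: refined trapezoid vs the analytic integral
  grid <- seq(0, 336, by = 0.25)
  conc <- simulate_pk(par, doses, grid)$conc
  trap <- sum((conc[-1] + conc[-length(conc)]) / 2 * diff(grid))
  expect_equal(trap, auc_interval(par, doses, 0, 336), tolerance = 0.005)
})

test_that("the cohort engine reproduces the analytic solution exactly", {
  subj <- one_subject()
  reg <- weekly_regimen(NULL, horizon_months = 6, strength = 3.5)
  sim <- simulate_subject(subj, reg, config = sim_config(update_weight = FALSE,
                                                         horizon_months = 6))
  par <- nominal_ind(subj$weight)
  sup <- simulate_pk(par, reg, sim$conc$times)
  expect_lt(max(abs(sim$conc$conc - sup$conc)), 1e-12 * max(sup$conc))
  # weekly AUC from the engine agrees with the analytic interval integral
  expect_equal(sim$engine$auc_weekly[1, 5],
               auc_interval(par, reg, 4 * 168, 5 * 168), tolerance = 1e-9)
})
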