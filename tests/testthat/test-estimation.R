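test_that("noise-free pooled fit recovers truth from a perturbed start", {
  nf <- noise_free_params()
  obs <- phase1_design(n = 6, seed = 1, params = nf)
  init <- pk_params(cl_pop = 2 * nf$pk$cl_pop, v_pop = 2 * nf$pk$v_pop,
                    ka_pop = 2 * nf$pk$ka_pop, wt_ref = nf$pk$wt_ref,
                    sigma_prop = 0, sigma_add = 0.001)
  fit <- fit_pk(obs, init, method = "naive_pooled", estimate_sigma = FALSE)
  expect_true(fit$convergence)
  rel <- abs(fit$estimates[c("cl_pop", "v_pop", "ka_pop")] /
               c(nf$pk$cl_pop, nf$pk$v_pop, nf$pk$ka_pop) - 1)
  expect_true(all(rel < 1e-3 / 100 * 100))
  expect_true(all(rel < 0.001))
})

test_that("empirical-Bayes modes behave: prior mode, recovery, shrinkage", {
  pop <- nominal_params()$pk
  # no observations -> prior mode zero
  empty <- data.frame(ID = 1, TIME = 0, AMT = 3.5, DV = NA, EVID = 1,
                      MDV = 1, CMT = 1, WT = 25, AGE = 8, SEX = "M")
  eb0 <- empirical_bayes(pop, empty)
  expect_equal(as.vector(eb0), c(0, 0, 0))
  expect_true(attr(eb0, "shrunk"))
  # near-zero residual error recovers the generating etas
  true_eta <- c(0.25, -0.2, 0.15)
  par <- individual_pk(pop, 25, true_eta)
  times <- c(6, 12, 24, 48, 96, 168, 240, 336)
  dv <- conc_single_dose(par, 3.5, times)
  sub <- rbind(
    data.frame(ID = 1, TIME = 0, AMT = 3.5, DV = NA, EVID = 1, MDV = 1,
               CMT = 1, WT = 25, AGE = 8, SEX = "M"),
    data.frame(ID = 1, TIME = times, AMT = 0, DV = dv, EVID = 0, MDV = 0,
               CMT = 2, WT = 25, AGE = 8, SEX = "M"))
  pop_tight <- pk_params(cl_pop = pop$cl_pop, v_pop = pop$v_pop,
                         ka_pop = pop$ka_pop, wt_ref = 25,
                         omega_cl = 0.3, omega_v = 0.25, omega_ka = 0.3,
                         sigma_prop = 1e-6, sigma_add = 1e-9)
  expect_equal(as.vector(empirical_bayes(pop_tight, sub)), true_eta,
               tolerance = 1e-3)
  # under an additive error model, growing residual SD shrinks the modes
  # monotonically toward the prior mode
  norms <- vapply(c(0.001, 0.01, 0.05, 0.3), function(sa) {
    popx <- pk_params(cl_pop = pop$cl_pop, v_pop = pop$v_pop,
                      ka_pop = pop$ka_pop, wt_ref = 25,
                      omega_cl = 0.3, omega_v = 0.25, omega_ka = 0.3,
                      sigma_prop = 0, sigma_add = sa)
    sum(abs(empirical_bayes(popx, sub)))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("FOCE with zero omegas reproduces the pooled objective", {
  p <- nominal_params()
  obs <- phase1_design(n = 8, seed = 2, params = p)
  init <- pk_params(cl_pop = p$pk$cl_pop, v_pop = p$pk$v_pop,
                    ka_pop = p$pk$ka_pop, wt_ref = 25,
                    omega_cl = 0, omega_v = 0, omega_ka = 0,
                    sigma_prop = 0.15, sigma_add = 0.01)
  f1 <- fit_pk(obs, init, method = "foce")
  f2 <- fit_pk(obs, init, method = "naive_pooled")
  expect_lt(abs(f1$objective - f2$objective) / abs(f2$objective), 1e-6)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-6)
})

test_that("noise-free sequential PD fit recovers truth to 0.1%", {
  nf <- noise_free_params()
  truth <- nominal_params()
  p1 <- phase1_design(n = 10, seed = 3, params = nf)
  pk_init <- pk_params(cl_pop = 2 * nf$pk$cl_pop, v_pop = 0.5 * nf$pk$v_pop,
                       ka_pop = 2 * nf$pk$ka_pop, wt_ref = 25,
                       sigma_prop = 0, sigma_add = 0.001)
  pk_fit <- fit_pk(p1, pk_init, method = "naive_pooled", estimate_sigma = FALSE)
  cohort <- generate_ghd_cohort(n = 10, seed = 3, params = nf)
  cohort[c("eta_cl", "eta_v", "eta_ka", "eta_gv")] <- 0
  cohort$baseline_gv <- nf$gv$e0
  obs <- sparse_pediatric_design(cohort, months = 24, seed = 3, params = nf,
                                 plan = titration_plan(rate = 0.189))
  init <- list(idr = idr_params(kout = nf$idr$kout, smax = 1.4 * nf$idr$smax,
                                sc50 = 0.6 * nf$idr$sc50),
               gv = gv_params(e0 = 1.2 * nf$gv$e0,
                              emax_gv = 0.7 * nf$gv$emax_gv,
                              auc50 = 1.6 * nf$gv$auc50, lam = 0.05))
  fit <- fit_pd_sequential(pk_fit, obs, init, step_h = 1)
  tr <- c(smax = truth$idr$smax, sc50 = truth$idr$sc50, e0 = truth$gv$e0,
          emax_gv = truth$gv$emax_gv, auc50 = truth$gv$auc50,
          lam = truth$gv$lam)
  rr <- recovery_report(tr, fit)
  expect_true(all(abs(rr$bias_pct) < 0.1))
})

test_that("reduced model with smax = 0 returns the geometric-mean baseline", {
  nf <- noise_free_params()
  cohort <- generate_ghd_cohort(n = 8, seed = 5, params = nf)
  cohort[c("eta_cl", "eta_v", "eta_ka", "eta_gv")] <- 0
  obs <- sparse_pediatric_design(cohort, months = 12, seed = 5, params = nf)
  pk_init <- pk_params(cl_pop = nf$pk$cl_pop, v_pop = nf$pk$v_pop,
                       ka_pop = nf$pk$ka_pop, wt_ref = nf$pk$wt_ref,
                       sigma_prop = 0, sigma_add = 0.001)
  pk_fit <- fit_pk(phase1_design(n = 6, seed = 5, params = nf),
                   pk_init, method = "naive_pooled", estimate_sigma = FALSE)
  fit <- fit_pd_sequential(pk_fit, obs, nominal_params()[c("idr", "gv")],
                           igf1_baseline = "pooled", fix_smax = 0)
  igf_dv <- obs$DV[obs$CMT == 3 & obs$MDV == 0]
  expect_equal(unname(fit$estimates["r0_pop"]), exp(mean(log(igf_dv))),
               tolerance = 1e-4)
})

test_that("a flat growth attenuation is detected as such (CI covers zero)", {
  p <- nominal_params()
  # iid residual noise only: the least-squares covariance is calibrated
  # (a between-subject effect would correlate residuals within subject and
  # the naive covariance would undercover)
  p$gv <- gv_params(e0 = p$gv$e0, emax_gv = p$gv$emax_gv, auc50 = p$gv$auc50,
                    lam = 0, omega_gv = 0, sigma_gv = 0.3)
  cohort <- generate_ghd_cohort(n = 30, seed = 12, params = p)
  obs <- sparse_pediatric_design(cohort, months = 24, seed = 12, params = p,
                                 plan = titration_plan(rate = 0.189))
  pk_fit <- fit_pk(phase1_design(n = 30, seed = 12, params = p),
                   p$pk, method = "foce")
  init <- list(idr = p$idr,
               gv = gv_params(e0 = p$gv$e0, emax_gv = p$gv$emax_gv,
                              auc50 = p$gv$auc50, lam = 0.05))
  fit <- fit_pd_sequential(pk_fit, obs, init)
  lam_hat <- fit$estimates["lam"]
  lam_se <- fit$se["lam"]
  expect_false(is.na(lam_se))
  expect_lt(abs(lam_hat) - 1.96 * lam_se, 0)
})

test_that("recovery report computes bias percentages", {
  truth <- c(a = 2, b = 10)
  expect_equal(recovery_report(truth, c(a = 2, b = 10))$bias_pct, c(0, 0))
  expect_equal(recovery_report(truth, c(a = 2.2, b = 11))$bias_pct, c(10, 10))
  expect_error(recovery_report(truth, c(x = 1)), "no matching")
})
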