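test_that("zero-dose regimen keeps IGF-1 at baseline and GV attenuating", {
  subj <- one_subject()
  p <- nominal_params()
  reg <- weekly_regimen(NULL, horizon_months = 24, strength = 1e-12)
  sim <- simulate_subject(subj, reg, config = sim_config(update_weight = FALSE))
  expect_lt(max(abs(sim$sds - subj$baseline_igf1_sds)), 1e-6)
  expect_equal(annualized_gv(sim$growth, 12),
               subj$baseline_gv * (1 - exp(-p$gv$lam)) / p$gv$lam,
               tolerance = 1e-3)
})

test_that("doubling doses doubles AUC but raises GV by less (saturation)", {
  subj <- one_subject()
  cfg <- sim_config(update_weight = FALSE)
  s1 <- simulate_subject(subj, weekly_regimen(NULL, 24, strength = 3.5), config = cfg)
  s2 <- simulate_subject(subj, weekly_regimen(NULL, 24, strength = 7.0), config = cfg)
  expect_equal(s2$engine$auc_weekly[1, ], 2 * s1$engine$auc_weekly[1, ],
               tolerance = 1e-9)
  gv1 <- annualized_gv(s1$growth, 12); gv2 <- annualized_gv(s2$growth, 12)
  expect_gt(gv2, gv1)
  expect_lt(gv2, 2 * gv1)
})

test_that("fixed strength equals weight-based dosing at the target weight", {
  subj <- one_subject(weight = 25)
  cfg <- sim_config(update_weight = FALSE)
  fixed <- simulate_subject(subj, weekly_regimen(NULL, 24, strength = 3.5),
                            config = cfg)
  wb <- simulate_subject(subj,
                         weekly_regimen(uptitration_schedule(titration_plan(rate = 0)),
                                        25, 24), config = cfg)
  expect_equal(fixed$conc$conc, wb$conc$conc, tolerance = 1e-12)
  expect_equal(fixed$growth$height, wb$growth$height, tolerance = 1e-12)
})

test_that("prediction bands match empirical quantiles and edge levels", {
  expect_error(prediction_band(matrix(1, 1, 3)), "2 replicates")
  const <- prediction_band(matrix(5, 10, 4))
  expect_true(all(const$lower == 5 & const$upper == 5))
  set.seed(11)
  x <- matrix(rnorm(1e5), ncol = 1)
  b <- prediction_band(x, 0.90)
  expect_lt(abs(b$lower + 1.645), 0.02)
  expect_lt(abs(b$median), 0.02)
  expect_lt(abs(b$upper - 1.645), 0.02)
  bmax <- prediction_band(x, 1.0)
  expect_equal(c(bmax$lower, bmax$upper), range(x))
})

test_that("band overlap obeys interval arithmetic", {
  b1 <- structure(list(lower = rep(0, 5), median = rep(1, 5),
                       upper = rep(2, 5)), class = "prediction_band")
  expect_equal(band_overlap(b1, b1), 1)
  b2 <- structure(list(lower = rep(3, 5), median = rep(4, 5),
                       upper = rep(5, 5)), class = "prediction_band")
  expect_equal(band_overlap(b1, b2), 0)
  # nested band of half the width
  b3 <- structure(list(lower = rep(0.5, 5), median = rep(1, 5),
                       upper = rep(1.5, 5)), class = "prediction_band")
  expect_equal(band_overlap(b1, b3), 0.5)
})

test_that("prediction-band coverage is near nominal for a known simulator", {
  set.seed(21)
  reps <- matrix(rlnorm(500 * 8, 1, 0.4), nrow = 500)
  b <- prediction_band(reps, 0.90)
  fresh <- matrix(rlnorm(4000 * 8, 1, 0.4), nrow = 4000)
  cover <- mean(sweep(fresh, 2, b$lower, `>=`) & sweep(fresh, 2, b$upper, `<=`))
  expect_lt(abs(cover - 0.90), 0.03)
})

test_that("up-titration study output is dose-monotone with shared subjects", {
  cohort <- generate_ghd_cohort(n = 60, seed = 9)
  study <- run_uptitration_study(cohort, config = sim_config(seed = 9))
  s <- study$summary
  expect_true(all(diff(s$gv12_mean) >= 0))
  expect_true(all(diff(s$sds12_mean) >= 0))
  expect_true(all(diff(s$prop2_12) >= 0))
  expect_equal(s$gv_baseline_mean, rep(mean(cohort$baseline_gv), 3))
  expect_equal(s$prop2_baseline, rep(0, 3))
  # rerun determinism
  study2 <- run_uptitration_study(cohort, config = sim_config(seed = 9))
  expect_identical(study$summary, study2$summary)
})

test_that("banded study has exact-zero reference rows and paired sign structure", {
  bc <- generate_banded_cohort(seed = 3)
  study <- run_banded_study(bc, config = sim_config(seed = 3, n_replicates = 10))
  t4 <- study$table4
  ref <- t4[t4$scenario == "target", ]
  expect_true(all(ref$gv_diff == 0))
  for (s in unique(t4$strength)) {
    g <- t4[t4$strength == s, ]
    expect_gte(g$gv_diff[g$scenario == "wide_low"], 0)
    expect_gte(g$gv_diff[g$scenario == "narrow_low"], 0)
    expect_lte(g$gv_diff[g$scenario == "narrow_high"], 0)
    expect_lte(g$gv_diff[g$scenario == "wide_high"], 0)
    expect_lte(abs(g$gv_diff[g$scenario == "narrow_low"]),
               abs(g$gv_diff[g$scenario == "wide_low"]))
    expect_lte(abs(g$gv_diff[g$scenario == "narrow_high"]),
               abs(g$gv_diff[g$scenario == "wide_high"]))
  }
  # narrow-band SDS time courses overlap the reference more than wide bands
  ov <- do.call(rbind, study$overlap)
  expect_true(all(ov[, "narrow"] >= ov[, "wide"]))
})
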