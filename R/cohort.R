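# Virtual-cohort generators and observation-table designs. Every generator
# is a pure function of (arguments, seed): the same call reproduces the same
# cohort bit for bit.

rtrunc_norm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

draw_etas <- function(n, params) {
  pk <- params$pk; gv <- params$gv
  data.frame(
    eta_cl = stats::rnorm(n, 0, pk$omega_cl),
    eta_v = stats::rnorm(n, 0, pk$omega_v),
    eta_ka = stats::rnorm(n, 0, pk$omega_ka),
    eta_gv = stats::rnorm(n, 0, gv$omega_gv)
  )
}

#' Generate a virtual pediatric GHD cohort
#'
#' Ages are uniform over `age_range`, sexes Bernoulli(1/2), weights and
#' heights drawn around the synthetic reference channels (log-normal weight
#' spread with the channel CV; heights shifted below the median to reflect
#' short stature), baseline growth velocity Normal(3.57, 1.06) truncated at
#' 0 and baseline IGF-1 SDS Normal(-1.27, 0.55) by default.
#'
#' @param n Cohort size.
#' @param seed Seed for the cohort stream.
#' @param params Parameter set (for between-subject effect SDs).
#' @param age_range Age span in years (within the reference table).
#' @param baseline_gv_mean,baseline_gv_sd Baseline GV distribution (cm/year).
#' @param baseline_sds_mean,baseline_sds_sd Baseline IGF-1 SDS distribution.
#' @param height_sds Mean height SDS of the cohort (negative: short
#'   stature).
#' @param ref A [growth_reference()].
#' @return Data.frame of class `ghd_cohort` with columns `id`, `sex`, `age`,
#'   `weight`, `height`, `baseline_gv`, `baseline_igf1_sds` and the four eta
#'   columns.
#' @export
generate_ghd_cohort <- function(n = 292, seed = 1L, params = nominal_params(),
                                age_range = c(4, 12),
                                baseline_gv_mean = 3.57, baseline_gv_sd = 1.06,
                                baseline_sds_mean = -1.27,
                                baseline_sds_sd = 0.55,
                                height_sds = -2, ref = growth_reference()) {
  stopifnot(n >= 1)
  set.seed(seed_stream(seed, "cohort"))
  age <- stats::runif(n, age_range[1], age_range[2])
  sex <- ifelse(stats::rbinom(n, 1, 0.5) == 1, "M", "F")
  weight <- height <- numeric(n)
  for (s in c("M", "F")) {
    i <- sex == s
    if (!any(i)) next
    wm <- ref_interp(ref, s, "weight_median", age[i])
    cv <- ref_interp(ref, s, "weight_cv", age[i])
    weight[i] <- wm * exp(stats::rnorm(sum(i), -0.1, cv))  # GHD: lighter
    hm <- ref_interp(ref, s, "height_median", age[i])
    hcv <- ref_interp(ref, s, "height_cv", age[i])
    height[i] <- hm * (1 + hcv * (height_sds + stats::rnorm(sum(i), 0, 0.5)))
  }
  cohort <- data.frame(
    id = seq_len(n), sex = sex, age = age, weight = weight, height = height,
    baseline_gv = rtrunc_norm_pos(n, baseline_gv_mean, baseline_gv_sd),
    baseline_igf1_sds = stats::rnorm(n, baseline_sds_mean, baseline_sds_sd)
  )
  cohort <- cbind(cohort, draw_etas(n, params))
  structure(cohort, class = c("ghd_cohort", "data.frame"))
}

#' Generate the weight-banded virtual cohort
#'
#' For each product strength, `per_group` subjects (alternating M/F for an
#' exact 1:1 ratio) whose weights cycle through the five scenario points of
#' the banded design (target, +/- narrow, +/- wide). Age and height are
#' back-solved from the growth reference so that the subject's reference
#' channel median weight equals the strength's target weight; baseline
#' IGF-1 SDS is standardised to `baseline_sds` for every subject.
#'
#' @param strengths Product strengths in mg.
#' @param per_group Subjects per strength (even, for the 1:1 sex ratio).
#' @param seed Seed for the cohort stream (random effects only; the design
#'   grid is deterministic).
#' @param params Parameter set.
#' @param unit_dose Reference unit dose (mg/kg/week).
#' @param baseline_sds Standardised baseline IGF-1 SDS.
#' @param ref A [growth_reference()].
#' @return Data.frame of class `banded_cohort`; in addition to the cohort
#'   columns it carries `strength` and `scenario`
#'   (`target`, `narrow_low`, `narrow_high`, `wide_low`, `wide_high`).
#' @export
generate_banded_cohort <- function(strengths = seq(2, 5, by = 0.5),
                                   per_group = 10, seed = 1L,
                                   params = nominal_params(),
                                   unit_dose = 0.14, baseline_sds = -1,
                                   ref = growth_reference()) {
  stopifnot(per_group >= 1)
  set.seed(seed_stream(seed, "banded-cohort"))
  scen_names <- c("wide_low", "narrow_low", "target", "narrow_high", "wide_high")
  rows <- list()
  for (s in strengths) {
    b <- band_edges(s, unit_dose)
    scen_wt <- c(b$lo_wide, b$lo_narrow, b$target_wt, b$hi_narrow, b$hi_wide)
    sexes <- rep(c("M", "F"), length.out = per_group)
    scen_i <- rep(seq_along(scen_wt), length.out = per_group)
    age <- vapply(seq_len(per_group), function(k)
      age_for_weight(b$target_wt, sexes[k], ref), numeric(1))
    height <- vapply(seq_len(per_group), function(k)
      ref_interp(ref, sexes[k], "height_median", age[k]), numeric(1))
    rows[[length(rows) + 1]] <- data.frame(
      strength = s, scenario = scen_names[scen_i], sex = sexes, age = age,
      weight = scen_wt[scen_i], height = height
    )
  }
  cohort <- do.call(rbind, rows)
  n <- nrow(cohort)
  cohort <- data.frame(id = seq_len(n), cohort[, c("sex", "age", "weight", "height")],
                       baseline_gv = rtrunc_norm_pos(n, 3.57, 1.06),
                       baseline_igf1_sds = baseline_sds,
                       strength = cohort$strength, scenario = cohort$scenario)
  cohort <- cbind(cohort, draw_etas(n, params))
  structure(cohort, class = c("banded_cohort", "data.frame"))
}

#' Advance a subject's weight along its reference channel
#'
#' Given the height gained since baseline, finds the implied age on the
#' subject's height channel and returns the weight of the subject's weight
#' channel at that age. Gain 0 leaves the weight unchanged; the update is
#' strictly increasing in the gain while the implied age is inside the
#' reference span (flat beyond it).
#'
#' @param subject One-row cohort data.frame.
#' @param height_gain_cm Height gained since baseline (>= 0).
#' @param ref A [growth_reference()].
#' @return Updated weight in kg.
#' @export
update_weight <- function(subject, height_gain_cm, ref = growth_reference()) {
  stopifnot(all(height_gain_cm >= 0))
  setup <- subject_pd_setup(subject, nominal_params()$idr, ref, igf1_reference())
  vapply(height_gain_cm, function(g)
    channel_weight(subject, setup, g, ref), numeric(1))
}

#' Rich single-dose PK study design
#'
#' Emulates a healthy-volunteer single-ascending-dose study: `n` subjects
#' split over the weight-normalised dose levels, each with one subcutaneous
#' dose and rich sampling at the 15 protocol times (0 through 336 h). The
#' pre-dose 0 h sample is retained as a missing-DV row (no drug on board).
#' Observations are model predictions with proportional and additive
#' residual error.
#'
#' @param n Number of subjects (allocated round-robin over dose levels).
#' @param dose_levels Unit doses in mg/kg.
#' @param seed Master seed (streams: `phase1-subjects`, `phase1-residual`).
#' @param params Parameter set.
#' @param weight_mean,weight_sd Adult body-weight distribution (kg).
#' @return An `obs_table` with dose rows (EVID 1, CMT 1) and PK observation
#'   rows (EVID 0, CMT 2).
#' @export
phase1_design <- function(n = 36, dose_levels = c(0.01, 0.03, 0.06, 0.12, 0.2),
                          seed = 1L, params = nominal_params(),
                          weight_mean = 70, weight_sd = 8) {
  times <- c(0, 6, 12, 15, 24, 48, 72, 96, 120, 144, 168, 192, 240, 288, 336)
  set.seed(seed_stream(seed, "phase1-subjects"))
  wt <- pmax(stats::rnorm(n, weight_mean, weight_sd), 40)
  level <- rep_len(dose_levels, n)
  etas <- cbind(stats::rnorm(n, 0, params$pk$omega_cl),
                stats::rnorm(n, 0, params$pk$omega_v),
                stats::rnorm(n, 0, params$pk$omega_ka))
  set.seed(seed_stream(seed, "phase1-residual"))
  rows <- lapply(seq_len(n), function(i) {
    par <- individual_pk(params$pk, wt[i], etas[i, ])
    dose <- level[i] * wt[i]
    pred <- conc_single_dose(par, dose, times)
    dv <- pred * (1 + stats::rnorm(length(times), 0, params$pk$sigma_prop)) +
      stats::rnorm(length(times), 0, params$pk$sigma_add)
    # pre-dose sample and non-positive (below-quantification) draws are
    # retained as missing-DV rows
    mdv <- ifelse(times == 0 | dv <= 0, 1L, 0L)
    dv[mdv == 1L] <- NA
    rbind(
      data.frame(ID = i, TIME = 0, AMT = dose, DV = NA, EVID = 1L, MDV = 1L,
                 CMT = CMT_DEPOT, WT = wt[i], AGE = 30, SEX = "M"),
      data.frame(ID = i, TIME = times, AMT = 0, DV = dv, EVID = 0L, MDV = mdv,
                 CMT = CMT_PK, WT = wt[i], AGE = 30, SEX = "M")
    )
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$ID, tab$TIME, tab$EVID, method = "radix",
                   decreasing = c(FALSE, FALSE, TRUE)), ]
  rownames(tab) <- NULL
  attr(tab, "etas") <- etas
  structure(tab, class = c("obs_table", "data.frame"))
}

#' Sparse pediatric PD observation design
#'
#' Simulates a weekly-dosing pediatric study and emits quarterly visit
#' observations: pre-dose (trough) IGF-1 and quarter-annualized growth
#' velocity, plus (optionally) pre-dose PK samples at the same visits,
#' mirroring the composition of a pediatric efficacy study with sparse PK.
#' Dose rows carry the full weekly schedule.
#'
#' @param cohort A [generate_ghd_cohort()] cohort.
#' @param months Design horizon in months (multiple of 3).
#' @param seed Master seed (stream: `sparse-residual`).
#' @param params Parameter set.
#' @param plan A [titration_plan()]; defaults to a flat 0.14 mg/kg/week.
#' @param include_pk Add quarterly pre-dose PK observations.
#' @param update_weight Quarterly weight progression during the simulated
#'   study.
#' @return An `obs_table`; IGF-1 rows have CMT 3, GV rows CMT 4. The
#'   simulation truth is attached as attribute `engine`.
#' @export
sparse_pediatric_design <- function(cohort, months = 12, seed = 1L,
                                    params = nominal_params(),
                                    plan = titration_plan(rate = 0),
                                    include_pk = TRUE,
                                    update_weight = TRUE) {
  stopifnot(nrow(cohort) >= 1, months %% 3 == 0)
  n_weeks <- months / 3 * 13
  sched <- uptitration_schedule(plan, horizon_months = months)
  dose_log <- matrix(NA_real_, nrow(cohort), n_weeks)
  dose_fn <- function(w, weight) {
    amt <- sched$unit_dose[w %/% 13 + 1] * weight
    dose_log[, w + 1] <<- amt
    amt
  }
  res <- sim_cohort(cohort, dose_fn, params, n_weeks,
                    update_weight = update_weight)
  visits <- seq(3, months, by = 3)
  set.seed(seed_stream(seed, "sparse-residual"))
  n <- nrow(cohort)
  rows <- lapply(seq_len(n), function(i) {
    # dose rows carry the time-varying body weight (quarterly updates), the
    # covariate a weight-dosed trial would record at each administration
    wt_by_week <- res$weight_quarterly[i, (seq_len(n_weeks) - 1) %/% 13 + 1]
    dose_rows <- data.frame(
      ID = cohort$id[i], TIME = (seq_len(n_weeks) - 1) * WEEK_H,
      AMT = dose_log[i, ], DV = NA, EVID = 1L, MDV = 1L, CMT = CMT_DEPOT,
      WT = wt_by_week, AGE = cohort$age[i], SEX = cohort$sex[i]
    )
    t_trough <- visits / 3 * 13 * WEEK_H - TROUGH_OFFSET_H
    igf_true <- c(res$setup$r0[i], res$trough_igf1[i, visits / 3 * 13])
    igf_dv <- igf_true * (1 + stats::rnorm(length(igf_true), 0, params$idr$sigma_igf))
    igf_rows <- data.frame(
      ID = cohort$id[i], TIME = c(0, t_trough), AMT = 0, DV = igf_dv,
      EVID = 0L, MDV = 0L, CMT = CMT_IGF1,
      WT = cohort$weight[i], AGE = cohort$age[i], SEX = cohort$sex[i]
    )
    gv_true <- vapply(visits, function(m)
      engine_annualized_gv(res, m - 3, m)[i], numeric(1))
    gv_dv <- c(cohort$baseline_gv[i], gv_true) +
      stats::rnorm(length(gv_true) + 1, 0, params$gv$sigma_gv)
    gv_rows <- data.frame(
      ID = cohort$id[i], TIME = c(0, visits / 3 * 13 * WEEK_H), AMT = 0,
      DV = gv_dv, EVID = 0L, MDV = 0L, CMT = CMT_GV,
      WT = cohort$weight[i], AGE = cohort$age[i], SEX = cohort$sex[i]
    )
    pk_rows <- NULL
    if (include_pk) {
      pk_true <- res$trough_conc[i, visits / 3 * 13]
      pk_dv <- pk_true * (1 + stats::rnorm(length(pk_true), 0, params$pk$sigma_prop)) +
        stats::rnorm(length(pk_true), 0, params$pk$sigma_add)
      pk_rows <- data.frame(
        ID = cohort$id[i], TIME = t_trough, AMT = 0, DV = pk_dv,
        EVID = 0L, MDV = 0L, CMT = CMT_PK,
        WT = cohort$weight[i], AGE = cohort$age[i], SEX = cohort$sex[i]
      )
    }
    out <- rbind(dose_rows, igf_rows, gv_rows, pk_rows)
    out[order(out$TIME, out$CMT), ]
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  attr(tab, "engine") <- res
  structure(tab, class = c("obs_table", "data.frame"))
}
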