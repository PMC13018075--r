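# End-to-end trial simulators: quarterly up-titration arms over 24 months in
# the pediatric cohort, and the weight-banded fixed-strength study with
# replicate-based prediction bands over the week-12 dosing interval.

#' Empirical prediction band
#'
#' Empirical lower/median/upper quantiles per time point across replicates.
#' At `level = 0.90` these are the 5th, 50th and 95th percentiles; at
#' `level = 1` the band spans min and max.
#'
#' @param replicate_values Numeric matrix (replicates x time points) or
#'   vector (treated as one time point).
#' @param level Coverage level in (0, 1].
#' @return List of class `prediction_band` with vectors `lower`, `median`,
#'   `upper` (and `times` if the input carried a `times` attribute).
#' @export
prediction_band <- function(replicate_values, level = 0.90) {
  if (is.null(dim(replicate_values)))
    replicate_values <- matrix(replicate_values, ncol = 1)
  if (nrow(replicate_values) < 2) stop("need at least 2 replicates")
  a <- (1 - level) / 2
  qs <- apply(replicate_values, 2, stats::quantile,
              probs = c(a, 0.5, 1 - a), names = FALSE)
  structure(list(lower = qs[1, ], median = qs[2, ], upper = qs[3, ],
                 level = level),
            class = "prediction_band")
}

#' Time-averaged overlap of two prediction bands
#'
#' Jaccard overlap of the two intervals at each time point (length of the
#' intersection over length of the union), averaged over the common grid.
#'
#' @param b1,b2 `prediction_band` objects on the same grid.
#' @return Overlap fraction in `[0, 1]`.
#' @export
band_overlap <- function(b1, b2) {
  if (length(b1$lower) != length(b2$lower)) stop("bands on different grids")
  inter <- pmax(0, pmin(b1$upper, b2$upper) - pmax(b1$lower, b2$lower))
  union <- pmax(b1$upper, b2$upper) - pmin(b1$lower, b2$lower)
  ok <- union > 0
  if (!any(ok)) return(1)  # two zero-width identical bands
  mean(inter[ok] / union[ok])
}

arm_dose_fn <- function(plan, config) {
  sched <- uptitration_schedule(plan, horizon_months = config$horizon_months,
                                round_doses = config$round_titrated)
  function(w, weight) sched$unit_dose[w %/% 13 + 1] * weight
}

#' Simulate the quarterly up-titration study
#'
#' Runs the pediatric cohort under each escalation rate (shared subjects and
#' random effects across arms when `config$paired_arms`) for the full
#' horizon and aggregates arm summaries: annualized growth velocity over
#' months 0-12 and 12-24, trough IGF-1 SDS at the quarterly visits, and the
#' proportion of subjects with trough SDS above +2.
#'
#' @param cohort A [generate_ghd_cohort()] cohort.
#' @param rates Quarterly escalation rates.
#' @param config A [sim_config()].
#' @return List of class `uptitration_study` with `summary` (one row per
#'   arm: Table-3-shaped aggregates), `visits` (per-arm per-visit SDS
#'   statistics) and `arms` (raw engine results).
#' @export
run_uptitration_study <- function(cohort, rates = c(0.123, 0.189, 0.260),
                                  config = sim_config()) {
  stopifnot(config$horizon_months >= 24)
  n_weeks <- round(config$horizon_months / 3 * 13)
  arms <- lapply(rates, function(r) {
    sim_cohort(cohort, arm_dose_fn(titration_plan(rate = r), config),
               config$params, n_weeks, step_h = config$grid_step_h,
               update_weight = config$update_weight)
  })
  names(arms) <- paste0("rate_", rates)
  visit_months <- seq(0, config$horizon_months, by = 3)
  visits <- do.call(rbind, lapply(seq_along(rates), function(a) {
    res <- arms[[a]]
    sds <- engine_trough_sds(res)
    do.call(rbind, lapply(visit_months, function(m) {
      v <- if (m == 0) cohort$baseline_igf1_sds else sds[, m / 3 * 13]
      data.frame(rate = rates[a], month = m,
                 sds_mean = mean(v), sds_sd = stats::sd(v),
                 prop_above_2 = proportion_above(v))
    }))
  }))
  summary <- do.call(rbind, lapply(seq_along(rates), function(a) {
    res <- arms[[a]]
    gv12 <- engine_annualized_gv(res, 0, 12)
    gv24 <- engine_annualized_gv(res, 12, 24)
    v12 <- visits[visits$rate == rates[a] & visits$month == 12, ]
    v24 <- visits[visits$rate == rates[a] & visits$month == 24, ]
    data.frame(
      rate = rates[a],
      gv_baseline_mean = mean(cohort$baseline_gv),
      gv_baseline_sd = stats::sd(cohort$baseline_gv),
      gv12_mean = mean(gv12), gv12_sd = stats::sd(gv12),
      gv24_mean = mean(gv24), gv24_sd = stats::sd(gv24),
      sds_baseline_mean = mean(cohort$baseline_igf1_sds),
      sds12_mean = v12$sds_mean, sds24_mean = v24$sds_mean,
      prop2_baseline = proportion_above(cohort$baseline_igf1_sds),
      prop2_12 = v12$prop_above_2, prop2_24 = v24$prop_above_2
    )
  }))
  structure(list(summary = summary, visits = visits, arms = arms,
                 config = config),
            class = "uptitration_study")
}

#' Simulate the weight-banded fixed-strength study
#'
#' For each product strength, the strength group's base subjects are
#' simulated at each of the five scenario weights (target, +/- narrow,
#' +/- wide) under the fixed weekly strength, paired across scenarios:
#' every replicate redraws the subjects' random effects once per strength
#' and reuses them for all scenarios, so scenario contrasts are free of
#' sampling noise. The read-out window is the dosing interval following the
#' week-12 dose: trough-anchored growth velocity at week 12 and the hourly
#' IGF-1 SDS time course for prediction bands.
#'
#' @param banded_cohort A [generate_banded_cohort()] cohort.
#' @param config A [sim_config()]; `n_replicates` sets the number of
#'   replicate cohorts (500 reproduces the full study design; smaller
#'   values scale it down).
#' @return List of class `banded_study` with `table4` (per strength x
#'   scenario: week-12 GV mean/SD and difference vs the target scenario),
#'   `bands` (per strength: `prediction_band`s of the week-12 IGF-1 SDS
#'   time course per scenario group), and `overlap` (per strength: band
#'   overlap of the narrow/wide groups with the target scenario).
#' @export
run_banded_study <- function(banded_cohort, config = sim_config()) {
  strengths <- sort(unique(banded_cohort$strength))
  scen_names <- c("wide_low", "narrow_low", "target", "narrow_high", "wide_high")
  n_weeks <- 13L
  gv_rows <- list()
  bands <- list()
  overlap <- list()
  for (s in strengths) {
    base <- banded_cohort[banded_cohort$strength == s, ]
    b <- band_edges(s)
    scen_wt <- c(b$lo_wide, b$lo_narrow, b$target_wt, b$hi_narrow, b$hi_wide)
    names(scen_wt) <- scen_names
    nb <- nrow(base)
    # replicate x scenario simulation with shared etas per replicate
    gv_scen <- list()
    sds_scen <- list()
    for (sc in scen_names) {
      subj <- base[rep(seq_len(nb), config$n_replicates), ]
      subj$weight <- scen_wt[[sc]]
      set.seed(seed_stream(config$seed, paste0("banded-etas-", s)))
      et <- draw_etas(nrow(subj), config$params)   # same draw across scenarios
      subj[names(et)] <- et
      res <- sim_cohort(subj, function(w, weight) rep(s, nrow(subj)),
                        config$params, n_weeks, step_h = config$grid_step_h,
                        update_weight = FALSE, record_week12 = TRUE)
      auc12 <- res$auc_weekly[, 12]
      gvp <- config$params$gv
      gv12 <- pmax(0, (subj$baseline_gv +
                         (gvp$emax_gv + subj$eta_gv) * auc12 / (gvp$auc50 + auc12)) *
                     exp(-gvp$lam * 12 / 52))
      gv_scen[[sc]] <- gv12
      sds_scen[[sc]] <- (log(res$week12$igf1) - res$setup$mu_ln) / res$setup$sd_ln
      times <- res$week12$times
    }
    ref_gv <- mean(gv_scen[["target"]])
    for (sc in scen_names) {
      gv_rows[[length(gv_rows) + 1]] <- data.frame(
        strength = s, scenario = sc, weight = scen_wt[[sc]],
        gv_mean = mean(gv_scen[[sc]]), gv_sd = stats::sd(gv_scen[[sc]]),
        gv_diff = mean(gv_scen[[sc]]) - ref_gv
      )
    }
    bands[[as.character(s)]] <- lapply(sds_scen, prediction_band,
                                       level = config$level)
    tb <- bands[[as.character(s)]]
    overlap[[as.character(s)]] <- c(
      narrow = mean(c(band_overlap(tb$narrow_low, tb$target),
                      band_overlap(tb$narrow_high, tb$target))),
      wide = mean(c(band_overlap(tb$wide_low, tb$target),
                    band_overlap(tb$wide_high, tb$target)))
    )
  }
  table4 <- do.call(rbind, gv_rows)
  rownames(table4) <- NULL
  structure(list(table4 = table4, bands = bands, overlap = overlap,
                 config = config),
            class = "banded_study")
}

#' Published-style rounding of the banded-study table
#'
#' @param study A `banded_study`.
#' @return `table4` with means and differences rounded to one decimal.
#' @export
banded_table <- function(study) {
  t4 <- study$table4
  t4$gv_mean <- round(t4$gv_mean, 1)
  t4$gv_sd <- round(t4$gv_sd, 2)
  t4$gv_diff <- round(t4$gv_diff, 1)
  t4
}
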