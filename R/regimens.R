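# Dose-schedule builders: quarterly up-titration of the weekly unit dose
# (mg/kg/week) with rounding and cap, weight-banded fixed-strength
# assignment, and expansion to concrete weekly dose-event schedules.

# Round half away from zero, the convention under which the escalated unit
# doses reproduce the published quarterly schedule cell for cell.
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Quarterly up-titration plan
#'
#' @param start_unit_dose Starting unit dose, mg/kg/week.
#' @param rate Fractional increase per step (e.g. 0.123, 0.189, 0.260).
#' @param step_months Months between escalations.
#' @param cap Maximum unit dose, mg/kg/week.
#' @param rounding Decimal places for the escalated dose.
#' @return An object of class `titration_plan`.
#' @export
titration_plan <- function(start_unit_dose = 0.14, rate = 0.123,
                           step_months = 3, cap = 0.28, rounding = 2) {
  stopifnot(start_unit_dose > 0, start_unit_dose <= cap, rate >= 0,
            step_months > 0)
  structure(list(start_unit_dose = start_unit_dose, rate = rate,
                 step_months = step_months, cap = cap, rounding = rounding),
            class = "titration_plan")
}

#' Quarterly unit-dose schedule under an up-titration plan
#'
#' Dose at escalation step k is `min(round(start * (1+rate)^k), cap)`, the
#' rounding applied half-up to `plan$rounding` decimals of the *unrounded*
#' compound value; once the cap is reached the dose is held there.
#'
#' @param plan A [titration_plan()].
#' @param horizon_months Schedule horizon; must be a multiple of
#'   `step_months`.
#' @param round_doses Apply the 2-dp rounding (default); `FALSE` keeps exact
#'   compound multipliers.
#' @return Data.frame with columns `month` and `unit_dose` (mg/kg/week),
#'   one row per quarterly step from month 0 to `horizon_months`.
#' @export
#' @examples
#' uptitration_schedule(titration_plan(rate = 0.123))$unit_dose
uptitration_schedule <- function(plan, horizon_months = 24,
                                 round_doses = TRUE) {
  if (plan$rate < 0) stop("rate must be non-negative")
  stopifnot(horizon_months %% plan$step_months == 0)
  k <- 0:(horizon_months / plan$step_months)
  raw <- plan$start_unit_dose * (1 + plan$rate)^k
  if (round_doses) raw <- round_half_up(raw, plan$rounding)
  dose <- pmin(raw, plan$cap)
  # hold at cap once attained
  hit <- which(dose >= plan$cap)
  if (length(hit) > 0) dose[seq(min(hit), length(dose))] <- plan$cap
  data.frame(month = k * plan$step_months, unit_dose = dose)
}

#' First month at which a plan reaches its cap
#'
#' @param plan A [titration_plan()].
#' @param horizon_months Search horizon.
#' @return Month (multiple of `step_months`) at which the schedule first
#'   equals the cap.
#' @export
months_to_cap <- function(plan, horizon_months = 60) {
  sched <- uptitration_schedule(plan, horizon_months)
  hit <- which(sched$unit_dose >= plan$cap)
  if (length(hit) == 0)
    stop("cap not reached within ", horizon_months, " months")
  sched$month[min(hit)]
}

#' Weight band for a fixed product strength
#'
#' The target weight is the weight at which the fixed strength equals the
#' reference unit dose (`strength / unit_dose`, rounded to 2 dp); the wide
#' band spans +/- `wide` kg and the narrow band half of that. Band edges are
#' computed on the rounded target and rounded offsets, the convention that
#' reproduces the published weight grid exactly.
#'
#' @param strength Product strength in mg.
#' @param unit_dose Reference unit dose, mg/kg/week.
#' @param wide Wide half-width in kg; defaults to `0.5 / unit_dose` (the
#'   strength increment over the unit dose) rounded to 2 dp.
#' @param narrow Narrow half-width in kg; defaults to half the wide width
#'   rounded half-to-even to 2 dp.
#' @return An object of class `strength_band`: list with `strength`,
#'   `target_wt`, `lo_wide`, `lo_narrow`, `hi_narrow`, `hi_wide`.
#' @export
#' @examples
#' band_edges(2)  # target 14.29, wide band [10.72, 17.86]
band_edges <- function(strength, unit_dose = 0.14,
                       wide = round(0.5 / unit_dose, 2),
                       narrow = round(wide / 2, 2)) {
  stopifnot(strength > 0)
  target <- round_half_up(strength / unit_dose, 2)
  b <- list(strength = strength, target_wt = target,
            lo_wide = target - wide, lo_narrow = target - narrow,
            hi_narrow = target + narrow, hi_wide = target + wide)
  stopifnot(b$lo_wide < b$lo_narrow, b$lo_narrow < b$target_wt,
            b$target_wt < b$hi_narrow, b$hi_narrow < b$hi_wide)
  structure(b, class = "strength_band")
}

#' Assign a product strength by nearest target weight
#'
#' @param weight Body weight in kg (> 0).
#' @param strengths Available strengths in mg.
#' @param unit_dose Reference unit dose, mg/kg/week.
#' @return List with `strength` (mg; ties broken toward the lower strength)
#'   and `in_band` (`FALSE`, with a warning, if the weight falls outside
#'   every wide band).
#' @export
assign_strength <- function(weight, strengths = seq(2, 5, by = 0.5),
                            unit_dose = 0.14) {
  stopifnot(weight > 0)
  bands <- lapply(sort(strengths), band_edges, unit_dose = unit_dose)
  targets <- vapply(bands, `[[`, numeric(1), "target_wt")
  d <- abs(weight - targets)
  pick <- which(d <= min(d) + 1e-12)[1]  # ties -> lower strength
  in_band <- weight >= bands[[pick]]$lo_wide & weight <= bands[[pick]]$hi_wide
  if (!in_band)
    warning(sprintf("weight %.2f kg outside all wide bands", weight))
  list(strength = sort(strengths)[pick], in_band = in_band)
}

#' Expand a unit-dose schedule into a weekly regimen
#'
#' Weekly dose = current quarterly unit dose times the body weight recorded
#' at the most recent quarterly visit, or a constant strength for
#' fixed-strength arms. Doses are spaced exactly 168 h apart.
#'
#' @param unit_dose_schedule Output of [uptitration_schedule()], or `NULL`
#'   for a fixed-strength regimen.
#' @param weight_series Weights (kg) at each quarterly visit covering the
#'   horizon; recycled if length 1.
#' @param horizon_months Regimen span in months.
#' @param strength Fixed strength (mg) when `unit_dose_schedule` is `NULL`.
#' @return An object of class `regimen`: dose-event data.frame with
#'   attribute `provenance` in `weight-based`, `titrated`, `fixed-strength`.
#' @export
weekly_regimen <- function(unit_dose_schedule = NULL, weight_series = NULL,
                           horizon_months = 24, strength = NULL) {
  n_weeks <- horizon_months / 3 * 13
  week <- 0:(n_weeks - 1)
  quarter <- week %/% 13
  if (is.null(unit_dose_schedule)) {
    stopifnot(!is.null(strength), strength > 0)
    amt <- rep(strength, n_weeks)
    prov <- "fixed-strength"
  } else {
    stopifnot(!is.null(weight_series))
    if (any(weight_series <= 0)) stop("negative or zero weight")
    wq <- rep_len(weight_series, max(quarter) + 1)
    ud <- unit_dose_schedule$unit_dose[
      match(quarter * 3, unit_dose_schedule$month)]
    if (any(is.na(ud))) stop("unit-dose schedule does not cover the horizon")
    amt <- ud * wq[quarter + 1]
    prov <- if (length(unique(ud)) > 1) "titrated" else "weight-based"
  }
  reg <- dose_events(time = week * 168, amount = amt)
  structure(reg, class = c("regimen", class(reg)), provenance = prov)
}
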