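# Direct-effect growth-velocity model: an Emax function of the preceding
# dosing-interval AUC, attenuated exponentially in time on treatment, with
# height obtained by integrating the velocity.

#' Instantaneous growth velocity
#'
#' `GV(t) = [e0 + (emax_gv + eta) * AUCtau / (auc50 + AUCtau)] * exp(-lam t)`
#' truncated at 0. `eta` is the subject's additive random effect on the
#' maximal drug effect.
#'
#' @param gv A [gv_params()] object.
#' @param auc_tau AUC of the dosing interval preceding the measurement
#'   (mg*h/L, >= 0); vectorised.
#' @param t Time on treatment in years (>= 0); vectorised.
#' @param eta Additive between-subject effect on `emax_gv` (cm/year).
#' @param e0 Optional individual baseline contribution overriding `gv$e0`.
#' @return Growth velocity in cm/year.
#' @export
#' @examples
#' g <- gv_params(e0 = 3.57, emax_gv = 10, auc50 = 100)
#' instantaneous_gv(g, auc_tau = 100, t = 0)  # e0 + emax/2
instantaneous_gv <- function(gv, auc_tau, t, eta = 0, e0 = gv$e0) {
  stopifnot(all(auc_tau >= 0), all(t >= 0))
  pmax(0, (e0 + (gv$emax_gv + eta) * auc_tau / (gv$auc50 + auc_tau)) *
         exp(-gv$lam * t))
}

#' Integrate a growth-velocity function into a height trajectory
#'
#' `H(t) = h0 + integral of GV(s) ds` with GV in cm/year, by the trapezoidal
#' rule on a fixed step.
#'
#' @param gv_fn Function of time in years returning GV in cm/year.
#' @param h0 Starting height (cm).
#' @param horizon_months Trajectory span in months (1 month = 13/3 weeks).
#' @param step_weeks Integration step in weeks (<= 1).
#' @return An object of class `growth_trajectory`: list with `months`,
#'   `height`, `inst_gv`.
#' @export
integrate_height <- function(gv_fn, h0, horizon_months, step_weeks = 1) {
  stopifnot(horizon_months > 0, step_weeks > 0, step_weeks <= 1)
  horizon_wk <- horizon_months / 3 * 13
  t_wk <- seq(0, horizon_wk, by = step_weeks)
  if (t_wk[length(t_wk)] < horizon_wk) t_wk <- c(t_wk, horizon_wk)
  t_yr <- t_wk / 52
  g <- pmax(0, gv_fn(t_yr))
  height <- h0 + c(0, cumsum((g[-1] + g[-length(g)]) / 2 * diff(t_yr)))
  structure(list(months = t_wk * 3 / 13, height = height, inst_gv = g),
            class = "growth_trajectory")
}

#' Annualized growth velocity at a visit
#'
#' Height gained over the 12 months preceding the visit, per year: the
#' 12-month value covers months 0-12 and the 24-month value covers months
#' 12-24 (second-year velocity).
#'
#' @param traj A `growth_trajectory`.
#' @param at_month Visit month (>= 12); the trajectory must span
#'   `[at_month - 12, at_month]`.
#' @return Annualized GV in cm/year.
#' @export
annualized_gv <- function(traj, at_month) {
  stopifnot(at_month >= 12)
  h <- stats::approx(traj$months, traj$height,
                     xout = c(at_month - 12, at_month), rule = 1)$y
  if (any(is.na(h))) stop("window outside trajectory")
  h[2] - h[1]
}
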