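# One-compartment population PK with first-order subcutaneous absorption.
# All public solvers are analytic (Bateman superposition or exact
# between-event propagation); an adaptive ODE route is kept as an oracle
# and as a hook for non-linear extensions.

#' Individualise population PK parameters
#'
#' Applies allometric weight scaling and log-normal between-subject random
#' effects to the population values:
#' `CL_i = cl_pop * (WT/wt_ref)^exp_cl * exp(eta[1])`, and analogously for
#' volume (`eta[2]`) and ka (`eta[3]`).
#'
#' @param pop A [pk_params()] object.
#' @param weight Body weight in kg (> 0); vectorised.
#' @param etas Numeric vector or 3-column matrix of random effects
#'   `(eta_cl, eta_v, eta_ka)`; defaults to zeros.
#' @return A list with vectors `cl`, `v`, `ka`, and scalars `ke` implied per
#'   subject, plus `f`.
#' @export
#' @examples
#' p <- nominal_params()$pk
#' individual_pk(p, weight = p$wt_ref)  # typical values
individual_pk <- function(pop, weight, etas = c(0, 0, 0)) {
  stopifnot(inherits(pop, "pk_params"), all(weight > 0))
  if (is.null(dim(etas))) etas <- matrix(etas, nrow = 1)
  if (!all(is.finite(etas))) stop("non-finite eta")
  n <- max(length(weight), nrow(etas))
  weight <- rep_len(weight, n)
  cl <- pop$cl_pop * (weight / pop$wt_ref)^pop$exp_cl * exp(rep_len(etas[, 1], n))
  v <- pop$v_pop * (weight / pop$wt_ref)^pop$exp_v * exp(rep_len(etas[, 2], n))
  ka <- pop$ka_pop * exp(rep_len(etas[, 3], n))
  list(cl = cl, v = v, ka = ka, ke = cl / v, f = pop$f_bio)
}

#' Concentration after a single subcutaneous dose
#'
#' Bateman solution of the one-compartment first-order absorption model,
#' `C(t) = F D ka / (V (ka - ke)) * (exp(-ke t) - exp(-ka t))` for `t >= 0`
#' and 0 before the dose. When `ka` and `ke` coincide to within relative
#' 1e-8 the analytic limit `F D ka t exp(-ka t) / V` is used.
#'
#' @param par Individual parameters as returned by [individual_pk()] (uses
#'   the first subject), or a list with `cl`, `v`, `ka`, `f`.
#' @param dose Dose amount in mg.
#' @param t Hours since the dose; vectorised.
#' @return Concentration in mg/L.
#' @export
conc_single_dose <- function(par, dose, t) {
  stopifnot(dose >= 0)
  ka <- par$ka[1]; v <- par$v[1]; ke <- par$cl[1] / v
  f <- if (is.null(par$f)) 1 else par$f
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  if (abs(ka - ke) < 1e-8 * ka) {
    out[pos] <- f * dose * ka * tp * exp(-ka * tp) / v
  } else {
    out[pos] <- f * dose * ka / (v * (ka - ke)) * (exp(-ke * tp) - exp(-ka * tp))
  }
  pmax(out, 0)
}

# Integral of the Bateman curve from dose time to u hours post-dose.
single_dose_auc_to <- function(par, dose, u) {
  ka <- par$ka[1]; v <- par$v[1]; ke <- par$cl[1] / v
  f <- if (is.null(par$f)) 1 else par$f
  dose <- rep_len(dose, length(u))
  out <- numeric(length(u))
  pos <- u > 0
  up <- u[pos]
  out[pos] <- f * dose[pos] * ka / (v * (ka - ke)) *
    ((1 - exp(-ke * up)) / ke - (1 - exp(-ka * up)) / ka)
  out
}

#' Build a dose-event table
#'
#' @param time Hours since first dose (>= 0).
#' @param amount Dose in mg (>= 0).
#' @return A data.frame with columns `time`, `amount` (route is always the
#'   subcutaneous depot).
#' @export
dose_events <- function(time, amount) {
  stopifnot(all(time >= 0), all(amount >= 0),
            length(time) == length(amount))
  o <- order(time)
  data.frame(time = time[o], amount = amount[o])
}

#' Weekly dose events
#'
#' @param amounts Vector of weekly dose amounts (mg), one per week.
#' @param interval_h Dosing interval in hours (168 for weekly).
#' @return A dose-event data.frame.
#' @export
weekly_doses <- function(amounts, interval_h = 168) {
  dose_events(time = (seq_along(amounts) - 1) * interval_h, amount = amounts)
}

#' Simulate a concentration profile under an arbitrary dose schedule
#'
#' Linear superposition of per-dose Bateman solutions evaluated on a time
#' grid.
#'
#' @param par Individual PK parameters ([individual_pk()]).
#' @param doses A dose-event data.frame ([dose_events()]); may be empty.
#' @param grid Strictly increasing time grid in hours, starting at or before
#'   the first dose.
#' @return An object of class `conc_profile`: list with `times`, `conc`.
#' @export
simulate_pk <- function(par, doses, grid) {
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  conc <- numeric(length(grid))
  if (nrow(doses) > 0) {
    if (min(doses$time) < grid[1]) stop("dose before grid start")
    for (i in seq_len(nrow(doses))) {
      conc <- conc + conc_single_dose(par, doses$amount[i], grid - doses$time[i])
    }
  }
  structure(list(times = grid, conc = conc), class = "conc_profile")
}

#' Area under the concentration curve on an interval
#'
#' Exact integral of the superposed analytic solution on `[t0, t1]`; for a
#' weekly dose D at steady state this converges to `F * D / CL`.
#'
#' @param par Individual PK parameters.
#' @param doses Dose-event data.frame.
#' @param t0,t1 Interval bounds in hours, `t1 > t0`.
#' @return AUC in mg*h/L.
#' @export
auc_interval <- function(par, doses, t0, t1) {
  stopifnot(t1 > t0)
  if (nrow(doses) == 0) return(0)
  sum(single_dose_auc_to(par, doses$amount, t1 - doses$time) -
        single_dose_auc_to(par, doses$amount, t0 - doses$time))
}

#' Steady-state PK summaries for constant weekly dosing
#'
#' Closed-form accumulation expressions for repeated dosing of amount `dose`
#' every `tau` hours: trough concentration just before a steady-state dose
#' and the steady-state interval AUC `F * dose / CL`.
#'
#' @param par Individual PK parameters.
#' @param dose Weekly dose (mg).
#' @param tau Dosing interval (h).
#' @return List with `trough`, `auc_tau`.
#' @export
pk_steady_state <- function(par, dose, tau = 168) {
  ka <- par$ka[1]; v <- par$v[1]; ke <- par$cl[1] / v
  f <- if (is.null(par$f)) 1 else par$f
  acc <- function(k) exp(-k * tau) / (1 - exp(-k * tau))
  trough <- f * dose * ka / (v * (ka - ke)) * (acc(ke) - acc(ka))
  list(trough = trough, auc_tau = f * dose / par$cl[1])
}

#' ODE solution of the PK model (oracle / extension hook)
#'
#' Integrates depot and central compartments with [deSolve::lsoda] at tight
#' tolerances. Used in tests as the independent oracle for the analytic
#' solvers.
#'
#' @inheritParams simulate_pk
#' @param rtol,atol Solver tolerances.
#' @return A `conc_profile`.
#' @export
simulate_pk_ode <- function(par, doses, grid, rtol = 1e-8, atol = 1e-10) {
  ka <- par$ka[1]; v <- par$v[1]; ke <- par$cl[1] / v
  f <- if (is.null(par$f)) 1 else par$f
  deriv <- function(t, y, parms) {
    list(c(-ka * y[1], ka * y[1] / v - ke * y[2]))
  }
  evt <- NULL
  if (nrow(doses) > 0) {
    evt <- list(data = data.frame(var = 1, time = doses$time,
                                  value = f * doses$amount, method = "add"))
  }
  times <- sort(unique(c(grid, doses$time)))
  out <- deSolve::lsoda(c(A = 0, C = 0), times, deriv, parms = NULL,
                        events = evt, rtol = rtol, atol = atol)
  conc <- out[match(grid, out[, "time"]), "C"]
  structure(list(times = grid, conc = pmax(conc, 0)), class = "conc_profile")
}
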