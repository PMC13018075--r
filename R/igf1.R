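# Indirect-response model for IGF-1: drug concentration stimulates
# production, dR/dt = kin_i * (1 + smax*C/(sc50+C)) - kout * R. The default
# integrator is an exponential trapezoidal scheme that is exact for constant
# concentration and second-order for smooth profiles; deSolve serves as the
# oracle in tests.

idr_stim <- function(idr, conc) 1 + idr$smax * conc / (idr$sc50 + conc)

#' Steady-state IGF-1 at a constant drug concentration
#'
#' Closed form `(kin/kout) * (1 + smax * C / (sc50 + C))` with the
#' individual production rate `kin_i = kout * r0`.
#'
#' @param idr An [idr_params()] object.
#' @param c_const Constant concentration (>= 0); vectorised.
#' @param r0 Individual baseline IGF-1; defaults to the population baseline
#'   `kin/kout`.
#' @return Steady-state IGF-1 level.
#' @export
igf1_steady_state <- function(idr, c_const, r0 = idr$kin / idr$kout) {
  stopifnot(all(c_const >= 0))
  r0 * idr_stim(idr, c_const)
}

#' Simulate IGF-1 dynamics driven by a concentration profile
#'
#' Integrates the indirect-response ODE on the profile's time grid with an
#' exponential trapezoidal update: over each step the stimulation function
#' is averaged between the endpoints and the linear turnover part is
#' propagated exactly, so a drug-free profile stays at baseline to machine
#' precision.
#'
#' @param idr An [idr_params()] object.
#' @param conc A `conc_profile` from [simulate_pk()].
#' @param r0 Individual baseline IGF-1 (> 0), the drug-free steady state.
#' @return An object of class `igf1_profile`: list with `times`, `igf1`.
#' @export
simulate_igf1 <- function(idr, conc, r0 = idr$kin / idr$kout) {
  stopifnot(r0 > 0)
  times <- conc$times
  s <- idr_stim(idr, conc$conc)
  r <- numeric(length(times))
  r[1] <- r0
  kin_i <- idr$kout * r0
  h <- diff(times)
  ek <- exp(-idr$kout * h)
  for (i in seq_along(h)) {
    sbar <- (s[i] + s[i + 1]) / 2
    r[i + 1] <- r[i] * ek[i] + (kin_i * sbar / idr$kout) * (1 - ek[i])
  }
  structure(list(times = times, igf1 = r), class = "igf1_profile")
}

#' ODE oracle for the indirect-response model
#'
#' @inheritParams simulate_igf1
#' @param rtol,atol Solver tolerances.
#' @return An `igf1_profile`.
#' @export
simulate_igf1_ode <- function(idr, conc, r0 = idr$kin / idr$kout,
                              rtol = 1e-8, atol = 1e-10) {
  cfun <- stats::approxfun(conc$times, conc$conc, rule = 2)
  kin_i <- idr$kout * r0
  deriv <- function(t, y, parms) {
    list(kin_i * idr_stim(idr, cfun(t)) - idr$kout * y)
  }
  out <- deSolve::lsoda(c(R = r0), conc$times, deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  if (nrow(out) < length(conc$times))
    stop("IGF-1 ODE solver failed to cover the requested span")
  structure(list(times = conc$times, igf1 = out[, "R"]), class = "igf1_profile")
}

#' Convert IGF-1 concentrations to standard deviation scores
#'
#' `SDS = (log(value) - mu_ln(age, sex)) / sd_ln(age, sex)` against the
#' packaged log-normal reference; `sds_to_igf1` is the exact inverse.
#'
#' @param value IGF-1 level (> 0); vectorised.
#' @param age Age in years; must lie within the reference span (no silent
#'   extrapolation).
#' @param sex `"M"` or `"F"`.
#' @param ref An [igf1_reference()] table.
#' @return SDS (dimensionless), or IGF-1 level for the inverse.
#' @export
igf1_to_sds <- function(value, age, sex, ref = igf1_reference()) {
  stopifnot(all(value > 0))
  mu <- ref_interp(ref, sex, "mu_ln", age)
  sd <- ref_interp(ref, sex, "sd_ln", age)
  (log(value) - mu) / sd
}

#' @rdname igf1_to_sds
#' @param sds Standard deviation score to invert.
#' @export
sds_to_igf1 <- function(sds, age, sex, ref = igf1_reference()) {
  mu <- ref_interp(ref, sex, "mu_ln", age)
  sd <- ref_interp(ref, sex, "sd_ln", age)
  exp(mu + sd * sds)
}

#' Pre-dose trough series from an IGF-1 profile
#'
#' For each requested visit (months since first dose, on the quarterly
#' schedule), returns the profile value at the last grid point strictly
#' before that visit's dose administration. Month 0 returns the profile
#' start (pre-first-dose baseline).
#'
#' @param profile An `igf1_profile` (or any list with `times` and a value
#'   vector named `igf1`).
#' @param dose_times Dose administration times in hours.
#' @param visit_months Visit months (multiples of 3, within the simulated
#'   span). One month is 13/3 weeks.
#' @return Numeric vector of trough values, one per visit.
#' @export
trough_igf1_series <- function(profile, dose_times, visit_months) {
  vapply(visit_months, function(m) {
    t_visit <- m / 3 * 13 * 168
    if (m == 0) return(profile$igf1[1])
    d_prev <- dose_times[dose_times < t_visit]
    if (length(d_prev) == 0) stop("visit before first dose")
    idx <- which(profile$times < t_visit)
    if (length(idx) == 0) stop("visit before profile start")
    profile$igf1[max(idx)]
  }, numeric(1))
}

#' @rdname trough_igf1_series
#' @param age,sex Subject age (years) and sex for the SDS conversion.
#' @param ref An [igf1_reference()] table.
#' @return `trough_sds_series`: the trough values converted to SDS.
#' @export
trough_sds_series <- function(profile, dose_times, visit_months, age, sex,
                              ref = igf1_reference()) {
  igf1_to_sds(trough_igf1_series(profile, dose_times, visit_months),
              age, sex, ref)
}

#' Fraction of a sample exceeding a safety threshold
#'
#' @param sds_values Numeric sample of SDS values (non-empty; NAs dropped).
#' @param threshold Safety ceiling, by convention +2.
#' @return Fraction in `[0, 1]` (multiply by 100 to report as %).
#' @export
proportion_above <- function(sds_values, threshold = 2) {
  sds_values <- sds_values[!is.na(sds_values)]
  if (length(sds_values) == 0) stop("empty sample")
  mean(sds_values > threshold)
}
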