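---
title: "Models and methods behind pegsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pegsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pegsim)
```

pegsim simulates once-weekly pegylated recombinant human growth hormone
(rhGH) therapy in pediatric growth hormone deficiency (GHD) and supports two
dosing-strategy questions: whether quarterly dose up-titration counteracts
the usual year-over-year waning of growth velocity (GV), and whether fixed
product strengths can safely replace exact mg/kg dosing within body-weight
bands. This vignette describes the models, their assumptions, the numerical
choices, and what the simulations can and cannot show.

## Structural models

**Pharmacokinetics.** A one-compartment model with first-order subcutaneous
absorption and linear elimination:

$$\frac{dA}{dt} = -k_a A, \qquad
  V\frac{dC}{dt} = k_a A - CL \cdot C,$$

with depot doses $F\cdot D$ at 168-hour intervals. The true compartmental
structure of the conjugate has not been published; one-compartment linear
kinetics is the parsimonious default for a 40 kDa PEG conjugate, makes
analytic solutions (and therefore exact oracles) available, and is
structured to be swappable: every consumer sees only concentration
profiles and interval AUCs. Clearance and volume scale allometrically,
$CL_i = CL_{pop}(W/25)^{0.75} e^{\eta}$, $V_i = V_{pop}(W/25)^{1}
e^{\eta}$, the standard pediatric convention with the 25 kg reference
chosen mid-range of the banded weights. Between-subject variability is
log-normal on $CL$, $V$, $k_a$; residual error is proportional plus
additive.

**IGF-1.** An indirect-response model in which drug concentration
stimulates IGF-1 production:

$$\frac{dR}{dt} = k_{in,i}\left(1 + \frac{S_{max} C}{SC_{50} + C}\right)
  - k_{out} R, \qquad k_{in,i} = k_{out} R_{0,i}.$$

Stimulation of production (rather than inhibition of loss) matches how
long-acting rhGH drives IGF-1. Tying the individual production rate to the
individual baseline makes the drug-free steady state each subject's own
baseline, so a cohort whose baseline IGF-1 SDS is standardised to a given
value stays there exactly until dosed. IGF-1 is reported as an age- and
sex-standardised SDS on the log scale, $SDS = (\ln R - \mu_{\ln}(a, s)) /
\sigma_{\ln}(a, s)$, against a packaged synthetic reference (see below).

**Growth velocity.** A direct-effect model driven by the AUC of the dosing
interval preceding each measurement, with first-order attenuation in time
on treatment:

$$GV(t) = \left[E_0 + \frac{(E_{max} + \eta_{gv})\,AUC_\tau}
  {AUC_{50} + AUC_\tau}\right] e^{-\lambda t},$$

truncated at zero. The attenuation factor is required to reproduce the
universal first-to-second-year GV decline observed at constant dose with
both daily and long-acting rhGH; without it ($\lambda = 0$) first- and
second-year velocities coincide, which the tests verify as a limit. Height
is the integral of GV ($AUC_\tau$ held piecewise-constant within each
week), and the annualized GV at a visit is the height gained over the
preceding 12 months: the 12-month value covers months 0-12, the 24-month
value months 12-24 (second-year velocity). The source material is
ambiguous about whether its 24-month "annualized GV" is second-year
velocity or a last-interval value; second-year velocity is adopted because
it makes the reported first-to-second-year reduction percentages
internally consistent.

## Calendar and trough conventions

Time is in hours internally. One quarter is exactly 13 weekly doses
(2184 h) and one year 52 weeks, so "month $m$" labels week $13m/3$.
Pre-dose (trough) read-outs are taken 167.9 h after the previous dose; the
integration grid contains that point by construction. The week-12
"steady-state" read-out window is the dosing interval following the
week-12 dose — by then the terminal half-life of about 3.3 days implies
accumulation beyond 99% of steady state.

## Dose schedules

The quarterly up-titration schedule is $\min(\text{round}(0.14(1+r)^k,\ 2),
0.28)$ mg/kg/week at quarter $k$, rounding half-up on the unrounded
compound value; this reproduces the published 27-cell schedule for
$r \in \{0.123, 0.189, 0.260\}$ and cap attainment at months 18, 12 and 9.
Weight-banded dosing assigns a fixed strength (2-5 mg in 0.5 mg steps) with
target weight $\text{round}(\text{strength}/0.14,\ 2)$ kg and bands of
$\pm 3.57$ kg (wide, $= 0.5/0.14$) and $\pm 1.78$ kg (narrow, half the
wide width as printed); band arithmetic is performed on the 2-dp rounded
values, which reproduces all 35 published boundary weights exactly
(e.g. $14.29 - 3.57 = 10.72$, not the 10.71 that unrounded arithmetic
would give). Weight-based arm doses are recomputed at quarterly visits
(the standard follow-up schedule) and are *not* snapped to vial strengths;
snapping exists only in the fixed-strength arms.

## Nominal parameters and calibration

The originating trials' fitted parameters were never published, so the
package ships a nominal, calibrated stand-in
(`nominal_params()`). PK values give a 3.3-day terminal half-life
(consistent with weekly dosing and week-12 steady state). The PD constants
were calibrated once with `scripts/calibrate_nominal.R`, which runs the
292-subject up-titration study and minimises the distance to the published
arm-level summaries: baseline GV 3.57 cm/year at zero exposure, 12-month
arm means inside the 9.51-9.88 cm/year range, second-year convergence near
9.35 cm/year, and 12/24-month mean IGF-1 SDS near 0.37-0.82. The result
(`emax_gv` 8.41 cm/year, `auc50` 52.1 mg·h/L, `lam` 0.100/year, `sc50`
1.33 mg/L) implies strong saturation above roughly 0.22 mg/kg/week, which
is exactly what makes the three escalation arms converge in year two. The
between-subject SD on the GV effect (2.85 cm/year) was set so the
simulated 12-month GV SD lands near the reported 2.35 cm/year. An exact
reproduction of all four printed arm means is impossible for this
three-parameter family (the printed 12-month spread 9.51/9.85/9.88 with a
common 9.35 at 24 months over-determines it); the calibrated optimum
reproduces the ordering, the band and the convergence, which is what the
acceptance checks assert.

## Synthetic cohorts and references

The growth reference (weight/height medians by age 3-16 and sex, constant
CVs) and the IGF-1 standardisation table (log-scale mean and SD by age and
sex) are smooth synthetic tables, clearly labelled non-clinical; every
downstream computation depends only on their interface. Consequently
absolute IGF-1 concentrations are arbitrary — only SDS logic is
meaningful. SDS conversions use each subject's baseline age throughout,
which keeps baseline standardisation exact and is self-consistent with the
age-constant production rate; modelling age-advancing IGF-1 reference
drift is out of scope.

The pediatric GHD cohort draws ages uniformly (4-12 years), sexes 1:1 in
expectation, weights/heights around the reference channels shifted
downward (short stature), baseline GV from Normal(3.57, 1.06) truncated at
zero (a negative draw has probability about 4e-4) and baseline IGF-1 SDS
from Normal(-1.27, 0.55). The 70-subject banded cohort takes, per
strength, ten subjects (five per sex) whose ages are back-solved so the
reference median weight matches the strength's target weight, with actual
weights cycling through the five scenario points; baseline SDS is
standardised to -1. During simulation, weight advances along each
subject's reference channel: the height gained implies an age on the
height channel, and the weight channel is read at that age. Children on
rhGH outgrow the reference median slope, so implied age advances faster
than calendar age; beyond the table edge the weight holds flat.

Residual-error defaults (15% proportional PK, 10% IGF-1, 0.5 cm/year GV)
are applied only by the observation-table generators, never inside the
simulators, and were chosen to make estimation non-trivial but
recoverable.

## Numerics

The PK state is propagated between events with the exact solution of the
linear system, so concentrations, troughs and interval AUCs carry no
solver error at any step size; superposition of Bateman solutions provides
an independent analytic route, and an adaptive ODE solver (relative
tolerance 1e-8) a second, numerical one — the three agree in the tests to
1e-6 or better. The IGF-1 turnover equation is integrated with an
exponential trapezoidal rule (exact for constant concentration,
second-order otherwise) on an hourly grid; against the adaptive solver the
error is below 0.1%. The trial engines are vectorised across subjects, so
the 292-subject three-arm 24-month study runs in about a second and the
100-replicate banded study in seconds.

Simulation problem sizes used by the shipped tests and acceptance script:
the full 292-subject cohort for the up-titration study, 100 replicates
(scaled from the design's 500) for the banded study, and 20 replicate
studies of 50 subjects each for parameter recovery.

## Estimation

The population PK fit approximates the marginal likelihood FOCE-style:
per-subject conditional modes of $(\eta_{CL}, \eta_V, \eta_{ka})$ are
found by damped Gauss-Newton on the joint density with interaction (the
residual variance is evaluated at the conditional prediction), and the
Laplace correction uses the Gauss-Newton curvature. The outer problem
optimises log fixed effects, log omegas and the log proportional error SD
with `nlminb` under an explicit central-difference gradient; the package's
convergence policy is optimizer success or a stationary point with scaled
gradient norm below 1e-3 of the objective magnitude (the warm-started
inner optimisation leaves numerical noise that makes tighter absolute
thresholds meaningless). With all omegas fixed at zero the same code path
reduces exactly to the naive pooled extended-least-squares objective.

The PD stage is sequential in the individual-PK-parameters sense: each
subject's PK random effects are frozen at their empirical-Bayes modes
(prior mode zero, with a shrinkage flag, for subjects without PK rows),
individual concentration and weekly-AUC grids are precomputed — honouring
the quarterly weight updates recorded on the dose rows — and then the
IGF-1 parameters $(S_{max}, SC_{50})$ are fit by log-scale least squares
and the GV parameters $(E_0, E_{max}, AUC_{50}, \lambda)$ by least
squares. Both random effects enter their models additively/linearly in a
way that leaves the pooled mean model unbiased. $k_{out}$ is treated as a
known constant: quarterly trough-only sampling carries no information
about a turnover that settles within days. Which sequential variant the
original analysis used is unstated; only the frozen-individual-parameters
variant is implemented.

**Identifiability of the growth Emax pair.** Under therapeutic dosing all
exposures sit well above the calibrated $AUC_{50}$, so $(E_{max},
AUC_{50})$ lie on a shallow likelihood ridge and single-regimen recovery
studies showed 20-seed mean biases above 20% for $AUC_{50}$. The packaged
recovery study (`recovery_study()`) therefore splits the PD cohort across
three regimens — 0.07 mg/kg/week flat, 0.14 flat, and 26% quarterly
titration — mirroring the dose-finding plus confirmatory composition of a
real development program and providing exposure contrast at matched
treatment times. With that design all 20-seed mean biases fall within
±15% (PK fixed effects) and ±20% (PD fixed effects); noise-free fits
recover the generating values to better than 0.1%.

## Design choices that were genuinely open

* **Paired arms.** The three escalation arms share subjects and random
  effects, and the banded scenarios share each strength group's subjects
  and per-replicate effects. The published identical 24-month values
  across arms suggest shared virtual subjects; pairing also removes
  sampling noise from arm contrasts, which is why the reference-scenario
  GV difference is exactly zero by construction. A flag un-pairs.
* **Rounded titrated doses.** The printed schedule is rounded to 2 dp and
  the simulators use those rounded values by default
  (`round_titrated = FALSE` switches to exact multipliers).
* **Trough definition.** 167.9 h after the previous dose, i.e. just before
  the next one; proportions above the +2 SDS safety ceiling are computed
  on those pre-dose values.
* **Banded scenarios by re-weighting.** Each strength's ten base subjects
  are simulated at all five scenario weights rather than only at their own
  generated weight, which is how scenario-level prediction bands for "the
  same children, heavier or lighter" are obtained.

## Limitations

The trial datasets behind the original analysis are not public and its
fitted parameters were never printed, so everything quantitative here is a
calibrated stand-in: simulated arm summaries reproduce the reported
orderings, bands and convergence, not the exact printed values (the
original authors themselves note their simulated velocities run below
clinical observations). The synthetic growth and IGF-1 references are not
clinical standards. Absolute exposure units are internally consistent but
arbitrary. Passing tests demonstrate correctness of the machinery and
qualitative fidelity of the study-level behaviour on synthetic data; they
do not validate predictions for real children. Puberty, bone age,
adherence, dropout, immunogenicity and adult-height projection are out of
scope.
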