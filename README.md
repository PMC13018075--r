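# pegsim

Population PK/PD simulation of once-weekly pegylated recombinant human
growth hormone (rhGH) dosing in pediatric growth hormone deficiency (GHD).

Children on growth hormone — daily or long-acting — show a well-documented
waning of growth velocity (GV) after the first treatment year, and mg/kg
dosing forces continual dose recalculation as they grow. pegsim is built
for pharmacometricians and trial designers who want to explore two
counter-strategies quantitatively: **quarterly dose up-titration**
(0.14 mg/kg/week escalated by a fixed percentage every 3 months, capped at
0.28) and **weight-banded fixed-strength dosing** (one vial strength for
every child within a weight band).

The model chain is

* a one-compartment population PK model with first-order subcutaneous
  absorption, allometric weight scaling
  (CL<sub>i</sub> = CL·(W/25)<sup>0.75</sup>·e<sup>η</sup>) and log-normal
  between-subject variability;
* an indirect-response model for IGF-1,
  dR/dt = k<sub>in,i</sub>·(1 + S<sub>max</sub>·C/(SC<sub>50</sub> + C)) − k<sub>out</sub>·R,
  reported as an age/sex-standardised SDS;
* a direct-effect growth-velocity model driven by the dosing-interval AUC,
  GV(t) = [E<sub>0</sub> + E<sub>max</sub>·AUC<sub>τ</sub>/(AUC<sub>50</sub> + AUC<sub>τ</sub>)]·e<sup>−λt</sup>,
  integrated into height.

Around the models sit dose-schedule builders, virtual-cohort generators,
trial simulators with replicate prediction bands, NONMEM-style dataset
I/O, and a sequential FOCE-style estimation stage (population PK first,
then IGF-1 and GV parameters conditioned on empirical-Bayes individual
PK). The methods vignette
(`vignettes/pkpd-simulation-methods.Rmd`) documents every model,
convention and calibration choice.

## Worked example

Escalating 18.9% per quarter reaches the 0.28 mg/kg/week cap at month 12:

```r
library(pegsim)
uptitration_schedule(titration_plan(rate = 0.189))
#>   month unit_dose
#> 1     0      0.14
#> 2     3      0.17
#> 3     6      0.20
#> 4     9      0.24
#> 5    12      0.28
#> ...                  (held at the 0.28 cap thereafter)
```

Simulate the 292-subject virtual GHD cohort under the three published
escalation rates for 24 months:

```r
cohort <- generate_ghd_cohort(n = 292, seed = 1)
study  <- run_uptitration_study(cohort, config = sim_config(seed = 1))
round(study$summary[, c("rate", "gv12_mean", "gv12_sd", "gv24_mean",
                        "sds12_mean", "prop2_12")], 2)
#>   rate gv12_mean gv12_sd gv24_mean sds12_mean prop2_12
#> 1 0.12      9.63    2.29      9.27       0.50     0.00
#> 2 0.19      9.74    2.32      9.36       0.62     0.02
#> 3 0.26      9.82    2.34      9.36       0.73     0.02
```

Reading the table: first-year annualized GV rises with the escalation rate
(9.63 → 9.82 cm/year, versus a 3.57 cm/year untreated baseline), while the
second-year velocities converge (spread < 0.1 cm/year) because the effect
saturates once every arm sits at the cap — faster titration buys
first-year growth, not second-year growth. Mean trough IGF-1 SDS at 12
months stays well below the +2 safety ceiling, with only ~2% of subjects
above it in the fastest arm.

Weight-banded dosing in one line: which children can receive the 3.5 mg
vial under the reference 0.14 mg/kg/week regimen?

```r
band_edges(3.5)
#> 3.5 mg serves 21.43-28.57 kg (narrow 23.22-26.78), target 25.00 kg
```

`run_banded_study()` then quantifies what the band costs: simulated
week-12 GV for children at the band edges differs from exact mg/kg dosing
by ≤ ~0.3 cm/year within the narrow (±1.78 kg) band, roughly half the
wide-band difference, with 90% prediction bands of the IGF-1 SDS time
course overlapping the reference scenario by ~90%.

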