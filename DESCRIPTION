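Package: pegsim
Title: Population PK/PD Simulation of Weekly Pegylated Growth Hormone Dosing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and estimation toolkit for once-weekly pegylated
    recombinant human growth hormone in pediatric growth hormone deficiency.
    Chains a one-compartment population pharmacokinetic model with first-order
    subcutaneous absorption, an indirect-response model for IGF-1 stimulation
    with conversion to age- and sex-standardised SDS, and a direct-effect
    growth-velocity model driven by the dosing-interval AUC with first-order
    attenuation. Includes dose-schedule builders for quarterly up-titration
    and weight-banded fixed-strength dosing, virtual-cohort generators,
    replicate trial simulators with prediction bands, NONMEM-style dataset
    input/output, and a sequential nonlinear mixed-effects estimation stage
    (FOCE-style Laplace approximation) for parameter recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
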