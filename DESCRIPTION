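Package: psmforge
Title: Three-State Partitioned Survival Models from Digitized Kaplan-Meier Curves
Version: 0.1.0
Authors@R:
    person("psmforge", "developers", email = "psmforge@example.org", role = c("aut", "cre"))
Description: Builds three-state (progression-free / progressed / dead)
    partitioned survival cost-effectiveness models starting from digitized
    Kaplan-Meier coordinates. Reconstructs approximate individual patient
    time-to-event data from monthly survival probabilities and published
    numbers at risk, fits eight parametric survival families by maximum
    likelihood with AIC model comparison, estimates or applies a constant
    hazard ratio for the intervention arm, translates granular posology
    schedules into per-cycle resource consumption, and runs a monthly-cycle
    partitioned survival engine with half-cycle correction, discounting,
    (Q)ALY and cost accumulation, ICER computation and univariate
    deterministic sensitivity analysis. Includes a synthetic-trial generator
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    readxl
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
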