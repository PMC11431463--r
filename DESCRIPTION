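Package: smartpcr
Title: Profile Quality Scoring, Amplification-Curve Modelling and
    Adaptive Control for PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building feedback-driven ("smart") PCR workflows for
    forensic STR profiling. Provides a single-source STR profile data model
    with GeneMapper-style peak-table input and output and threshold-based
    allele calling; a profile quality metric that combines log-density
    penalties on mean peak height and the coefficient of variation with
    artefact and duration terms; baseline subtraction, hyperbolic-tangent
    sigmoid fitting and threshold-cycle estimation for real-time
    amplification curves; a thermocycler program model with per-cycle
    annealing-time ramps; swarm and gradient-pair optimizers for cycling
    parameters; and a closed-loop cycle-by-cycle controller exercised
    against a built-in phenomenological PCR simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
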