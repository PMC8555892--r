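Package: taukinetics
Title: Chemical Kinetics of Tau Seed Replication and Spreading in
    Alzheimer's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the accumulation of tau seeds in
    Alzheimer's disease with chemical kinetics. Implements the
    Fisher-KPP reaction-diffusion model of seed replication and
    spreading across brain regions, classification of rate-limiting
    regimes, grid-based Bayesian inference of effective replication
    rates from multi-assay seed and aggregate time courses, calibration
    of Braak stage to calendar time from stage-by-age tables,
    longitudinal tau-PET rate-versus-signal fitting, decomposition of
    replication into growth and multiplication rates, AT8
    immunohistochemistry quantification, and seedable synthetic-data
    generators emulating each study input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
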