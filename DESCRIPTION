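Package: olfnet
Title: Channel-Network Models of Rodent Nasal Airflow, Odorant Uptake,
    Chromatographic Efficiency and Particle Deposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduced-order models of odorant and aerosol transport in rodent
    nasal cavities. Builds synthetic channel-network noses calibrated to
    micro-CT morphometry, solves steady laminar Hagen-Poiseuille flow with an
    imposed dorsal-medial split, computes dimensionless screening numbers and a
    secondary-flow-strength statistic, solves Graetz-type advection-diffusion
    odorant uptake with an air-mucus Robin wall condition, evaluates olfactory
    architectures as parallel gas-chromatograph columns via the Golay plate
    height equation, and tracks inertial particles (Schiller-Naumann drag,
    gravity, optional Saffman lift) to deposition-efficiency curves versus the
    impaction factor. Tibble-first interfaces with tidy(), glance() and
    autoplot() methods.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
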