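Package: lungburden
Title: Lung Metastasis Burden Quantification, Growth Kinetics and Projected Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies melanized lung-metastasis burden from lobe photographs
    (red-channel extraction, Kapur maximum-entropy thresholding, grid-based
    mm2 calibration, nodule counting), calibrates exponential and power-law
    growth from cross-sectional cohorts in which each mouse is measured once
    at sacrifice, projects per-mouse survival against a critical burden
    threshold with Kaplan-Meier curves and log-rank comparison, and models
    tumor growth suppressed by phagocytic macrophages with a linear-clearance
    ODE. Includes seeded simulators for cohorts, lobe images with known
    ground truth, and treatment regression trajectories, so the full pipeline
    is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
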