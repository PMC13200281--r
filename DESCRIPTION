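Package: rnfltrend
Title: Bivariate Bayesian Trend Analysis of Paired-Device RNFL Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing longitudinal retinal nerve fiber layer (RNFL)
    thickness trajectories measured on the same eyes by two optical coherence
    tomography (OCT) devices. Fits a bivariate Bayesian hierarchical model with
    correlated random intercepts, rates of change, and log residual standard
    deviations, plus within-visit cross-device residual correlation. Includes
    clock-hour sector aggregation of 768-point circle-scan profiles, robust
    outlier screening with paired removal, posterior summaries of device
    differences and residual-SD ratios, per-eye progression classification,
    Bayesian McNemar comparison of paired proportions, and a synthetic-cohort
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
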