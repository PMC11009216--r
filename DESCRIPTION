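Package: danhi
Title: Differential Aging and Health Index from Health-Screening Biomarkers
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates an individual's biological-aging deviation from routine
    health-screening biomarkers using an ensemble of dichotomized-age logistic
    regression models. Each model age n classifies participants as younger or
    older than n; the fitted probability referenced to the model's Youden-index
    cutoff gives a per-age deviation, and the age-weighted mean of these
    deviations is the Differential Aging and Health Index (DAnHI). The package
    also provides a seeded synthetic-cohort simulator with age- and
    sex-dependent biomarker trajectories and latent aging acceleration, data
    cleansing with variance-inflation-factor covariate screening, and a
    mortality evaluation suite: Cox proportional hazards fits, DAnHI risk
    strata with Kaplan-Meier curves and log-rank tests, fixed-horizon AUC, and
    DeLong comparisons of correlated AUCs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    car,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
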