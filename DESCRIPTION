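Package: cardiospectra
Title: Structured Sparse Latent-State Screening for Athlete Cardiovascular Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pre-participation cardiovascular screening for athletic cohorts
    built around two complementary engines: a structured sparse inference model
    that places a capped sparsemax posterior over latent clinical states
    (normal, physiological remodeling, borderline abnormality, pathological)
    under clinical compatibility constraints and a low-rank bilinear scoring
    function, and a risk-stratified exertional embedding that projects athlete
    profiles into a latent space with per-state Mahalanobis prototypes, a
    fidelity margin around benign athletic adaptation, and a hybrid
    alignment/fidelity/orthogonality training loss. A utility layer
    (alpha*TPR - beta*FPR) supports threshold tuning, and a seeded synthetic
    cohort generator emulates the grey zone between athletic remodeling and
    early pathology for controlled evaluation.
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
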