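Package: cd8pet
Title: Quantitative Analysis of Whole-Body CD8 Immuno-PET Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of zirconium-89 CD8
    immuno-PET imaging trials: standardized uptake value (SUV) computation
    and radioactive decay correction, geometric-mean summaries, time-uptake
    curve selection across tracer protein doses, noncompartmental serum
    half-life estimation, an empirical restricted-cubic-spline partial-volume
    adjustment of longitudinal lesion uptake, log-scale linear mixed models
    with patient and nested lesion random intercepts, Kaplan-Meier and
    Firth-penalized Cox survival analysis on baseline-uptake strata, and
    landmark-based coregistration of tumor autoradiography to CD8
    immunohistochemistry with tile-based Kendall rank correlation. Includes
    a seeded synthetic-data generator that emulates the hierarchical
    statistical structure of such trials for method validation, since the
    underlying clinical data are access-restricted.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    lme4,
    lmerTest,
    survival,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
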