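Package: costtraj
Title: Medical Cost Trajectories Around the Onset of Chronic Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of per-capita medical cost trajectories around the
    claims-ascertained onset of aging-related chronic diseases. Provides a
    synthetic Medicare-like claims generator with exported ground truth,
    ICD-9 based incident-case ascertainment (two-record onset rule with
    prevalent-case exclusion), construction of onset-aligned 41-point
    monthly cost profiles with right censoring, Charlson comorbidity and
    ADL/IADL disability stratification, nonlinear least-squares fitting of
    a four-parameter plateau-peak-exponential-decay cost model with a step
    model fallback, and a survival-weighted population cost forecast with
    closed-form constant-hazard and exact Kaplan-Meier variants.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    ggplot2,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
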