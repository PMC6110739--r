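Package: survmeta
Title: Metadata-Driven Survival Analysis for Clinical Tabular Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A metadata-driven pipeline for right-censored clinical cohort
    data. A three-layer metadata codebook (column roles, measurement types,
    categorical dictionaries) governs import, recoding and validation of a
    flat patient-level CSV; inclusion/exclusion filtering with per-criterion
    exclusion accounting; an automatic test-selection flow that builds a
    stratified baseline-characteristics ("Table 1") summary; and a survival
    core implementing the Kaplan-Meier product-limit estimator with Greenwood
    variance, the (stratified, multi-group) log-rank test, and Cox
    proportional-hazards regression by Newton-Raphson on the partial
    likelihood with Efron or Breslow tie handling. A cohort simulator with
    known ground truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices, nortest, jsonlite
Suggests: testthat (>= 3.0.0), survival, withr, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
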