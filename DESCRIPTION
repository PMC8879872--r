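Package: sbrtpkpd
Title: Pharmacokinetic-Pharmacodynamic Modelling of Lung Tumour Response to
    Stereotactic Body Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates lung tumour volume dynamics under hypofractionated
    stereotactic body radiotherapy (SBRT) with a compartmental
    pharmacokinetic-pharmacodynamic (PKPD) model: proliferating and necrotic
    tumour volumes are driven by a Hill-type dose-response whose interaction
    index couples normalised tumour burden and radiation exposure. Provides
    lesion-level cohort input/output with a bundled 19-patient reference
    cohort, per-lesion calibration of the patient-response exponent against
    pre/post-treatment gross tumour volumes, treatment-efficacy and
    regression summaries, initial-volume uncertainty analysis, and a
    synthetic-cohort generator for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
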