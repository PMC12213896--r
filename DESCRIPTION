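Package: thermorad
Title: Virtual Trials of Tumour Response to Radiotherapy and Hyperthermia
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An ordinary-differential-equation model of tumour,
    vasculature and oxygen dynamics under fractionated radiotherapy (RT)
    and high-temperature hyperthermia (HT), together with the machinery
    for in-silico clinical trials: classification of untreated tumours
    into nutrient-limited, space-limited and bistable growth regimes,
    seeded virtual cohorts, construction of RT/HT/RT+HT dosing schedules
    under maximum-tolerated-dose constraints, a Dormand-Prince adaptive
    integrator with treatment-window segmentation, end-of-treatment
    response metrics and stratification, and rule-based treatment
    comparison and regimen ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    parallel,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
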