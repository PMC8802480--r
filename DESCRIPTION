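Package: ventwave
Title: Waveform-Based Detection of Patient Respiratory Effort During
    Pressure Support Ventilation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based detection of the start and end of a patient's
    inspiratory effort from airway-pressure and flow waveforms recorded
    during pressure support ventilation (the waveform method), together
    with the esophageal-pressure reference method, breath and asynchrony
    classification, agreement statistics (Cohen's kappa, sensitivity,
    specificity, predictive values, ROC AUC), the expiratory time
    constant, and a single-compartment patient-ventilator simulator that
    produces ground-truth-labelled synthetic recordings for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
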