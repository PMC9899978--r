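Package: epimap
Title: Epicardial Activation-Recovery Mapping and Early Ischemic
    Repolarization Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-lead unipolar epicardial
    electrograms and surface ECG recorded during acute coronary occlusion.
    Detects per-beat activation and repolarization fiducials (dV/dt minimum
    during the QRS, dV/dt maximum during the T wave), computes natural and
    Bazett rate-corrected activation-recovery and QT intervals, classifies
    core/border/remote ischemic zones from activation delay on the electrode
    grid, derives per-animal map summaries (dispersion of repolarization,
    cross-lead extrema, early repolarization-prolongation flags), and tests
    their association with early-phase ventricular fibrillation (logistic,
    linear and Cox regression, ROC with Youden cutoff, Kaplan-Meier with
    log-rank). Includes a fully ground-truthed synthetic cohort generator
    emulating a porcine occlusion experiment so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    survival,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
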