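Package: pepticc
Title: Measurement-Error-Aware Analysis of MALDI-TOF Peptidomic Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for reliability-focused analysis of MALDI-TOF mass-spectrometry
    peptidomic feature tables. Implements limit-of-detection (LOD) aware
    normalization (sLOD substitution, per-spectrum median or creatinine
    normalization, log2 transformation), intraclass correlation and
    variance-component estimation from replicate designs, nested-ANOVA
    intra-/inter-assay precision, Monte Carlo assessment of ICC reliability
    under left-censoring, and measurement-error-corrected logistic screening
    of features against disease status by regression calibration (RCAL) and
    simulation-extrapolation (SIMEX), together with diagnostic accuracy
    metrics (ROC AUC, sensitivity/specificity, likelihood ratios) and a
    synthetic-data generator emulating the statistical structure of
    repeatability, precision and case-control peptidomic studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pROC,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
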