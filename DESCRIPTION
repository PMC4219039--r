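Package: kbplan
Title: Knowledge-Based DVH Prediction and Plan-Quality Auditing for
    Arc-Therapy Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a knowledge-based planning engine for volumetric
    modulated arc therapy: principal-component models of cumulative
    dose-volume histograms (DVH) and of geometry-based expected dose (GED)
    curves, ordinary-least-squares regression of DVH component scores on
    geometric predictors with leverage-based outlier diagnostics (Cook's
    distance, externally studentized residuals), DVH prediction bands with
    automatic generation of dose-volume optimization objectives, clinical
    dose-volume endpoint pass/fail auditing, and a synthetic virtual-patient
    cohort generator with a known geometry-to-DVH linear structure for
    model-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'pca.R'
    'structure-model.R'
    'prediction.R'
    'kb-model.R'
    'evaluation.R'
    'synthetic.R'
    'io.R'
    'cli.R'
    'dvh-core.R'
    'dvh-metrics.R'
    'ged.R'
    'kbplan-package.R'
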