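#' @include prediction.R
NULL

#' Recommended number of training cases
#'
#' The training engine estimates the ideal number of cases per structure as
#' five times the number of regression parameters; the recommendation is
#' only reported when the available cases fall short of it.
#'
#' @param nParameters number of regression parameters (including the
#'   intercept).
#' @param nCases available training cases.
#' @return the recommended count when `nCases` is below it, otherwise
#'   `NA`.
#' @export
recommendedCases <- function(nParameters, nCases) {
  rec <- 5L * as.integer(nParameters)
  if (nCases < rec) rec else NA_integer_
}

# Resample one patient's structure record onto the relative-dose modelling
# grid: GED and DVH as volume fractions.
.caseOnModelGrid <- function(patient, structure, config, grid) {
  rx <- patient$field$prescription
  absGrid <- grid * rx
  rec <- patient$structures[[structure]]
  ged <- computeGED(rec$geometry, patient$field, config$kernel,
                    grid = absGrid)
  dvh <- resampleDVH(rec$dvh, absGrid)
  list(ged = ged@volume / 100, dvh = dvh@volume / 100,
       features = data.frame(targetVolume = patient$targetVolume,
                             structureVolume = rec$geometry$volumeCm3,
                             inFieldFraction = rec$geometry$inFieldFraction,
                             nArcs = patient$field$nArcs))
}

.structureCaseMatrices <- function(cohort, structure, config, grid) {
  have <- vapply(cohort, function(p) structure %in% names(p$structures),
                 logical(1))
  cases <- cohort[have]
  rows <- lapply(cases, .caseOnModelGrid, structure = structure,
                 config = config, grid = grid)
  ids <- vapply(cases, function(p) p$id, character(1))
  ged <- do.call(rbind, lapply(rows, `[[`, "ged"))
  dvh <- do.call(rbind, lapply(rows, `[[`, "dvh"))
  rownames(ged) <- rownames(dvh) <- ids
  features <- do.call(rbind, lapply(rows, `[[`, "features"))
  rownames(features) <- ids
  list(ids = ids, ged = ged, dvh = dvh, features = features)
}

#' Assemble the training matrices of one structure
#'
#' Resamples every patient's GED and DVH curves for `structure` onto the
#' relative-dose modelling grid (volume-fraction units) and collects the
#' scalar features, i.e. exactly the inputs [fitStructureModel()] and
#' [crossValidate()] consume.
#'
#' @inheritParams fitKBModel
#' @param structure structure name.
#' @return list with `ids`, `ged` (cases x grid), `dvh` (cases x grid)
#'   and `features`.
#' @export
structureTrainingData <- function(cohort, structure, config = kbConfig()) {
  .structureCaseMatrices(cohort, structure, config,
                         relDoseGrid(config$nGrid))
}

#' Train a knowledge-based model on a cohort of plans
#'
#' Trains one [StructureModel-class] per structure present in the cohort,
#' computes the cross-validated goodness of estimation, the regression
#' quality diagnostics and the outlier candidate table, and assembles the
#' training report. Structures with fewer than `config$minCases` cases are
#' excluded from modelling with a warning.
#'
#' @param cohort list of patient records as produced by
#'   [generateCohort()] or [readCohort()]: each has `id`, `field`
#'   (a [fieldConfig()]), `targetVolume`, and `structures`, a named list
#'   of records with `geometry` (a [structureGeometry()]) and `dvh`
#'   (a [DVHCurve-class]).
#' @param config a [kbConfig()].
#' @return a [KBModel-class].
#' @export
fitKBModel <- function(cohort, config = kbConfig()) {
  if (!length(cohort)) stop("empty cohort")
  grid <- relDoseGrid(config$nGrid)
  structures <- unique(unlist(lapply(cohort,
                                     function(p) names(p$structures))))
  models <- list()
  reportRows <- list()
  outlierRows <- list()
  for (s in structures) {
    cm <- .structureCaseMatrices(cohort, s, config, grid)
    n <- length(cm$ids)
    if (n < config$minCases) {
      warning("structure '", s, "' has ", n, " cases (< ",
              config$minCases, "); excluded from modelling")
      next
    }
    model <- fitStructureModel(cm$ged, cm$dvh, cm$features, config,
                               structureName = s, grid = grid,
                               dropRedundant = TRUE)
    goodness <- crossValidate(cm$ged, cm$dvh, cm$features, config,
                              folds = config$cvFolds, seed = config$cvSeed,
                              grid = grid, dropRedundant = TRUE)
    diag <- regressionDiagnostics(model)
    out <- detectOutliers(model, config$cooksThreshold,
                          config$studentizedThreshold, cm$ids)
    models[[s]] <- model
    p <- length(model@predictorNames)
    reportRows[[s]] <- data.frame(
      structure = s, nCases = n, nParameters = p,
      recommendedCases = recommendedCases(p, n),
      averageChiSquare = diag$averageChiSquare,
      modelFit = diag$modelFit,
      goodnessOfEstimation = goodness,
      nOutliers = nrow(out),
      stringsAsFactors = FALSE)
    if (nrow(out)) outlierRows[[s]] <- out
  }
  report <- if (length(reportRows)) do.call(rbind, reportRows) else
    data.frame()
  rownames(report) <- NULL
  outliers <- if (length(outlierRows)) do.call(rbind, outlierRows) else
    data.frame(patientId = character(0), structure = character(0),
               cooksDistance = numeric(0),
               studentizedResidual = numeric(0), reasons = character(0))
  rownames(outliers) <- NULL
  methods::new("KBModel", structures = models, grid = grid,
               config = config, report = report, outliers = outliers)
}

#' Predict DVHs (with bands) for a new patient
#'
#' Resolves the patient's structure names against the model ontology,
#' computes each matched structure's GED curve and returns the predicted
#' DVH band. Unmatched structures are returned for user action, not
#' predicted.
#'
#' @param kb a [KBModel-class].
#' @param patient a patient record (as in [fitKBModel()]; the `dvh` entry
#'   of each structure is not needed).
#' @param synonyms structure-name synonym table (see [mapOntology()]).
#' @return list with `predictions` (named list of [PredictedDVH-class])
#'   and `unmatched` (character vector).
#' @export
predictPlan <- function(kb, patient, synonyms = defaultSynonyms()) {
  map <- mapOntology(names(patient$structures), names(kb@structures),
                     synonyms)
  preds <- list()
  for (plan in names(map$matched)) {
    preds[[plan] ] <- predictStructure(kb, map$matched[[plan]],
                                       patient$structures[[plan]]$geometry,
                                       patient$field, patient$targetVolume)
  }
  list(predictions = preds, unmatched = map$unmatched)
}

#' @describeIn predictPlan predict a single structure by model name;
#'   errors when the model holds no structure of that name.
#' @param structure model structure name.
#' @param geometry a [structureGeometry()].
#' @param field a [fieldConfig()].
#' @param targetVolume target volume in cm^3.
#' @export
predictStructure <- function(kb, structure, geometry, field, targetVolume) {
  if (!structure %in% names(kb@structures))
    stop("no model for structure '", structure, "'")
  model <- kb@structures[[structure]]
  absGrid <- kb@grid * field$prescription
  ged <- computeGED(geometry, field, kb@config$kernel, grid = absGrid)
  features <- data.frame(targetVolume = targetVolume,
                         structureVolume = geometry$volumeCm3,
                         inFieldFraction = geometry$inFieldFraction,
                         nArcs = field$nArcs)
  predictDVH(model, ged@volume / 100, features, field$prescription)
}
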