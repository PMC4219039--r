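#' @include AllClasses.R
NULL

#' Accessors for curve and model objects
#'
#' Slot access for the S4 classes of the package: structure name, dose grid
#' and volume values of a curve, absolute volume, and the pieces of a
#' trained model or a prediction.
#'
#' @param object an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("structureName", function(object) standardGeneric("structureName"))

#' @rdname accessors
#' @export
setGeneric("doseGrid", function(object) standardGeneric("doseGrid"))

#' @rdname accessors
#' @export
setGeneric("volumePct", function(object) standardGeneric("volumePct"))

#' @rdname accessors
#' @export
setGeneric("absoluteVolume", function(object) standardGeneric("absoluteVolume"))

#' @rdname accessors
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))

#' @rdname accessors
#' @export
setGeneric("meanCurve", function(object) standardGeneric("meanCurve"))

#' @rdname accessors
#' @export
setGeneric("pcaComponents", function(object) standardGeneric("pcaComponents"))

#' @rdname accessors
#' @export
setGeneric("explainedVariance",
           function(object) standardGeneric("explainedVariance"))

#' @rdname accessors
#' @export
setGeneric("mostProbable", function(object) standardGeneric("mostProbable"))

#' @rdname accessors
#' @export
setGeneric("lowerBand", function(object) standardGeneric("lowerBand"))

#' @rdname accessors
#' @export
setGeneric("upperBand", function(object) standardGeneric("upperBand"))

#' @rdname accessors
#' @export
setGeneric("violationTotals",
           function(object) standardGeneric("violationTotals"))

#' @rdname accessors
#' @export
setGeneric("trainingReport", function(object) standardGeneric("trainingReport"))

#' @rdname accessors
#' @export
setGeneric("outlierRecords", function(object) standardGeneric("outlierRecords"))

setMethod("structureName", "DVHCurve", function(object) object@structureName)
setMethod("structureName", "StructureModel",
          function(object) object@structureName)
setMethod("structureName", "PredictedDVH",
          function(object) object@structureName)

setMethod("doseGrid", "DVHCurve", function(object) object@doseGrid)
setMethod("doseGrid", "PredictedDVH", function(object) object@doseGrid)

setMethod("volumePct", "DVHCurve", function(object) object@volume)

setMethod("absoluteVolume", "DVHCurve", function(object) object@volumeCm3)

setMethod("nComponents", "PCABasis", function(object) object@nComponents)
setMethod("meanCurve", "PCABasis", function(object) object@meanCurve)
setMethod("pcaComponents", "PCABasis", function(object) object@components)
setMethod("explainedVariance", "PCABasis",
          function(object) object@explainedVariance)

setMethod("mostProbable", "PredictedDVH", function(object) object@mostProbable)
setMethod("lowerBand", "PredictedDVH", function(object) object@lower)
setMethod("upperBand", "PredictedDVH", function(object) object@upper)

setMethod("violationTotals", "PassFailReport", function(object) object@totals)

setMethod("trainingReport", "KBModel", function(object) object@report)
setMethod("outlierRecords", "KBModel", function(object) object@outliers)

#' @describeIn accessors regression coefficients of a structure model
#'   (predictors x DVH components).
#' @export
setMethod("coef", "StructureModel", function(object, ...) object@coefficients)

setMethod("show", "DVHCurve", function(object) {
  cat(sprintf("<%s> %s: %d dose bins, 0-%.2f Gy, volume %.1f cm^3\n",
              class(object), object@structureName,
              length(object@doseGrid), max(object@doseGrid),
              object@volumeCm3))
})

setMethod("show", "PCABasis", function(object) {
  cat(sprintf("<PCABasis> %d grid points, %d components (%.1f%% variance)\n",
              length(object@grid), object@nComponents,
              100 * sum(object@explainedVariance)))
})

setMethod("show", "StructureModel", function(object) {
  cat(sprintf(
    "<StructureModel> %s: %d cases, %d DVH x %d GED components, %d predictors\n",
    object@structureName, object@nTrainingCases,
    object@dvhBasis@nComponents, object@gedBasis@nComponents,
    length(object@predictorNames)))
})

setMethod("show", "KBModel", function(object) {
  cat(sprintf("<KBModel> %d structures: %s\n",
              length(object@structures),
              paste(names(object@structures), collapse = ", ")))
  if (nrow(object@report)) {
    cat("training report:\n")
    print(object@report, row.names = FALSE)
  }
})

setMethod("show", "PredictedDVH", function(object) {
  cat(sprintf("<PredictedDVH> %s: %d dose bins, band width %.2f-%.2f%%\n",
              object@structureName, length(object@doseGrid),
              min(object@upper - object@lower),
              max(object@upper - object@lower)))
})

setMethod("show", "PassFailReport", function(object) {
  t <- object@totals
  cat(sprintf(
    "<PassFailReport> %d patients x %d endpoints: %d violations (%.1f%%), %d patients affected, max %d simultaneous\n",
    object@nPatients, nrow(object@endpoints), t$violations, t$ratePct,
    t$patientsWithViolations, t$maxSimultaneous))
})
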