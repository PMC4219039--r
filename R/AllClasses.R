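#' @include utils.R
NULL

.VOL_TOL <- 1e-6

#' Cumulative dose-volume histogram
#'
#' A cumulative DVH: for every dose level on a strictly increasing dose grid
#' starting at 0 Gy, the percentage of the structure volume receiving at
#' least that dose. The absolute structure volume (cm^3) is carried so that
#' percent and cm^3 dose-volume metrics interconvert.
#'
#' @slot structureName name of the structure the curve belongs to.
#' @slot doseGrid dose values in Gy, strictly increasing, first value 0.
#' @slot volume cumulative relative volume in percent, non-increasing,
#'   starting at 100.
#' @slot volumeCm3 absolute structure volume in cm^3.
#' @export
setClass("DVHCurve",
  representation(
    structureName = "character",
    doseGrid      = "numeric",
    volume        = "numeric",
    volumeCm3     = "numeric"
  )
)

setValidity("DVHCurve", function(object) {
  msg <- character()
  if (length(object@doseGrid) != length(object@volume))
    msg <- c(msg, "doseGrid and volume must have equal length")
  if (length(object@doseGrid) < 2L)
    msg <- c(msg, "curve needs at least two grid points")
  else {
    if (abs(object@doseGrid[1L]) > 1e-9)
      msg <- c(msg, "dose grid must start at 0 Gy")
    if (any(diff(object@doseGrid) <= 0))
      msg <- c(msg, "dose grid must be strictly increasing")
    if (any(object@volume < -.VOL_TOL) || any(object@volume > 100 + .VOL_TOL))
      msg <- c(msg, "volume values must lie in [0, 100]")
    if (any(diff(object@volume) > .VOL_TOL))
      msg <- c(msg, "cumulative volume must be non-increasing")
    if (object@volume[1L] < 100 - .VOL_TOL)
      msg <- c(msg, "volume at 0 Gy must be 100%")
  }
  if (length(object@volumeCm3) != 1L || !is.finite(object@volumeCm3) ||
      object@volumeCm3 <= 0)
    msg <- c(msg, "volumeCm3 must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Geometry-based expected dose curve
#'
#' A GED curve has the exact shape of a cumulative DVH but is computed from
#' anatomy and beam arrangement alone: each sub-volume of the structure is
#' assigned the dose the target is expected to contribute to it given its
#' distance to the target surface, and the cumulative histogram of those
#' doses is formed. It is the geometric feature from which achievable DVHs
#' are predicted.
#'
#' @export
setClass("GEDCurve", contains = "DVHCurve")

#' Principal-component basis of a curve population
#'
#' Mean curve plus ordered orthonormal component curves of a centred curve
#' population on a common grid, with the fraction of total variance each
#' component explains.
#'
#' @slot grid the common (relative-dose) grid the curves live on.
#' @slot meanCurve population mean curve.
#' @slot components matrix (grid points x components) of unit-norm,
#'   mutually orthogonal component curves, ordered by explained variance.
#' @slot explainedVariance fraction of total variance per retained
#'   component, non-increasing.
#' @slot totalVariance total variance of the centred population (sum of all
#'   eigenvalues, retained or not).
#' @slot nComponents number of retained components.
#' @export
setClass("PCABasis",
  representation(
    grid              = "numeric",
    meanCurve         = "numeric",
    components        = "matrix",
    explainedVariance = "numeric",
    totalVariance     = "numeric",
    nComponents       = "integer"
  )
)

setValidity("PCABasis", function(object) {
  msg <- character()
  k <- object@nComponents
  if (length(object@meanCurve) != length(object@grid))
    msg <- c(msg, "meanCurve must match grid length")
  if (ncol(object@components) != k)
    msg <- c(msg, "components must have nComponents columns")
  if (k > 0L && nrow(object@components) != length(object@grid))
    msg <- c(msg, "components must match grid length")
  if (length(object@explainedVariance) != k)
    msg <- c(msg, "explainedVariance must have one entry per component")
  if (k > 1L && any(diff(object@explainedVariance) > 1e-12))
    msg <- c(msg, "explainedVariance must be non-increasing")
  if (k > 0L) {
    g <- crossprod(object@components)
    if (max(abs(g - diag(k))) > 1e-6)
      msg <- c(msg, "components must be orthonormal")
  }
  if (length(msg)) msg else TRUE
})

#' Trained per-structure knowledge-based model
#'
#' The artifact trained for one structure: PCA bases for the DVH and GED
#' curve populations, ordinary-least-squares coefficients (with standard
#' errors) regressing each DVH component score on the GED component scores
#' and scalar geometric features, per-component residual standard errors,
#' and a pointwise mean/SD model for the low-dose (out-of-field) segment of
#' the curve.
#'
#' @slot structureName structure the model applies to.
#' @slot dvhBasis,gedBasis [PCABasis] objects for the DVH and GED curves.
#' @slot coefficients matrix (predictors x DVH components) of regression
#'   coefficients.
#' @slot coefficientSE matching matrix of coefficient standard errors.
#' @slot residualSE per-DVH-component residual standard error of the
#'   regression.
#' @slot outOfFieldMean,outOfFieldSd pointwise mean and SD (volume
#'   fraction) of the training DVHs over the full grid; used below the
#'   in-field/out-of-field partition.
#' @slot partitionIndex first grid index belonging to the in-field (high
#'   dose) segment.
#' @slot nTrainingCases number of training cases.
#' @slot predictorNames names of the regression predictors (incl. intercept).
#' @slot fits list of per-component \code{lm} fits (dropped when a model is
#'   read back from an archive).
#' @export
setClass("StructureModel",
  representation(
    structureName  = "character",
    dvhBasis       = "PCABasis",
    gedBasis       = "PCABasis",
    coefficients   = "matrix",
    coefficientSE  = "matrix",
    residualSE     = "numeric",
    outOfFieldMean = "numeric",
    outOfFieldSd   = "numeric",
    partitionIndex = "integer",
    nTrainingCases = "integer",
    predictorNames = "character",
    fits           = "list"
  )
)

setValidity("StructureModel", function(object) {
  msg <- character()
  k <- object@dvhBasis@nComponents
  if (ncol(object@coefficients) != k)
    msg <- c(msg, "coefficient matrix must have one column per DVH component")
  if (!all(dim(object@coefficientSE) == dim(object@coefficients)))
    msg <- c(msg, "coefficientSE must match coefficients in shape")
  if (length(object@residualSE) != k)
    msg <- c(msg, "residualSE must have one entry per DVH component")
  if (k > 0L && nrow(object@coefficients) != length(object@predictorNames))
    msg <- c(msg, "coefficient rows must match predictorNames")
  if (object@nTrainingCases < 2L)
    msg <- c(msg, "a structure model needs at least 2 training cases")
  if (length(msg)) msg else TRUE
})

#' Knowledge-based model over a set of structures
#'
#' Container holding one [StructureModel] per modelled structure together
#' with the training configuration, the training quality report and the
#' outlier candidate table.
#'
#' @slot structures named list of [StructureModel] objects.
#' @slot grid relative-dose modelling grid shared by all structures.
#' @slot config training configuration (see [kbConfig()]).
#' @slot report training quality report, one row per structure.
#' @slot outliers outlier candidate records.
#' @export
setClass("KBModel",
  representation(
    structures = "list",
    grid       = "numeric",
    config     = "list",
    report     = "data.frame",
    outliers   = "data.frame"
  )
)

#' Predicted DVH with uncertainty band
#'
#' Most-probable cumulative DVH for a new case together with pointwise
#' lower/upper band curves, all projected onto the non-increasing cone.
#'
#' @slot structureName structure the prediction applies to.
#' @slot doseGrid absolute dose grid in Gy.
#' @slot mostProbable,lower,upper volume-percent curves with
#'   \code{lower <= mostProbable <= upper} pointwise.
#' @export
setClass("PredictedDVH",
  representation(
    structureName = "character",
    doseGrid      = "numeric",
    mostProbable  = "numeric",
    lower         = "numeric",
    upper         = "numeric"
  )
)

setValidity("PredictedDVH", function(object) {
  msg <- character()
  n <- length(object@doseGrid)
  if (length(object@mostProbable) != n || length(object@lower) != n ||
      length(object@upper) != n)
    msg <- c(msg, "curves must match the dose grid in length")
  if (any(object@lower > object@mostProbable + 1e-9) ||
      any(object@mostProbable > object@upper + 1e-9))
    msg <- c(msg, "band ordering lower <= mostProbable <= upper violated")
  if (any(diff(object@mostProbable) > 1e-9) ||
      any(diff(object@lower) > 1e-9) || any(diff(object@upper) > 1e-9))
    msg <- c(msg, "band curves must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' Clinical endpoint pass/fail report
#'
#' Per patient-by-endpoint metric values with violation flags, plus the
#' cohort totals: number of violations, number of patients with at least
#' one violation, the maximum number of simultaneous violations in a single
#' patient, and the violation rate in percent of all evaluated dose-volume
#' points.
#'
#' @slot table data.frame with columns patient, endpoint, value, violated.
#' @slot endpoints the endpoint definitions the report was built against.
#' @slot nPatients number of patients evaluated.
#' @slot denominator number of dose-volume points the rate is computed
#'   over (defaults to patients x endpoints).
#' @slot totals list with violations, patientsWithViolations,
#'   maxSimultaneous, ratePct.
#' @export
setClass("PassFailReport",
  representation(
    table       = "data.frame",
    endpoints   = "data.frame",
    nPatients   = "integer",
    denominator = "numeric",
    totals      = "list"
  )
)
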