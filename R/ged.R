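#' @include dvh-metrics.R
NULL

#' Beam arrangement of a plan
#'
#' @param nArcs number of partial arcs (clinically 2-4).
#' @param coplanar logical; `FALSE` when at least one arc is non-coplanar.
#' @param prescription prescription dose in Gy.
#' @return a `FieldConfig` list.
#' @export
fieldConfig <- function(nArcs, coplanar, prescription) {
  if (nArcs < 1L) stop("at least one arc is required")
  if (prescription <= 0) stop("prescription must be positive")
  structure(list(nArcs = as.integer(nArcs), coplanar = isTRUE(coplanar),
                 prescription = as.numeric(prescription)),
            class = "FieldConfig")
}

#' Structure geometry summary
#'
#' Geometry as consumed by the expected-dose construction: a histogram of
#' signed distances from the structure's sub-volumes to the target surface
#' (negative = inside the target) and the fraction of the structure inside
#' the union of the beam apertures.
#'
#' @param name structure name.
#' @param volumeCm3 absolute structure volume in cm^3.
#' @param distanceMm representative signed distances (mm) of the histogram
#'   bins.
#' @param fraction volume fraction per bin; must sum to 1.
#' @param inFieldFraction fraction of the structure volume inside the beam
#'   aperture union, in [0, 1].
#' @return a `StructureGeometry` list.
#' @export
structureGeometry <- function(name, volumeCm3, distanceMm, fraction,
                              inFieldFraction) {
  if (volumeCm3 <= 0) stop("structure volume must be positive")
  if (length(distanceMm) != length(fraction))
    stop("distanceMm and fraction must have equal length")
  if (length(fraction) == 0L) stop("empty distance histogram")
  if (abs(sum(fraction) - 1) > 1e-9)
    stop("volume fractions must sum to 1")
  if (any(fraction < 0)) stop("volume fractions must be non-negative")
  if (inFieldFraction < 0 || inFieldFraction > 1)
    stop("inFieldFraction must lie in [0, 1]")
  structure(list(name = as.character(name), volumeCm3 = as.numeric(volumeCm3),
                 distanceMm = as.numeric(distanceMm),
                 fraction = as.numeric(fraction),
                 inFieldFraction = as.numeric(inFieldFraction)),
            class = "StructureGeometry")
}

#' Expected-dose kernel parameters
#'
#' Exponential fall-off kernels translating distance to the target surface
#' into the dose the target is expected to contribute. Sub-volumes inside
#' the target receive the prescription; in-field sub-volumes decay with
#' rate `kIn` per mm; out-of-field sub-volumes start from a scatter floor
#' `fOut` of the prescription and decay faster with rate `kOut`.
#'
#' @param kIn in-field decay rate per mm (default 0.05).
#' @param kOut out-of-field decay rate per mm (default 0.15).
#' @param fOut out-of-field scatter fraction of the prescription
#'   (default 0.3).
#' @return a `KernelParams` list.
#' @export
kernelParams <- function(kIn = 0.05, kOut = 0.15, fOut = 0.3) {
  if (kIn <= 0 || kOut <= 0) stop("kernel decay rates must be positive")
  if (fOut < 0 || fOut > 1) stop("fOut must lie in [0, 1]")
  structure(list(kIn = kIn, kOut = kOut, fOut = fOut),
            class = "KernelParams")
}

#' Expected dose of a sub-volume at a given distance from the target
#'
#' @param signedDistanceMm signed distance to the target surface in mm
#'   (negative = inside the target).
#' @param inField logical; whether the sub-volume lies inside the beam
#'   aperture union. Vectorized together with `signedDistanceMm`.
#' @param field a [fieldConfig()].
#' @param kernel a [kernelParams()].
#' @return expected dose in Gy, in `[0, prescription]`.
#' @export
gedVoxelDose <- function(signedDistanceMm, inField, field,
                         kernel = kernelParams()) {
  rx <- field$prescription
  d <- pmax(signedDistanceMm, 0)
  inField <- rep_len(inField, length(d))
  dose <- ifelse(inField,
                 rx * exp(-kernel$kIn * d),
                 rx * kernel$fOut * exp(-kernel$kOut * d))
  ifelse(signedDistanceMm <= 0, rx, dose)
}

#' Compute the geometry-based expected dose curve of a structure
#'
#' Each distance-histogram bin is split into an in-field part (weight
#' `inFieldFraction`) and an out-of-field part, each assigned its kernel
#' dose, and the cumulative histogram of the resulting dose distribution
#' is accumulated on the dose grid.
#'
#' @param geometry a [structureGeometry()].
#' @param field a [fieldConfig()].
#' @param kernel a [kernelParams()].
#' @param grid dose grid in Gy; defaults to 100 points spanning 0 to 110%
#'   of the prescription.
#' @return a [GEDCurve-class].
#' @export
computeGED <- function(geometry, field, kernel = kernelParams(),
                       grid = NULL) {
  if (is.null(grid)) grid <- relDoseGrid() * field$prescription
  dIn  <- gedVoxelDose(geometry$distanceMm, TRUE,  field, kernel)
  dOut <- gedVoxelDose(geometry$distanceMm, FALSE, field, kernel)
  fIn  <- geometry$inFieldFraction
  doses   <- c(dIn, dOut)
  weights <- c(geometry$fraction * fIn, geometry$fraction * (1 - fIn))
  vol <- vapply(grid, function(d) sum(weights[doses >= d - 1e-12]),
                numeric(1))
  methods::new("GEDCurve", structureName = geometry$name,
               doseGrid = as.numeric(grid), volume = 100 * vol,
               volumeCm3 = geometry$volumeCm3)
}

#' Partition a structure into in-field and out-of-field volume fractions
#'
#' The in-field fraction is the volume fraction whose expected dose
#' reaches at least `gedThreshold` times the prescription; the remainder is
#' out-of-field. The two fractions sum to 1.
#'
#' @param geometry a [structureGeometry()].
#' @param field a [fieldConfig()].
#' @param gedThreshold fraction of the prescription separating the
#'   regression-modelled high-dose region from the mean/SD low-dose region
#'   (default 0.2).
#' @param kernel a [kernelParams()].
#' @return named numeric vector `c(inField = ..., outField = ...)`.
#' @export
splitInOutField <- function(geometry, field, gedThreshold = 0.2,
                            kernel = kernelParams()) {
  if (gedThreshold <= 0 || gedThreshold >= 1)
    stop("gedThreshold must lie in (0, 1)")
  cut <- gedThreshold * field$prescription
  dIn  <- gedVoxelDose(geometry$distanceMm, TRUE,  field, kernel)
  dOut <- gedVoxelDose(geometry$distanceMm, FALSE, field, kernel)
  fIn  <- geometry$inFieldFraction
  inside <- sum(geometry$fraction * fIn * (dIn >= cut)) +
    sum(geometry$fraction * (1 - fIn) * (dOut >= cut))
  c(inField = inside, outField = 1 - inside)
}
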