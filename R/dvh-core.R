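#' @include AllGenerics.R
NULL

#' Construct a cumulative DVH curve
#'
#' @param structureName structure label.
#' @param doseGrid dose values in Gy, strictly increasing, starting at 0.
#' @param volume cumulative relative volume in percent aligned to
#'   `doseGrid`, non-increasing, starting at 100.
#' @param volumeCm3 absolute structure volume in cm^3.
#' @return a [DVHCurve-class] object.
#' @export
dvhCurve <- function(structureName, doseGrid, volume, volumeCm3) {
  methods::new("DVHCurve",
               structureName = as.character(structureName),
               doseGrid = as.numeric(doseGrid),
               volume = as.numeric(volume),
               volumeCm3 = as.numeric(volumeCm3))
}

#' Build a cumulative DVH from per-voxel dose samples
#'
#' Forms the empirical cumulative dose-volume histogram of a set of voxel
#' doses: at every grid dose d, the percentage of samples receiving at
#' least d. The absolute volume is the sample count times the voxel volume.
#'
#' @param doseSamples per-voxel doses in Gy (non-negative).
#' @param voxelVolume volume of one voxel in cm^3.
#' @param binWidth dose grid spacing in Gy (default 0.05).
#' @param maxDose upper end of the dose grid; defaults to 110% of the
#'   maximum sample so the curve always reaches zero.
#' @param structureName structure label.
#' @return a [DVHCurve-class].
#' @examples
#' dvh <- buildDVH(c(10, 20, 30, 40), voxelVolume = 0.1)
#' volumeAtDose(dvh, 25)  # 50
#' @export
buildDVH <- function(doseSamples, voxelVolume, binWidth = 0.05,
                     maxDose = NULL, structureName = "structure") {
  if (length(doseSamples) == 0L) stop("empty structure")
  if (binWidth <= 0) stop("binWidth must be positive")
  if (any(doseSamples < 0)) stop("dose samples must be non-negative")
  if (is.null(maxDose)) maxDose <- max(doseSamples) * .REL_SPAN
  maxDose <- max(maxDose, binWidth)
  grid <- seq(0, ceiling(maxDose / binWidth) * binWidth, by = binWidth)
  s <- sort(doseSamples)
  n <- length(s)
  # count of samples >= d for each grid dose
  atLeast <- n - findInterval(grid, s, left.open = TRUE)
  dvhCurve(structureName, grid, 100 * atLeast / n, n * voxelVolume)
}

#' Rescale all curves of a plan so the target mean dose equals the
#' prescription
#'
#' Plans are normalized to the mean target dose: every curve's dose axis is
#' scaled by `prescription / meanDose(target)` so that after rescaling the
#' target mean dose equals the prescription exactly.
#'
#' @param curves named list of [DVHCurve-class] objects (one plan).
#' @param targetName name of the target curve within `curves`.
#' @param prescription prescription dose in Gy.
#' @return the list of curves with rescaled dose grids.
#' @export
normalizeToTargetMean <- function(curves, targetName, prescription) {
  if (!targetName %in% names(curves))
    stop("target curve '", targetName, "' not present")
  m <- meanDose(curves[[targetName]])
  if (m <= 0) stop("target mean dose must be positive")
  f <- prescription / m
  lapply(curves, function(cv) {
    methods::initialize(cv, doseGrid = cv@doseGrid * f)
  })
}

#' Resample a DVH curve onto a new dose grid
#'
#' Linear interpolation of the cumulative volume onto `newGrid`; doses
#' beyond the stored grid carry the last volume value.
#'
#' @param curve a [DVHCurve-class].
#' @param newGrid new dose grid in Gy.
#' @return a [DVHCurve-class] on `newGrid`.
#' @export
resampleDVH <- function(curve, newGrid) {
  v <- linInterp(curve@doseGrid, curve@volume, newGrid)
  methods::initialize(curve, doseGrid = as.numeric(newGrid), volume = v)
}
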