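#' @include dvh-core.R
NULL

#' Dose-volume metrics
#'
#' Standard plan-quality metrics of a cumulative DVH:
#' \describe{
#'   \item{`doseAtVolume(curve, pct)`}{D_x%: smallest dose received by the
#'     hottest x% of the volume (linear interpolation; flat segments
#'     resolve to the lower dose).}
#'   \item{`doseAtVolumeCm3(curve, cm3)`}{D_x cm^3, converting the absolute
#'     volume to percent via the structure volume.}
#'   \item{`volumeAtDose(curve, doseGy)`}{V_x Gy: percent volume receiving
#'     at least x Gy.}
#'   \item{`meanDose(curve)`}{mean dose from the differential DVH
#'     (midpoint rule per bin).}
#'   \item{`homogeneityIndex(curve)`}{(D5 - D95) / mean dose; 0 for a
#'     perfectly uniform dose.}
#'   \item{`conformityIndex(curve, bodyV95Cm3)`}{ratio of the body volume
#'     receiving at least 95% of the prescription to the target volume.
#'     The body V95 volume is an explicit input because it is not
#'     computable from the target curve alone.}
#' }
#'
#' @param curve a [DVHCurve-class].
#' @param pct volume level in percent (0-100).
#' @param cm3 volume level in cm^3 (must not exceed the structure volume).
#' @param doseGy dose level in Gy.
#' @param bodyV95Cm3 absolute body volume (cm^3) receiving at least 95% of
#'   the prescription dose.
#' @return a single numeric metric value.
#' @name dvh-metrics
NULL

#' @rdname dvh-metrics
#' @export
doseAtVolume <- function(curve, pct) {
  if (pct < 0 || pct > 100) stop("volume percentage outside [0, 100]")
  curveDoseAtVolume(curve@doseGrid, curve@volume, pct)
}

#' @rdname dvh-metrics
#' @export
doseAtVolumeCm3 <- function(curve, cm3) {
  pct <- 100 * cm3 / curve@volumeCm3
  if (pct < 0 || pct > 100)
    stop("absolute volume outside the structure volume")
  doseAtVolume(curve, pct)
}

#' @rdname dvh-metrics
#' @export
volumeAtDose <- function(curve, doseGy) {
  if (doseGy < 0) stop("dose must be non-negative")
  if (doseGy > max(curve@doseGrid)) return(curve@volume[length(curve@volume)])
  linInterp(curve@doseGrid, curve@volume, doseGy)
}

#' @rdname dvh-metrics
#' @export
meanDose <- function(curve) {
  curveMeanDose(curve@doseGrid, curve@volume / 100)
}

#' @rdname dvh-metrics
#' @export
homogeneityIndex <- function(curve) {
  m <- meanDose(curve)
  if (m <= 0) stop("mean dose must be positive")
  (doseAtVolume(curve, 5) - doseAtVolume(curve, 95)) / m
}

#' @rdname dvh-metrics
#' @export
conformityIndex <- function(curve, bodyV95Cm3) {
  if (missing(bodyV95Cm3) || is.null(bodyV95Cm3))
    stop("conformity index requires the body V95 volume")
  bodyV95Cm3 / curve@volumeCm3
}

#' Evaluate a dose-volume metric specification
#'
#' Dispatches on a metric kind, covering the endpoint vocabulary used in
#' plan auditing. `threshold` is the metric argument (a volume level for
#' dose-at-volume metrics, a dose level for volume-at-dose metrics; unused
#' for mean dose and the indices).
#'
#' @param curve a [DVHCurve-class].
#' @param kind one of `"dose_at_volume_pct"`, `"dose_at_volume_cm3"`,
#'   `"volume_pct_at_dose"`, `"mean_dose"`, `"homogeneity_index"`,
#'   `"conformity_index"`.
#' @param threshold metric argument, units matching `kind`.
#' @param bodyV95Cm3 body V95 volume, required for the conformity index.
#' @return numeric metric value.
#' @export
dvhMetric <- function(curve, kind, threshold = NA_real_, bodyV95Cm3 = NULL) {
  switch(match.arg(kind, c("dose_at_volume_pct", "dose_at_volume_cm3",
                           "volume_pct_at_dose", "mean_dose",
                           "homogeneity_index", "conformity_index")),
    dose_at_volume_pct = doseAtVolume(curve, threshold),
    dose_at_volume_cm3 = doseAtVolumeCm3(curve, threshold),
    volume_pct_at_dose = volumeAtDose(curve, threshold),
    mean_dose          = meanDose(curve),
    homogeneity_index  = homogeneityIndex(curve),
    conformity_index   = conformityIndex(curve, bodyV95Cm3))
}
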