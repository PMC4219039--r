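#' @include structure-model.R
NULL

.BLEND_POINTS <- 5L  # linear cross-fade width at the in/out-of-field seam

# Blend the out-of-field mean/SD segment into the in-field regression
# segment at the partition index, then project every band curve onto the
# non-increasing cone and clamp to [0, 1]. Isotonic projection is order
# preserving, so the band ordering survives the projection.
.predictFraction <- function(model, gedCurve, features) {
  seg <- .predictSegments(model, gedCurve, features)
  g <- length(seg$mpIn)
  w <- rep(1, g)  # weight of the in-field segment
  part <- model@partitionIndex
  if (part > 1L) {
    lo <- max(1L, part - .BLEND_POINTS %/% 2L)
    hi <- min(g, lo + .BLEND_POINTS - 1L)
    w[seq_len(lo - 1L)] <- 0
    w[lo:hi] <- seq(0, 1, length.out = hi - lo + 1L)
  }
  mp   <- w * seg$mpIn + (1 - w) * seg$mpOut
  half <- w * seg$halfIn + (1 - w) * seg$halfOut
  list(mp = clampRange(monotoneNonIncreasing(mp), 0, 1),
       lower = clampRange(monotoneNonIncreasing(mp - half), 0, 1),
       upper = clampRange(monotoneNonIncreasing(mp + half), 0, 1))
}

#' Predict a DVH with uncertainty band for a new case
#'
#' The in-field curve segment is the basis mean plus the regression-
#' predicted component scores times the components; its band half-width
#' adds in quadrature the DVH principal components multiplied by the
#' per-component regression standard error. The out-of-field segment is
#' the stored training mean with a band of plus/minus one standard
#' deviation. The two segments are blended linearly across a few grid
#' points at the partition and all three curves are projected onto the
#' non-increasing cone.
#'
#' @param model a [StructureModel-class].
#' @param gedCurve the case's GED curve in volume-fraction units on the
#'   model grid (numeric vector), e.g. a resampled [computeGED()] result.
#' @param features one-row data.frame with `targetVolume`,
#'   `structureVolume`, `inFieldFraction`, `nArcs`.
#' @param prescription prescription dose in Gy, used to place the curves
#'   on an absolute dose grid.
#' @return a [PredictedDVH-class] (volume in percent).
#' @export
predictDVH <- function(model, gedCurve, features, prescription) {
  pr <- .predictFraction(model, gedCurve, features)
  methods::new("PredictedDVH",
               structureName = model@structureName,
               doseGrid = model@dvhBasis@grid * prescription,
               mostProbable = 100 * pr$mp,
               lower = 100 * pr$lower,
               upper = 100 * pr$upper)
}

#' Objective template rules
#'
#' Declarative rules from which dose-volume optimization objectives are
#' generated: one row per rule with the structure, the objective kind
#' (`upper_point`, `lower_point` or `line`), the volume level(s) to sample
#' and the optimizer priority. Priorities are data, not code; the default
#' template puts target coverage highest.
#'
#' @param structures OAR names to generate the default template for.
#' @param targetName name of the target structure (gets a coverage
#'   `lower_point` rule at 98% volume).
#' @return data.frame with columns structure, kind, volumePct, priority.
#' @export
defaultObjectiveRules <- function(structures, targetName = "ptv") {
  oar <- setdiff(structures, targetName)
  rules <- do.call(rbind, lapply(oar, function(s) {
    data.frame(structure = s, kind = "upper_point",
               volumePct = c(10, 50, 90), priority = 80,
               stringsAsFactors = FALSE)
  }))
  if (targetName %in% structures) {
    rules <- rbind(rules,
                   data.frame(structure = targetName, kind = "lower_point",
                              volumePct = 98, priority = 120,
                              stringsAsFactors = FALSE))
  }
  rules
}

#' Generate optimization objectives from a predicted DVH
#'
#' Point objectives for organs at risk are placed strictly below the lower
#' limit of the prediction band: at each rule volume level, the objective
#' dose is the lower-band dose at that level minus a margin (default 2%
#' of the prescription). Line objectives sample the lower band minus the
#' margin on a fixed volume grid. Target `lower_point` rules take the
#' lower-band dose at the rule level without the margin (the optimizer
#' should push the target dose up to it).
#'
#' @param pred a [PredictedDVH-class].
#' @param rules objective template rows for this structure (see
#'   [defaultObjectiveRules()]).
#' @param prescription prescription dose in Gy.
#' @param marginFraction margin below the lower band as a fraction of the
#'   prescription (default 0.02).
#' @param lineVolumes volume grid (percent) for line objectives.
#' @return data.frame with columns structure, kind, doseGy, volumePct,
#'   priority.
#' @export
generateObjectives <- function(pred, rules, prescription,
                               marginFraction = 0.02,
                               lineVolumes = seq(5, 95, by = 10)) {
  rules <- rules[rules$structure == pred@structureName, , drop = FALSE]
  margin <- marginFraction * prescription
  out <- list()
  for (i in seq_len(nrow(rules))) {
    kind <- rules$kind[i]
    vols <- if (kind == "line") lineVolumes else rules$volumePct[i]
    if (any(vols <= 0 | vols >= 100))
      stop("rule volume level outside (0, 100)")
    dose <- vapply(vols, function(v)
      curveDoseAtVolume(pred@doseGrid, pred@lower, v), numeric(1))
    if (kind != "lower_point") dose <- pmax(dose - margin, 0)
    out[[i]] <- data.frame(structure = pred@structureName, kind = kind,
                           doseGy = dose, volumePct = vols,
                           priority = rules$priority[i],
                           stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(structure = character(0), kind = character(0),
                      doseGy = numeric(0), volumePct = numeric(0),
                      priority = numeric(0)))
  }
  do.call(rbind, out)
}

.normalizeStructureName <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

#' Default structure-name synonym table
#'
#' Maps normalized clinical aliases to the model's structure ontology.
#'
#' @return named character vector (normalized alias -> model name).
#' @export
defaultSynonyms <- function() {
  c(liver_ptv = "normal_liver", healthy_liver = "normal_liver",
    liver = "normal_liver", cord = "spinal_cord", spine = "spinal_cord",
    kidney_l = "left_kidney", kidney_r = "right_kidney",
    oesophagus = "esophagus", target = "ptv", ptv_total = "ptv")
}

#' Match plan structure names to model structure names
#'
#' Case-insensitive normalized exact matches are taken first, then synonym
#' table lookups; names that resolve to no model structure are returned as
#' unmatched for user action. Two plan structures resolving to the same
#' model structure is an error.
#'
#' @param planStructures structure names present in the plan.
#' @param modelStructures structure names the model provides.
#' @param synonyms named character vector mapping normalized aliases to
#'   model names (default [defaultSynonyms()]).
#' @return list with `matched` (named character vector, plan name ->
#'   model name) and `unmatched` (character vector).
#' @export
mapOntology <- function(planStructures, modelStructures,
                        synonyms = defaultSynonyms()) {
  normModel <- .normalizeStructureName(modelStructures)
  matched <- character(0)
  unmatched <- character(0)
  for (s in planStructures) {
    ns <- .normalizeStructureName(s)
    hit <- modelStructures[normModel == ns]
    if (!length(hit) && ns %in% names(synonyms)) {
      cand <- synonyms[[ns]]
      hit <- modelStructures[normModel == .normalizeStructureName(cand)]
    }
    if (length(hit)) matched[s] <- hit[1L] else unmatched <- c(unmatched, s)
  }
  if (anyDuplicated(matched))
    stop("ambiguous mapping: plan structures ",
         paste(names(matched)[duplicated(matched) |
                                duplicated(matched, fromLast = TRUE)],
               collapse = ", "),
         " map to the same model structure")
  list(matched = matched, unmatched = unmatched)
}
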