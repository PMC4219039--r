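#' @include kb-model.R
NULL

#' Clinical dose-volume endpoint definitions
#'
#' A plan is audited against a set of clinical dose-volume objectives.
#' The `"protocol"` set is the acceptance protocol: D_1cm3 < 45 Gy to the
#' spinal cord, V_15Gy < 35% for each kidney, V_36Gy < 5% for the
#' stomach, D_1cm3 < 60 Gy and V_55Gy < 30% for the esophagus,
#' V_30Gy < 30% for the normal liver (liver minus target) and
#' D_98% > 90% of the prescription for the target. The `"tables"`
#' variant replaces the stomach and esophagus volume endpoints with
#' V_35Gy < 5% and V_30Gy < 30%, the set used in the summary tables;
#' neither set is silently preferred.
#'
#' @param set `"protocol"` or `"tables"`.
#' @return data.frame with columns id, structure, metricKind, metricArg,
#'   comparator, limit, unit.
#' @export
defaultEndpoints <- function(set = c("protocol", "tables")) {
  set <- match.arg(set)
  e <- function(id, structure, kind, arg, comparator, limit, unit) {
    data.frame(id = id, structure = structure, metricKind = kind,
               metricArg = arg, comparator = comparator, limit = limit,
               unit = unit, stringsAsFactors = FALSE)
  }
  base <- rbind(
    e("spine_d1cc", "spinal_cord", "dose_at_volume_cm3", 1, "<", 45, "gy"),
    e("left_kidney_v15", "left_kidney", "volume_pct_at_dose", 15, "<", 35,
      "pct"),
    e("right_kidney_v15", "right_kidney", "volume_pct_at_dose", 15, "<", 35,
      "pct"),
    e("esophagus_d1cc", "esophagus", "dose_at_volume_cm3", 1, "<", 60, "gy"),
    e("liver_v30", "normal_liver", "volume_pct_at_dose", 30, "<", 30, "pct"),
    e("ptv_d98", "ptv", "dose_at_volume_pct", 98, ">", 90, "pct_rx"))
  extra <- if (set == "protocol") rbind(
    e("stomach_v36", "stomach", "volume_pct_at_dose", 36, "<", 5, "pct"),
    e("esophagus_v55", "esophagus", "volume_pct_at_dose", 55, "<", 30, "pct"))
  else rbind(
    e("stomach_v35", "stomach", "volume_pct_at_dose", 35, "<", 5, "pct"),
    e("esophagus_v30", "esophagus", "volume_pct_at_dose", 30, "<", 30, "pct"))
  out <- rbind(base, extra)
  rownames(out) <- NULL
  out
}

#' Compute endpoint metric values for a set of plans
#'
#' Evaluates every endpoint metric on every patient's curves. Endpoints in
#' prescription-relative units (`pct_rx`) are converted using the
#' patient's prescription.
#'
#' @param cohort list of patient records with observed DVHs (see
#'   [fitKBModel()]).
#' @param endpoints endpoint table from [defaultEndpoints()].
#' @return data.frame with columns patient, endpoint, value (one row per
#'   available patient-endpoint pair).
#' @export
computeMetricTable <- function(cohort, endpoints) {
  rows <- list()
  for (p in cohort) {
    for (i in seq_len(nrow(endpoints))) {
      s <- endpoints$structure[i]
      if (!s %in% names(p$structures)) next
      curve <- p$structures[[s]]$dvh
      val <- dvhMetric(curve, endpoints$metricKind[i],
                       endpoints$metricArg[i])
      if (endpoints$unit[i] == "pct_rx")
        val <- 100 * val / p$field$prescription
      rows[[length(rows) + 1L]] <-
        data.frame(patient = p$id, endpoint = endpoints$id[i],
                   value = val, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Pass/fail audit of endpoint values
#'
#' Flags each (patient, endpoint) value against its clinical limit.
#' Comparators are strict in the passing direction: a value exactly at the
#' limit passes, so a `<` endpoint is violated only when the value exceeds
#' the limit and a `>` endpoint only when the value falls below it.
#' Cells absent from the value table count as passes (violations-only
#' tables list just the failing parameters).
#'
#' @param values data.frame with columns patient, endpoint, value
#'   (optionally unit, checked against the endpoint definition).
#' @param endpoints endpoint table from [defaultEndpoints()].
#' @param nPatients total number of patients audited (needed when
#'   `values` lists only violating patients).
#' @param denominator number of dose-volume points the violation rate is
#'   computed over; defaults to `nPatients * nrow(endpoints)`.
#' @return a [PassFailReport-class].
#' @export
evaluateEndpoints <- function(values, endpoints,
                              nPatients = length(unique(values$patient)),
                              denominator = NULL) {
  if (!all(values$endpoint %in% endpoints$id))
    stop("unknown endpoint id in value table: ",
         paste(setdiff(values$endpoint, endpoints$id), collapse = ", "))
  if ("unit" %in% names(values)) {
    eu <- endpoints$unit[match(values$endpoint, endpoints$id)]
    if (any(values$unit != eu))
      stop("unit mismatch between values and endpoint definitions")
  }
  idx <- match(values$endpoint, endpoints$id)
  cmp <- endpoints$comparator[idx]
  lim <- endpoints$limit[idx]
  violated <- ifelse(cmp == "<", values$value > lim, values$value < lim)
  tab <- data.frame(patient = values$patient, endpoint = values$endpoint,
                    value = values$value, violated = violated,
                    stringsAsFactors = FALSE)
  if (is.null(denominator)) denominator <- nPatients * nrow(endpoints)
  perPatient <- tapply(tab$violated, tab$patient, sum)
  totals <- list(
    violations = sum(tab$violated),
    patientsWithViolations = sum(perPatient > 0),
    maxSimultaneous = if (length(perPatient)) max(perPatient) else 0L,
    ratePct = 100 * sum(tab$violated) / denominator)
  methods::new("PassFailReport", table = tab, endpoints = endpoints,
               nPatients = as.integer(nPatients),
               denominator = as.numeric(denominator), totals = totals)
}

#' Compare the violations of two pass/fail reports
#'
#' Set algebra on the violated cells of a clinical report and a test
#' (model-based) report over the same patients and endpoints: violations
#' shared by both plans, new failures introduced by the test plans,
#' failures of the clinical plans resolved by the test plans, and the net
#' improvement in the pass-rate (clinical violation rate minus test
#' violation rate, each rounded to one decimal).
#'
#' @param clinical,test [PassFailReport-class] objects over the same
#'   cohort.
#' @return list with sharedFailures, newFailures, resolvedFailures,
#'   netImprovementPct.
#' @export
violationSummary <- function(clinical, test) {
  if (clinical@nPatients != test@nPatients ||
      !setequal(unique(clinical@table$patient), unique(test@table$patient)))
    stop("mismatched patient sets")
  key <- function(r) paste(r$patient, r$endpoint, sep = "\r")
  vC <- key(clinical@table[clinical@table$violated, ])
  vT <- key(test@table[test@table$violated, ])
  list(sharedFailures = length(intersect(vC, vT)),
       newFailures = length(setdiff(vT, vC)),
       resolvedFailures = length(setdiff(vC, vT)),
       netImprovementPct = round(clinical@totals$ratePct, 1) -
         round(test@totals$ratePct, 1))
}

#' Paired cohort comparison of a dosimetric metric
#'
#' Summary statistics in the reporting convention mean +/- SD [min-max]
#' plus a paired Wilcoxon signed-rank p-value. When all pairs are
#' identical the p-value is reported as 1 (no evidence of a difference).
#'
#' @param valuesA,valuesB paired per-patient metric values.
#' @return list with meanA, sdA, rangeA, meanB, sdB, rangeB,
#'   meanDifference, pValue.
#' @export
compareCohorts <- function(valuesA, valuesB) {
  if (length(valuesA) != length(valuesB))
    stop("paired samples must have equal length")
  if (length(valuesA) < 2L) stop("need at least 2 pairs")
  d <- valuesA - valuesB
  p <- if (all(d == 0)) 1 else
    suppressWarnings(stats::wilcox.test(valuesA, valuesB,
                                        paired = TRUE)$p.value)
  list(meanA = mean(valuesA), sdA = stats::sd(valuesA),
       rangeA = range(valuesA),
       meanB = mean(valuesB), sdB = stats::sd(valuesB),
       rangeB = range(valuesB),
       meanDifference = mean(d), pValue = p)
}

#' Packaged transcription of the published constraint-violation table
#'
#' The worked example ships as a plain-text fixture: the per-patient
#' dose-volume parameters that were violated in either the clinical or the
#' model-based plans, for the closed-loop validation (45 training
#' patients re-optimized) and the two open-loop validations (25 held-out
#' patients). Unlisted patient-endpoint cells passed in all plans.
#'
#' @param block `"closed_loop"` or `"open_loop"`.
#' @return data.frame of the fixture rows.
#' @export
table5Fixture <- function(block = c("closed_loop", "open_loop")) {
  block <- match.arg(block)
  path <- system.file("extdata", paste0("table5_", block, ".csv"),
                      package = "kbplan")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Audit one plan column of the violation-table fixture
#'
#' Builds the [PassFailReport-class] for one plan variant of the packaged
#' violation table. The closed-loop block audits 45 patients (360
#' dose-volume points); the open-loop block audits 25 patients, for which
#' the published denominator of 224 dose-volume points is used when
#' reproducing the printed rates even though 25 patients x 8 endpoints
#' gives 200 (a message flags the discrepancy).
#'
#' @param block `"closed_loop"` or `"open_loop"`.
#' @param plan which plan column to audit: `"clinical"`, `"closed_loop"`,
#'   `"open_loop_1"` or `"open_loop_2"`.
#' @param denominator override for the dose-volume point count.
#' @return a [PassFailReport-class].
#' @export
evaluateTable5 <- function(block = c("closed_loop", "open_loop"),
                           plan = "clinical", denominator = NULL) {
  block <- match.arg(block)
  fx <- table5Fixture(block)
  if (!plan %in% names(fx))
    stop("plan column '", plan, "' not in the ", block, " block")
  nPatients <- if (block == "closed_loop") 45L else 25L
  if (is.null(denominator)) {
    if (block == "closed_loop") {
      denominator <- nPatients * 8L
    } else {
      denominator <- 224
      message("using the published denominator of 224 dose-volume points; ",
              "25 patients x 8 endpoints would give 200")
    }
  }
  values <- data.frame(patient = fx$patient, endpoint = fx$endpoint,
                       value = fx[[plan]], stringsAsFactors = FALSE)
  evaluateEndpoints(values, defaultEndpoints("tables"),
                    nPatients = nPatients, denominator = denominator)
}
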