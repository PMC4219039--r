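#' @include synthetic.R
NULL

#' Write and read DVH tables
#'
#' Plain-text DVH exchange format: a CSV with columns
#' `structure,dose_gy,volume_pct`, one row per dose bin, preceded by one
#' comment line per structure `# volume_cm3 <structure>=<v>` carrying the
#' absolute volumes.
#'
#' @param curves named list of [DVHCurve-class] objects (one plan).
#' @param path file path.
#' @return `readDVHTable` returns a named list of [DVHCurve-class]
#'   objects; `writeDVHTable` returns the path invisibly.
#' @name dvh-io
NULL

#' @rdname dvh-io
#' @export
writeDVHTable <- function(curves, path) {
  header <- vapply(curves, function(cv)
    sprintf("# volume_cm3 %s=%.9g", cv@structureName, cv@volumeCm3),
    character(1))
  rows <- do.call(rbind, lapply(curves, function(cv)
    data.frame(structure = cv@structureName, dose_gy = cv@doseGrid,
               volume_pct = cv@volume, stringsAsFactors = FALSE)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname dvh-io
#' @export
readDVHTable <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# volume_cm3 ", lines, value = TRUE)
  vols <- numeric(0)
  for (h in hdr) {
    kv <- sub("^# volume_cm3 ", "", h)
    eq <- regexpr("=", kv, fixed = TRUE)
    vols[substr(kv, 1L, eq - 1L)] <-
      as.numeric(substr(kv, eq + 1L, nchar(kv)))
  }
  df <- utils::read.csv(textConnection(lines[!startsWith(lines, "#")]),
                        stringsAsFactors = FALSE)
  need <- c("structure", "dose_gy", "volume_pct")
  if (!all(need %in% names(df)))
    stop("malformed DVH CSV '", path, "': expected columns ",
         paste(need, collapse = ", "))
  bad <- which(df$volume_pct < -1e-9 | df$volume_pct > 100 + 1e-9)
  if (length(bad))
    stop("validation error in '", path, "', row ", bad[1L],
         ": volume_pct outside [0, 100]")
  out <- list()
  for (s in unique(df$structure)) {
    sub <- df[df$structure == s, ]
    if (any(diff(sub$volume_pct) > 1e-9))
      stop("validation error in '", path, "', structure '", s,
           "': cumulative volume must be non-increasing")
    if (!s %in% names(vols))
      stop("missing '# volume_cm3 ", s, "=' header in '", path, "'")
    out[[s]] <- dvhCurve(s, sub$dose_gy, sub$volume_pct, vols[[s]])
  }
  out
}

#' Write and read patient geometry
#'
#' Structured JSON per patient: field block (`n_arcs`, `coplanar`,
#' `prescription_gy`), the target volume, and per structure the absolute
#' volume, the signed distance histogram (mm and volume fractions) and
#' the in-field fraction.
#'
#' @param patient a patient record (see [fitKBModel()]).
#' @param path file path.
#' @return `readGeometry` returns a patient record without DVHs;
#'   `writeGeometry` returns the path invisibly.
#' @name geometry-io
NULL

#' @rdname geometry-io
#' @export
writeGeometry <- function(patient, path) {
  obj <- list(
    id = patient$id,
    fields = list(n_arcs = patient$field$nArcs,
                  coplanar = patient$field$coplanar,
                  prescription_gy = patient$field$prescription),
    target_volume_cm3 = patient$targetVolume,
    structures = lapply(patient$structures, function(rec) {
      g <- rec$geometry
      list(volume_cm3 = g$volumeCm3, distance_mm = g$distanceMm,
           fraction = g$fraction, in_field_fraction = g$inFieldFraction)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname geometry-io
#' @export
readGeometry <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structures <- lapply(names(obj$structures), function(s) {
    g <- obj$structures[[s]]
    list(geometry = structureGeometry(s, g$volume_cm3, g$distance_mm,
                                      g$fraction, g$in_field_fraction))
  })
  names(structures) <- names(obj$structures)
  list(id = obj$id,
       field = fieldConfig(obj$fields$n_arcs, obj$fields$coplanar,
                           obj$fields$prescription_gy),
       targetVolume = obj$target_volume_cm3,
       structures = structures)
}

#' Write and read a cohort directory
#'
#' One geometry JSON and one DVH CSV per patient plus an index file with
#' the producing configuration fingerprint. For synthetic cohorts the
#' generating truth is written to a segregated `truth/` subdirectory,
#' which `readCohort` never reads.
#'
#' @param cohort list of patient records.
#' @param dir directory path (created if missing).
#' @return `readCohort` returns the patient list; `writeCohort` the
#'   directory invisibly.
#' @name cohort-io
NULL

#' @rdname cohort-io
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(cohort, `[[`, character(1), "id")
  for (p in cohort) {
    writeGeometry(p, file.path(dir, paste0(p$id, "_geometry.json")))
    curves <- lapply(p$structures, `[[`, "dvh")
    writeDVHTable(curves, file.path(dir, paste0(p$id, "_dvh.csv")))
  }
  truth <- attr(cohort, "kbplanTruth")
  index <- list(patients = ids,
                config_hash = configHash(truth$config %||% list()),
                synthetic = !is.null(truth))
  jsonlite::write_json(index, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) {
    tdir <- file.path(dir, "truth")
    dir.create(tdir, showWarnings = FALSE)
    ser <- lapply(truth$structures, function(s)
      list(true_beta = s$trueBeta, scores = s$scores,
           dvh_mean = s$dvhMean, dvh_components = s$dvhComponents,
           ged_mean = s$gedBasis@meanCurve,
           ged_components = s$gedBasis@components,
           noise_sd = s$noiseSd))
    jsonlite::write_json(list(structures = ser),
                         file.path(tdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname cohort-io
#' @export
readCohort <- function(dir) {
  index <- jsonlite::fromJSON(file.path(dir, "cohort.json"))
  lapply(index$patients, function(id) {
    p <- readGeometry(file.path(dir, paste0(id, "_geometry.json")))
    curves <- readDVHTable(file.path(dir, paste0(id, "_dvh.csv")))
    for (s in names(p$structures)) {
      if (!s %in% names(curves))
        stop("patient ", id, ": structure '", s, "' has no DVH")
      p$structures[[s]]$dvh <- curves[[s]]
    }
    p
  })
}

#' Read one plan (geometry plus DVH table)
#'
#' @param geometryPath path to the patient geometry JSON.
#' @param dvhPath path to the plan's DVH CSV.
#' @return a patient record with geometry and DVH curves.
#' @export
readPlan <- function(geometryPath, dvhPath) {
  p <- readGeometry(geometryPath)
  curves <- readDVHTable(dvhPath)
  for (s in names(p$structures)) {
    if (s %in% names(curves)) p$structures[[s]]$dvh <- curves[[s]]
  }
  p
}

.basisToList <- function(b) {
  list(grid = b@grid, mean = b@meanCurve, components = b@components,
       explained_variance = b@explainedVariance,
       total_variance = b@totalVariance)
}

.basisFromList <- function(l) {
  k <- length(l$explained_variance)
  comps <- l$components
  if (k == 0L) {
    comps <- matrix(numeric(0), length(l$grid), 0L)
  } else if (is.null(dim(comps))) {
    comps <- matrix(unlist(comps), nrow = length(l$grid))
  }
  methods::new("PCABasis", grid = as.numeric(l$grid),
               meanCurve = as.numeric(l$mean), components = comps,
               explainedVariance = as.numeric(l$explained_variance),
               totalVariance = as.numeric(l$total_variance),
               nComponents = ncol(comps))
}

#' Write and read a model archive
#'
#' Versioned JSON archive of a trained [KBModel-class]: configuration,
#' grid, per-structure bases, coefficients with standard errors, the
#' out-of-field mean/SD model, and the training report and outlier
#' tables. Per-component regression fit objects are not archived, so
#' diagnostics that need them must be computed before archiving.
#'
#' @param kb a [KBModel-class].
#' @param path file path.
#' @return `readKBModel` returns the [KBModel-class]; `writeKBModel` the
#'   path invisibly.
#' @name model-io
NULL

#' @rdname model-io
#' @export
writeKBModel <- function(kb, path) {
  cfg <- kb@config
  cfg$kernel <- unclass(cfg$kernel)
  obj <- list(
    schema_version = 1L,
    config = cfg,
    config_hash = configHash(cfg),
    grid = kb@grid,
    structures = lapply(kb@structures, function(m) list(
      structure = m@structureName,
      dvh_basis = .basisToList(m@dvhBasis),
      ged_basis = .basisToList(m@gedBasis),
      coefficients = m@coefficients,
      coefficient_se = m@coefficientSE,
      residual_se = m@residualSE,
      out_of_field_mean = m@outOfFieldMean,
      out_of_field_sd = m@outOfFieldSd,
      partition_index = m@partitionIndex,
      n_cases = m@nTrainingCases,
      predictor_names = m@predictorNames)),
    report = kb@report,
    outliers = kb@outliers)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname model-io
#' @export
readKBModel <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- obj$config
  cfg$kernel <- do.call(kernelParams, cfg$kernel)
  structures <- lapply(obj$structures, function(l) {
    pn <- as.character(l$predictor_names)
    k <- length(l$residual_se)
    asCoefMatrix <- function(x) {
      if (k == 0L) return(matrix(numeric(0), length(pn), 0L))
      matrix(unlist(x), nrow = length(pn))
    }
    co <- asCoefMatrix(l$coefficients)
    se <- asCoefMatrix(l$coefficient_se)
    rownames(co) <- rownames(se) <- pn
    methods::new("StructureModel",
                 structureName = l$structure,
                 dvhBasis = .basisFromList(l$dvh_basis),
                 gedBasis = .basisFromList(l$ged_basis),
                 coefficients = co, coefficientSE = se,
                 residualSE = as.numeric(l$residual_se),
                 outOfFieldMean = as.numeric(l$out_of_field_mean),
                 outOfFieldSd = as.numeric(l$out_of_field_sd),
                 partitionIndex = as.integer(l$partition_index),
                 nTrainingCases = as.integer(l$n_cases),
                 predictorNames = pn, fits = list())
  })
  report <- if (length(obj$report)) as.data.frame(obj$report) else
    data.frame()
  outliers <- if (length(obj$outliers)) as.data.frame(obj$outliers) else
    data.frame(patientId = character(0), structure = character(0),
               cooksDistance = numeric(0),
               studentizedResidual = numeric(0), reasons = character(0))
  methods::new("KBModel", structures = structures,
               grid = as.numeric(obj$grid), config = cfg,
               report = report, outliers = outliers)
}

#' Export a predicted DVH band as CSV
#'
#' @param pred a [PredictedDVH-class].
#' @param path file path.
#' @return the path, invisibly.
#' @export
writePrediction <- function(pred, path) {
  utils::write.csv(data.frame(structure = pred@structureName,
                              dose_gy = pred@doseGrid,
                              most_probable = pred@mostProbable,
                              lower = pred@lower, upper = pred@upper),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
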