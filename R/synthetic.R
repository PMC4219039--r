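#' @include evaluation.R
NULL

# Per-organ generating family. Falloff centre/width shape the population
# mean DVH on the relative-dose grid; distance-histogram parameters (mm)
# shape the geometry family; sdT1/sdT2 are calibration constants: the
# typical population SDs of the two leading GED component scores of the
# family, measured once on a large reference sample and frozen here so
# that the score amplitudes of the embedded linear structure are stable
# across cohorts.
.organTable <- function() {
  list(
    spinal_cord = list(c = 0.22, w = 0.10, volMedian = 45,  volSdLog = 0.25,
                       distShift = 8,  distShape = 3.0, distScale = 12,
                       inFieldMu = 0.40, sdT1 = 0.58, sdT2 = 0.14),
    left_kidney = list(c = 0.12, w = 0.08, volMedian = 160, volSdLog = 0.30,
                       distShift = 10, distShape = 2.5, distScale = 15,
                       inFieldMu = 0.30, sdT1 = 0.51, sdT2 = 0.12),
    right_kidney = list(c = 0.18, w = 0.10, volMedian = 160, volSdLog = 0.30,
                        distShift = 6,  distShape = 2.0, distScale = 14,
                        inFieldMu = 0.40, sdT1 = 0.65, sdT2 = 0.14),
    normal_liver = list(c = 0.35, w = 0.15, volMedian = 1100,
                        volSdLog = 0.35, distShift = 1, distShape = 1.5,
                        distScale = 10, inFieldMu = 0.70,
                        sdT1 = 0.92, sdT2 = 0.21),
    stomach = list(c = 0.15, w = 0.09, volMedian = 280, volSdLog = 0.30,
                   distShift = 8,  distShape = 2.0, distScale = 16,
                   inFieldMu = 0.30, sdT1 = 0.51, sdT2 = 0.11),
    esophagus = list(c = 0.16, w = 0.09, volMedian = 38,  volSdLog = 0.25,
                     distShift = 12, distShape = 3.0, distScale = 18,
                     inFieldMu = 0.25, sdT1 = 0.31, sdT2 = 0.07),
    ptv = list(c = 0.97, w = 0.015, volMedian = NA, volSdLog = NA,
               distShift = NA, distShape = NA, distScale = NA,
               inFieldMu = 1.0, sdT1 = 1, sdT2 = 1)
  )
}

#' Virtual-cohort configuration
#'
#' Population parameters of the synthetic virtual-patient generator. The
#' defaults emulate the training population: target volume 596 +/- 538
#' cm^3 (log-normal, truncated to 54-2188 cm^3), prescriptions at
#' representative levels 60 / 42 / 36 Gy mixed 55/40/5 (the printed
#' proportions sum to 110%; the default adopts the normalized 55/40/5
#' mix), 2-4 partial arcs, and a non-coplanar setting in 40 of 45 cases.
#' `scoreSd` sets the population SD of the embedded DVH component
#' score; `noiseSd` is the pointwise SD (volume-fraction units) of the
#' smooth curve-level noise, whose squared value is the irreducible
#' estimation floor of any DVH model on these cohorts.
#'
#' @param nPatients number of virtual patients.
#' @param seed generator seed; identical config + seed reproduce the
#'   cohort exactly.
#' @param targetVolumeMean,targetVolumeSd target-volume moments in cm^3.
#' @param volumeRange truncation range for the target volume in cm^3.
#' @param prescriptionMix proportions for the three prescription levels
#'   (normalized to sum to 1 with a message if needed).
#' @param prescriptionLevels representative prescription doses in Gy.
#' @param arcProbs probabilities of 2, 3 and 4 arcs.
#' @param noncoplanarFraction fraction of plans with a non-coplanar arc.
#' @param noiseSd curve-level noise SD in volume-fraction units.
#' @param scoreSd population SD of the embedded DVH component score.
#' @param structures organ subset to generate (default: all organs and
#'   the target).
#' @param kb the training configuration ([kbConfig()]) the cohort is
#'   meant to be modelled with; the generator uses its kernel, grid and
#'   PCA settings so the embedded structure is expressed in the
#'   coordinates the trainer will use.
#' @return a config list.
#' @export
cohortConfig <- function(nPatients = 45L, seed = 1L,
                         targetVolumeMean = 596, targetVolumeSd = 538,
                         volumeRange = c(54, 2188),
                         prescriptionMix = c(0.55, 0.40, 0.05),
                         prescriptionLevels = c(60, 42, 36),
                         arcProbs = c(0.3, 0.5, 0.2),
                         noncoplanarFraction = 40 / 45,
                         noiseSd = 0.02,
                         scoreSd = 0.30,
                         structures = names(.organTable()),
                         kb = kbConfig()) {
  if (nPatients < 0) stop("nPatients must be non-negative")
  if (any(prescriptionMix < 0) || sum(prescriptionMix) <= 0)
    stop("invalid prescription mix")
  if (abs(sum(prescriptionMix) - 1) > 1e-9) {
    message("prescription mix normalized from ",
            paste(round(100 * prescriptionMix), collapse = "/"),
            " to sum to 100%")
    prescriptionMix <- prescriptionMix / sum(prescriptionMix)
  }
  if (volumeRange[1] <= 0 || volumeRange[1] >= volumeRange[2])
    stop("invalid volume range")
  structures <- match.arg(structures, names(.organTable()),
                          several.ok = TRUE)
  list(nPatients = as.integer(nPatients), seed = as.integer(seed),
       targetVolumeMean = targetVolumeMean, targetVolumeSd = targetVolumeSd,
       volumeRange = volumeRange, prescriptionMix = prescriptionMix,
       prescriptionLevels = prescriptionLevels, arcProbs = arcProbs,
       noncoplanarFraction = noncoplanarFraction, noiseSd = noiseSd,
       scoreSd = scoreSd, structures = structures, kb = kb)
}

# Population mean DVH on the relative grid: logistic falloff pinned to 1
# at zero dose and 0 at the grid end.
.organMeanCurve <- function(x, c, w) {
  f <- stats::plogis(-(x - c) / w)
  (f - f[length(f)]) / (f[1L] - f[length(f)])
}

# Unit-norm component shape: a falloff-shift bump whose slope is
# dominated by the mean falloff slope (both are logistic-density shaped),
# so mean + score * component stays monotone for realistic score ranges.
# An exponential taper pins the shape to zero at both grid ends.
.organComponents <- function(x, c, w, taper = 0.12) {
  span <- x[length(x)]
  t <- (1 - exp(-x / taper)) * (1 - exp(-(span - x) / taper))
  raw <- stats::dlogis((x - c) / w) * t
  .signFlip(cbind(raw / sqrt(sum(raw^2))))
}

# Unit-pointwise-variance smooth noise field: rows of a Gaussian kernel
# matrix, row-normalized; correlation length in relative-dose units.
.noiseMixer <- function(x, corLength = 0.15) {
  s <- exp(-outer(x, x, "-")^2 / (2 * corLength^2))
  s / sqrt(rowSums(s^2))
}

# Noise amplitude envelope, normalized to unit mean square so that
# noiseSd^2 equals the grid-averaged injected noise variance.
.noiseEnvelope <- function(m) {
  e <- m * (1 - m)
  e / sqrt(mean(e^2))
}

.sampleTruncLognormal <- function(n, meanArith, sdArith, range) {
  cv <- sdArith / meanArith
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(meanArith) - sdlog^2 / 2
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rlnorm(length(need), meanlog, sdlog)
    ok <- draw >= range[1] & draw <= range[2]
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

.organGeometry <- function(organ, pars, volumeCm3, shiftMult, scaleMult,
                           inFieldFraction) {
  if (organ == "ptv") {
    return(structureGeometry("ptv", volumeCm3, distanceMm = -5,
                             fraction = 1, inFieldFraction = 1))
  }
  edges <- seq(0, 160, by = 2)
  shift <- pars$distShift * shiftMult
  scale <- pars$distScale * scaleMult
  p <- stats::pgamma(pmax(edges - shift, 0), shape = pars$distShape,
                     scale = scale)
  frac <- diff(p)
  frac[length(frac)] <- frac[length(frac)] + (1 - p[length(p)])
  mids <- edges[-1L] - 1
  keep <- frac > 0
  structureGeometry(organ, volumeCm3, mids[keep], frac[keep] / sum(frac),
                    inFieldFraction)
}

# Ground-truth regression coefficients in the trainer's predictor
# parameterization: the embedded DVH component score is a fixed linear
# function of the two leading GED scores and the scalar features. The
# intercept centres the score at the population feature means (frozen
# reference values) so generated curves scatter around the organ mean.
.trueBeta <- function(predictorNames, pars, scoreSd, isTarget = FALSE) {
  beta <- matrix(0, length(predictorNames), 1L,
                 dimnames = list(predictorNames, "comp1"))
  s <- scoreSd
  if ("gedScore1" %in% predictorNames)
    beta["gedScore1", 1L] <- 0.85 * s / pars$sdT1
  if ("gedScore2" %in% predictorNames)
    beta["gedScore2", 1L] <- 0.30 * s / pars$sdT2
  beta["logTargetVolume", 1L] <- 0.12 * s
  if (!isTarget) beta["logStructureVolume", 1L] <- -0.08 * s
  beta["inFieldFraction", 1L] <- 0.6 * s
  beta["nArcs", 1L] <- 0.05 * s
  refVs <- if (isTarget) 6.09 else log(pars$volMedian)
  beta["(Intercept)", 1L] <- -(beta["logTargetVolume", 1L] * 6.09 +
                                 beta["logStructureVolume", 1L] * refVs +
                                 beta["inFieldFraction", 1L] * pars$inFieldMu +
                                 beta["nArcs", 1L] * 2.9)
  beta
}

#' Generate a virtual-patient cohort
#'
#' Draws field configurations, target volumes and per-organ geometries
#' from the configured population, computes each structure's GED curve,
#' and builds the DVHs as the organ's population mean curve plus two
#' component curves weighted by scores that are an exact linear function
#' of the cohort's GED component scores and scalar features (the embedded
#' ground truth), plus smooth curve-level noise, projected onto the
#' non-increasing cone. The generating parameters and per-patient latent
#' scores are recorded and retrievable with [cohortTruth()]; training
#' code paths never see them.
#'
#' @param config a [cohortConfig()].
#' @return list of virtual patients (records as consumed by
#'   [fitKBModel()]), each additionally carrying `latentScores`; the
#'   ground truth is attached as an attribute.
#' @export
generateCohort <- function(config = cohortConfig()) {
  n <- config$nPatients
  organTab <- .organTable()[config$structures]
  grid <- relDoseGrid(config$kb$nGrid)
  if (n == 0L) {
    cohort <- list()
    attr(cohort, "kbplanTruth") <- list(config = config, structures = list())
    return(cohort)
  }
  withSeed(config$seed, {
    rxIdx <- sample.int(3L, n, replace = TRUE, prob = config$prescriptionMix)
    rx <- config$prescriptionLevels[rxIdx]
    nArcs <- sample(2:4, n, replace = TRUE, prob = config$arcProbs)
    coplanar <- stats::runif(n) > config$noncoplanarFraction
    targetVolume <- .sampleTruncLognormal(n, config$targetVolumeMean,
                                          config$targetVolumeSd,
                                          config$volumeRange)
    fields <- lapply(seq_len(n), function(i)
      fieldConfig(nArcs[i], coplanar[i], rx[i]))
    ids <- sprintf("vp%03d", seq_len(n))

    mixer <- .noiseMixer(grid)
    truth <- list(config = config, structures = list())
    perPatientStructures <- replicate(n, list(), simplify = FALSE)

    for (organ in names(organTab)) {
      pars <- organTab[[organ]]
      if (organ == "ptv") {
        structureVolume <- targetVolume
        shiftMult <- scaleMult <- rep(1, n)
        inField <- rep(1, n)
      } else {
        structureVolume <- stats::rlnorm(n, log(pars$volMedian),
                                         pars$volSdLog)
        shiftMult <- stats::rlnorm(n, 0, 0.45)
        scaleMult <- stats::rlnorm(n, 0, 0.35)
        inField <- stats::plogis(stats::qlogis(pars$inFieldMu) +
                                   stats::rnorm(n, 0, 0.6))
      }
      geoms <- lapply(seq_len(n), function(i)
        .organGeometry(organ, pars, structureVolume[i], shiftMult[i],
                       scaleMult[i], inField[i]))
      gedMat <- do.call(rbind, lapply(seq_len(n), function(i) {
        g <- computeGED(geoms[[i]], fields[[i]], config$kb$kernel,
                        grid = grid * rx[i])
        g@volume / 100
      }))
      rownames(gedMat) <- ids
      gedBasis <- if (n >= 2L) {
        fitPCA(gedMat, grid, config$kb$varianceTarget,
               config$kb$maxComponents)
      } else {
        # single-patient cohort: degenerate basis, feature-driven scores
        methods::new("PCABasis", grid = grid, meanCurve = gedMat[1L, ],
                     components = matrix(numeric(0), length(grid), 0L),
                     explainedVariance = numeric(0), totalVariance = 0,
                     nComponents = 0L)
      }
      tScores <- pcaScore(gedBasis, gedMat)

      features <- data.frame(targetVolume = targetVolume,
                             structureVolume = structureVolume,
                             inFieldFraction = inField, nArcs = nArcs)
      x <- buildPredictors(tScores, features)
      predictorNames <- c("(Intercept)", colnames(x))
      scoreSd <- if (organ == "ptv") config$scoreSd / 8 else config$scoreSd
      beta <- .trueBeta(predictorNames, pars, scoreSd,
                        isTarget = organ == "ptv")
      scores <- cbind(1, x) %*% beta

      m <- .organMeanCurve(grid, pars$c, pars$w)
      comps <- .organComponents(grid, pars$c, pars$w)
      env <- .noiseEnvelope(m)
      noise <- if (config$noiseSd > 0) {
        w <- matrix(stats::rnorm(n * length(grid)), n)
        config$noiseSd * (w %*% t(mixer)) *
          matrix(env, n, length(grid), byrow = TRUE)
      } else {
        matrix(0, n, length(grid))
      }
      curves <- matrix(m, n, length(grid), byrow = TRUE) +
        scores %*% t(comps) + noise
      curves <- t(apply(curves, 1L, function(v)
        clampRange(monotoneNonIncreasing(v), 0, 1)))

      for (i in seq_len(n)) {
        dvh <- dvhCurve(organ, grid * rx[i], 100 * curves[i, ],
                        structureVolume[i])
        perPatientStructures[[i]][[organ]] <-
          list(geometry = geoms[[i]], dvh = dvh)
      }
      truth$structures[[organ]] <- list(
        gedBasis = gedBasis, trueBeta = beta, scores = scores,
        dvhMean = m, dvhComponents = comps,
        noiseSd = config$noiseSd, noiseEnvelope = env)
    }

    cohort <- lapply(seq_len(n), function(i) {
      sc <- lapply(names(perPatientStructures[[i]]), function(s)
        truth$structures[[s]]$scores[i, ])
      names(sc) <- names(perPatientStructures[[i]])
      list(id = ids[i], field = fields[[i]],
           targetVolume = targetVolume[i],
           structures = perPatientStructures[[i]],
           latentScores = sc)
    })
    attr(cohort, "kbplanTruth") <- truth
    cohort
  })
}

#' Retrieve the generating ground truth of a synthetic cohort
#'
#' Returns the exact generating parameters of a cohort produced by
#' [generateCohort()]: per structure, the GED basis the scores are
#' expressed in, the true regression coefficients, the per-patient latent
#' scores, and the mean/component curves and noise model. Intended for
#' recovery testing only; the training functions never read it.
#'
#' @param cohort a cohort from [generateCohort()].
#' @return the truth list (`config` plus per-structure entries).
#' @export
cohortTruth <- function(cohort) {
  tr <- attr(cohort, "kbplanTruth")
  if (is.null(tr)) stop("cohort is not synthetic: no ground truth attached")
  tr
}
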