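#' @include pca.R
NULL

#' Training configuration
#'
#' Collects the tunable training parameters with their defaults: the PCA
#' variance target and component cap, the minimum number of cases per
#' structure, the relative-dose partition between the regression-modelled
#' in-field curve segment and the mean/SD out-of-field segment, the
#' outlier reporting thresholds, and the expected-dose kernel.
#'
#' @param varianceTarget fraction of curve variance the retained principal
#'   components must explain (default 0.95).
#' @param maxComponents cap on retained components per basis (default 5).
#' @param minCases minimum number of training cases per structure
#'   (default 20); structures with fewer cases are excluded from modelling.
#' @param partitionRelDose relative dose (fraction of prescription)
#'   separating the out-of-field from the in-field curve segment
#'   (default 0.2).
#' @param cooksThreshold Cook's distance reporting threshold (default 4).
#' @param studentizedThreshold absolute externally studentized residual
#'   reporting threshold (default 3).
#' @param cvFolds number of cross-validation folds (default 10).
#' @param cvSeed seed for the deterministic fold assignment (default 1).
#' @param kernel expected-dose kernel, a [kernelParams()].
#' @param nGrid number of points of the relative-dose modelling grid.
#' @return a config list.
#' @export
kbConfig <- function(varianceTarget = 0.95, maxComponents = 5L,
                     minCases = 20L, partitionRelDose = 0.2,
                     cooksThreshold = 4, studentizedThreshold = 3,
                     cvFolds = 10L, cvSeed = 1L,
                     kernel = kernelParams(), nGrid = .N_GRID) {
  stopifnot(varianceTarget > 0, varianceTarget <= 1, maxComponents >= 1,
            minCases >= 2, partitionRelDose > 0, partitionRelDose < 1,
            cooksThreshold > 0, studentizedThreshold > 0, cvFolds >= 2)
  list(varianceTarget = varianceTarget,
       maxComponents = as.integer(maxComponents),
       minCases = as.integer(minCases),
       partitionRelDose = partitionRelDose,
       cooksThreshold = cooksThreshold,
       studentizedThreshold = studentizedThreshold,
       cvFolds = as.integer(cvFolds), cvSeed = as.integer(cvSeed),
       kernel = kernel, nGrid = as.integer(nGrid))
}

# Regression design: GED component scores followed by the scalar geometric
# features. Volumes enter on the log scale (they span two orders of
# magnitude in the population).
buildPredictors <- function(gedScores, features) {
  gedScores <- as.matrix(gedScores)
  x <- cbind(gedScores,
             logTargetVolume = log(features$targetVolume),
             logStructureVolume = log(features$structureVolume),
             inFieldFraction = features$inFieldFraction,
             nArcs = as.numeric(features$nArcs))
  if (ncol(gedScores) > 0L)
    colnames(x)[seq_len(ncol(gedScores))] <-
      paste0("gedScore", seq_len(ncol(gedScores)))
  x
}

.checkFullRank <- function(x, dropRedundant = FALSE) {
  xi <- cbind(`(Intercept)` = 1, x)
  q <- qr(xi)
  if (q$rank < ncol(xi)) {
    bad <- colnames(xi)[q$pivot[(q$rank + 1L):ncol(xi)]]
    if (!dropRedundant)
      stop("rank-deficient predictor matrix; collinear predictors: ",
           paste(bad, collapse = ", "))
    message("dropping redundant predictors: ", paste(bad, collapse = ", "))
    return(x[, setdiff(colnames(x), bad), drop = FALSE])
  }
  x
}

#' Train the knowledge-based model for one structure
#'
#' Fits principal-component bases to the DVH and GED curve populations,
#' then regresses each DVH component score by ordinary least squares on
#' the GED component scores and the scalar geometric features (log target
#' volume, log structure volume, in-field fraction, number of arcs),
#' storing coefficients, their standard errors and the per-component
#' residual standard error. The low-dose (out-of-field) curve segment is
#' modelled by the pointwise mean and standard deviation of the training
#' curves.
#'
#' @param gedCurves matrix (cases x grid) of GED curves in volume-fraction
#'   units on the relative-dose grid.
#' @param dvhCurves matrix (cases x grid) of DVH curves, same convention.
#' @param features data.frame with columns `targetVolume`,
#'   `structureVolume`, `inFieldFraction`, `nArcs` (one row per case).
#' @param config a [kbConfig()].
#' @param structureName structure label.
#' @param grid relative-dose grid (defaults to [relDoseGrid()]).
#' @param dropRedundant drop collinear predictor columns (with a message)
#'   instead of raising an error; used by the cohort-level trainer for
#'   structures with degenerate features.
#' @return a [StructureModel-class].
#' @export
fitStructureModel <- function(gedCurves, dvhCurves, features,
                              config = kbConfig(),
                              structureName = "structure", grid = NULL,
                              dropRedundant = FALSE) {
  gedCurves <- as.matrix(gedCurves)
  dvhCurves <- as.matrix(dvhCurves)
  n <- nrow(dvhCurves)
  if (n < config$minCases)
    stop("insufficient cases: ", n, " < ", config$minCases)
  if (nrow(gedCurves) != n || nrow(features) != n)
    stop("case counts of curves and features disagree")
  if (is.null(grid)) grid <- relDoseGrid(config$nGrid)

  dvhBasis <- fitPCA(dvhCurves, grid, config$varianceTarget,
                     config$maxComponents)
  gedBasis <- fitPCA(gedCurves, grid, config$varianceTarget,
                     config$maxComponents)
  sDvh <- pcaScore(dvhBasis, dvhCurves)
  sGed <- pcaScore(gedBasis, gedCurves)

  x <- buildPredictors(sGed, features)
  x <- .checkFullRank(x, dropRedundant)
  k <- dvhBasis@nComponents
  p <- ncol(x) + 1L
  coefs <- matrix(NA_real_, p, k)
  ses <- matrix(NA_real_, p, k)
  rse <- numeric(k)
  fits <- vector("list", k)
  predictorNames <- c("(Intercept)", colnames(x))
  for (j in seq_len(k)) {
    df <- data.frame(.y = sDvh[, j], x, check.names = FALSE)
    fit <- stats::lm(.y ~ ., data = df)
    # summary.lm warns on zero-residual fits; those are legitimate here
    # (noise-free cohorts) and the coefficient table is still exact
    sm <- suppressWarnings(summary(fit))
    coefs[, j] <- stats::coef(fit)
    ses[, j] <- sm$coefficients[, "Std. Error"]
    rse[j] <- sm$sigma
    fits[[j]] <- fit
  }
  rownames(coefs) <- rownames(ses) <- predictorNames

  part <- which(grid >= config$partitionRelDose)[1L]
  methods::new("StructureModel",
               structureName = structureName,
               dvhBasis = dvhBasis, gedBasis = gedBasis,
               coefficients = coefs, coefficientSE = ses, residualSE = rse,
               outOfFieldMean = colMeans(dvhCurves),
               outOfFieldSd = apply(dvhCurves, 2L, stats::sd),
               partitionIndex = as.integer(part),
               nTrainingCases = as.integer(n),
               predictorNames = predictorNames,
               fits = fits)
}

# Estimation-model curve (pure PC + regression reconstruction over the
# whole grid, monotone-projected) in fraction units; used by the
# cross-validated goodness of estimation. The clinical prediction band
# additionally blends in the out-of-field mean/SD segment.
.estimateFraction <- function(model, gedCurve, features) {
  seg <- .predictSegments(model, gedCurve, features)
  clampRange(monotoneNonIncreasing(seg$mpIn), 0, 1)
}

# Most-probable curve and band half-width in fraction units on the model
# grid, before blending/projection.
.predictSegments <- function(model, gedCurve, features) {
  sGed <- pcaScore(model@gedBasis, gedCurve)
  x <- buildPredictors(sGed, features)
  xi <- c(1, as.numeric(x[1L, model@predictorNames[-1L]]))
  k <- model@dvhBasis@nComponents
  comps <- model@dvhBasis@components
  if (k > 0L) {
    sHat <- as.numeric(xi %*% model@coefficients)
    mpIn <- as.numeric(pcaReconstruct(model@dvhBasis, sHat))
    halfIn <- sqrt(rowSums((comps * rep(model@residualSE,
                                        each = nrow(comps)))^2))
  } else {
    mpIn <- model@dvhBasis@meanCurve
    halfIn <- rep(0, length(mpIn))
  }
  list(mpIn = mpIn, halfIn = halfIn,
       mpOut = model@outOfFieldMean, halfOut = model@outOfFieldSd)
}

#' Cross-validated goodness of estimation
#'
#' The training set is divided into `folds` parts; `folds` models are
#' trained, each tested against the held-out part, and the mean squared
#' error between the held-out DVH curves (volume-fraction units) and their
#' model estimates is averaged over all held-out cases. Fold assignment is
#' deterministic from `seed`.
#'
#' @inheritParams fitStructureModel
#' @param folds number of folds (default 10); `folds = n` gives
#'   leave-one-out.
#' @param seed fold-assignment seed.
#' @return mean squared estimation error (volume-fraction units squared).
#' @export
crossValidate <- function(gedCurves, dvhCurves, features,
                          config = kbConfig(), folds = 10L, seed = 1L,
                          grid = NULL, dropRedundant = FALSE) {
  gedCurves <- as.matrix(gedCurves)
  dvhCurves <- as.matrix(dvhCurves)
  n <- nrow(dvhCurves)
  if (n < folds) stop("fewer cases than folds")
  if (is.null(grid)) grid <- relDoseGrid(config$nGrid)
  # Fold membership is keyed to case labels (when present) so that the
  # goodness of estimation does not depend on the storage order of the
  # training set.
  ids <- rownames(dvhCurves) %||% as.character(seq_len(n))
  assign <- integer(n)
  assign[order(ids)] <- withSeed(seed, sample(rep(seq_len(folds),
                                                  length.out = n)))
  cvConfig <- config
  cvConfig$minCases <- 2L
  err <- numeric(0)
  for (f in seq_len(folds)) {
    test <- which(assign == f)
    train <- which(assign != f)
    m <- fitStructureModel(gedCurves[train, , drop = FALSE],
                           dvhCurves[train, , drop = FALSE],
                           features[train, , drop = FALSE],
                           cvConfig, grid = grid,
                           dropRedundant = dropRedundant)
    for (i in test) {
      est <- .estimateFraction(m, gedCurves[i, ], features[i, , drop = FALSE])
      err <- c(err, mean((est - dvhCurves[i, ])^2))
    }
  }
  mean(err)
}

#' Regression quality diagnostics
#'
#' Two summary numbers of a trained structure model, both best when close
#' to 1:
#' \describe{
#'   \item{averageChiSquare}{mean over DVH components of the reduced
#'     chi-square of the score regression: the classical residual variance
#'     estimate (RSS over residual degrees of freedom) divided by a robust
#'     (median-absolute-deviation based) estimate of the residual variance.
#'     Near 1 for a well-specified model with clean residuals; inflated by
#'     heavy-tailed residuals or gross outliers.}
#'   \item{modelFit}{coefficient of determination of the pooled score
#'     regressions (1 minus pooled residual sum of squares over pooled
#'     total sum of squares), at most 1.}
#' }
#'
#' @param model a fitted [StructureModel-class] (with regression fits).
#' @return list with `averageChiSquare` and `modelFit`.
#' @export
regressionDiagnostics <- function(model) {
  fits <- model@fits
  if (!length(fits)) stop("model carries no regression fits")
  chi <- numeric(0)
  rss <- tss <- 0
  for (fit in fits) {
    r <- stats::residuals(fit)
    df <- stats::df.residual(fit)
    if (df <= 0) stop("zero residual degrees of freedom")
    s2 <- sum(r^2) / df
    robust <- stats::mad(r)^2
    chi <- c(chi, if (robust > 0) s2 / robust else 1)
    rss <- rss + sum(r^2)
    y <- r + stats::fitted(fit)
    tss <- tss + sum((y - mean(y))^2)
  }
  list(averageChiSquare = mean(chi),
       modelFit = if (tss > 0) 1 - rss / tss else 1)
}

#' Detect outlier candidates in the score regressions
#'
#' Flags training cases whose Cook's distance reaches `cooksThreshold` or
#' whose externally studentized residual reaches `studentizedThreshold` in
#' absolute value, in any DVH component regression. Cook's distance
#' combines residual size and leverage,
#' `D_i = r_i^2 / (p s^2) * h_ii / (1 - h_ii)^2`; the studentized residual
#' scales each residual by its leave-one-out standard deviation so that
#' small residuals at influential points are still detected. Exact
#' leverage points (`h_ii = 1`) are reported with infinite influence.
#' Candidates are reported, never removed.
#'
#' @param model a fitted [StructureModel-class].
#' @param cooksThreshold Cook's distance threshold (default 4).
#' @param studentizedThreshold absolute studentized residual threshold
#'   (default 3).
#' @param patientIds optional case labels (default case indices).
#' @return data.frame with columns patientId, structure, cooksDistance,
#'   studentizedResidual, reasons (only flagged cases; zero rows when
#'   nothing is flagged).
#' @export
detectOutliers <- function(model, cooksThreshold = 4,
                           studentizedThreshold = 3, patientIds = NULL) {
  fits <- model@fits
  if (!length(fits)) {
    return(data.frame(patientId = character(0), structure = character(0),
                      cooksDistance = numeric(0),
                      studentizedResidual = numeric(0),
                      reasons = character(0)))
  }
  n <- model@nTrainingCases
  if (is.null(patientIds)) patientIds <- as.character(seq_len(n))
  dmax <- rep(0, n)
  tmax <- rep(0, n)
  for (fit in fits) {
    h <- stats::hatvalues(fit)
    d <- stats::cooks.distance(fit)
    t <- stats::rstudent(fit)
    d[h >= 1 - 1e-12] <- Inf
    t[!is.finite(t)] <- Inf
    dmax <- pmax(dmax, d)
    tmax <- ifelse(abs(t) > abs(tmax), t, tmax)
  }
  flagC <- dmax >= cooksThreshold
  flagS <- abs(tmax) >= studentizedThreshold
  keep <- which(flagC | flagS)
  data.frame(
    patientId = patientIds[keep],
    structure = rep(model@structureName, length(keep)),
    cooksDistance = dmax[keep],
    studentizedResidual = tmax[keep],
    reasons = vapply(keep, function(i) {
      paste(c(if (flagC[i]) "cooks", if (flagS[i]) "studentized"),
            collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE)
}
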