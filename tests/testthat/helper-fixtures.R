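# Shared in-code fixtures for the test suite.

# A strictly decreasing random DVH-like curve on a uniform grid.
randomMonotoneCurve <- function(nGrid = 80, maxDose = 70) {
  grid <- seq(0, maxDose, length.out = nGrid)
  drops <- stats::runif(nGrid - 1)
  v <- 100 * c(1, 1 - cumsum(drops) / sum(drops))[seq_len(nGrid)]
  v[1] <- 100
  dvhCurve("random", grid, pmax(v, 0), volumeCm3 = 120)
}

# Curve population: mean shape plus rank-`k` structure plus optional noise,
# rows = curves.
curvePopulation <- function(n, nGrid = 60, k = 2, noise = 0) {
  x <- seq(0, 1, length.out = nGrid)
  mean <- exp(-3 * x)
  shapes <- sapply(seq_len(k), function(j) {
    s <- sin(pi * j * x) * x * (1 - x)
    s / sqrt(sum(s^2))
  })
  scores <- matrix(stats::rnorm(n * k, sd = 0.3 / seq_len(k)), n,
                   byrow = TRUE)
  curves <- matrix(mean, n, nGrid, byrow = TRUE) +
    scores %*% t(shapes) +
    matrix(stats::rnorm(n * nGrid, sd = noise), n)
  list(curves = curves, grid = x, mean = mean, shapes = shapes,
       scores = scores)
}

# Small regression cohort on the model grid with an exact (optionally
# noisy) linear DVH-score/GED-score relation; features are drawn but have
# no effect unless betaFeatures is set.
linearScoreCohort <- function(n, slope = 2, noise = 0, seed = 42) {
  set.seed(seed)
  grid <- relDoseGrid()
  gMean <- exp(-2 * grid)
  dMean <- stats::plogis(-(grid - 0.4) / 0.12)
  gShape <- {
    s <- stats::dlogis((grid - 0.3) / 0.1)
    s / sqrt(sum(s^2))
  }
  dShape <- {
    s <- stats::dlogis((grid - 0.4) / 0.12)
    s / sqrt(sum(s^2))
  }
  u <- stats::runif(n, -0.5, 0.5)
  ged <- matrix(gMean, n, length(grid), byrow = TRUE) + outer(u, gShape)
  dvhScores <- slope * u + stats::rnorm(n, sd = noise)
  dvh <- matrix(dMean, n, length(grid), byrow = TRUE) +
    outer(dvhScores, dShape)
  features <- data.frame(
    targetVolume = stats::rlnorm(n, log(500), 0.4),
    structureVolume = stats::rlnorm(n, log(150), 0.3),
    inFieldFraction = stats::runif(n, 0.2, 0.8),
    nArcs = sample(2:4, n, replace = TRUE))
  rownames(ged) <- rownames(dvh) <- rownames(features) <-
    sprintf("case%03d", seq_len(n))
  list(ged = ged, dvh = dvh, features = features, grid = grid, u = u,
       dvhScores = dvhScores, gShape = gShape, dShape = dShape)
}

# Hand-built one- or two-component structure model with no out-of-field
# segment (partition at the first grid point disables blending).
handModel <- function(residualSE, coefGed1 = 1, nComp = length(residualSE)) {
  grid <- relDoseGrid()
  m <- stats::plogis(-(grid - 0.5) / 0.15)
  m <- (m - m[length(m)]) / (m[1] - m[length(m)])
  comps <- sapply(seq_len(nComp), function(j) {
    s <- stats::dlogis((grid - 0.3 - 0.15 * j) / 0.1)
    s / sqrt(sum(s^2))
  })
  comps <- qr.Q(qr(cbind(comps)))
  gMean <- exp(-2 * grid)
  gShape <- stats::dlogis((grid - 0.3) / 0.1)
  gShape <- gShape / sqrt(sum(gShape^2))
  dvhBasis <- methods::new("PCABasis", grid = grid, meanCurve = m,
                           components = comps,
                           explainedVariance = rep(1 / nComp, nComp),
                           totalVariance = 1, nComponents = as.integer(nComp))
  gedBasis <- methods::new("PCABasis", grid = grid, meanCurve = gMean,
                           components = cbind(gShape),
                           explainedVariance = 1, totalVariance = 1,
                           nComponents = 1L)
  predictorNames <- c("(Intercept)", "gedScore1", "logTargetVolume",
                      "logStructureVolume", "inFieldFraction", "nArcs")
  coefs <- matrix(0, length(predictorNames), nComp,
                  dimnames = list(predictorNames, NULL))
  coefs["gedScore1", 1] <- coefGed1
  methods::new("StructureModel", structureName = "hand",
               dvhBasis = dvhBasis, gedBasis = gedBasis,
               coefficients = coefs, coefficientSE = coefs * 0,
               residualSE = residualSE,
               outOfFieldMean = m, outOfFieldSd = rep(0, length(grid)),
               partitionIndex = 1L, nTrainingCases = 25L,
               predictorNames = predictorNames, fits = list())
}

handFeatures <- function() {
  data.frame(targetVolume = 500, structureVolume = 150,
             inFieldFraction = 0.5, nArcs = 3)
}
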