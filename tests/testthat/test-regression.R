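test_that("a noise-free linear cohort is recovered exactly", {
  lc <- linearScoreCohort(30, slope = 2, noise = 0)
  cfg <- kbConfig(minCases = 20)
  m <- fitStructureModel(lc$ged, lc$dvh, lc$features, cfg, grid = lc$grid)
  expect_equal(unname(coef(m)["gedScore1", 1]), 2, tolerance = 1e-6)
  expect_lt(m@residualSE[1], 1e-8)
  feats <- names(coef(m)[, 1])
  other <- setdiff(feats, c("(Intercept)", "gedScore1"))
  expect_true(all(abs(coef(m)[other, 1]) < 1e-6))
})

test_that("known coefficients are recovered within 3 standard errors", {
  cfg <- cohortConfig(nPatients = 200, seed = 31,
                      structures = "right_kidney")
  co <- suppressMessages(generateCohort(cfg))
  truth <- cohortTruth(co)$structures$right_kidney
  kb <- suppressMessages(fitKBModel(co, kbConfig()))
  m <- kb@structures$right_kidney
  # orientation of the fitted leading component vs. the generating shape
  sgn <- sign(sum(m@dvhBasis@components[, 1] *
                    truth$dvhComponents[, 1]))
  shared <- intersect(rownames(coef(m)), rownames(truth$trueBeta))
  for (p in setdiff(shared, "(Intercept)")) {
    est <- sgn * coef(m)[p, 1]
    se <- m@coefficientSE[p, 1]
    expect_lt(abs(est - truth$trueBeta[p, 1]), 3 * se)
  }
})

test_that("collinear predictors raise a named error", {
  lc <- linearScoreCohort(25, noise = 0.05)
  lc$features$structureVolume <- lc$features$targetVolume
  expect_error(
    fitStructureModel(lc$ged, lc$dvh, lc$features,
                      kbConfig(minCases = 20), grid = lc$grid),
    "logStructureVolume")
})

test_that("cross-validation measures the estimation error", {
  lc <- linearScoreCohort(30, slope = 2, noise = 0)
  cfg <- kbConfig(minCases = 10)
  # noise-free: the held-out estimate is exact
  expect_lt(crossValidate(lc$ged, lc$dvh, lc$features, cfg, folds = 10,
                          seed = 3, grid = lc$grid), 1e-6)
  expect_error(crossValidate(lc$ged[1:5, ], lc$dvh[1:5, ],
                             lc$features[1:5, ], cfg, folds = 10,
                             grid = lc$grid), "fewer cases than folds")
})

test_that("leave-one-out equals an explicit leave-one-out loop", {
  lc <- linearScoreCohort(12, slope = 1.5, noise = 0.15, seed = 9)
  cfg <- kbConfig(minCases = 2)
  got <- crossValidate(lc$ged, lc$dvh, lc$features, cfg, folds = 12,
                       seed = 5, grid = lc$grid)
  errs <- vapply(seq_len(12), function(i) {
    m <- fitStructureModel(lc$ged[-i, ], lc$dvh[-i, ],
                           lc$features[-i, , drop = FALSE], cfg,
                           grid = lc$grid)
    est <- kbplan:::.estimateFraction(m, lc$ged[i, ],
                                      lc$features[i, , drop = FALSE])
    mean((est - lc$dvh[i, ])^2)
  }, numeric(1))
  expect_equal(got, mean(errs), tolerance = 1e-12)
})

test_that("cross-validated goodness does not depend on case order", {
  lc <- linearScoreCohort(24, slope = 1, noise = 0.1, seed = 13)
  cfg <- kbConfig(minCases = 2)
  base <- crossValidate(lc$ged, lc$dvh, lc$features, cfg, folds = 6,
                        seed = 11, grid = lc$grid)
  perm <- sample(24)
  shuf <- crossValidate(lc$ged[perm, ], lc$dvh[perm, ],
                        lc$features[perm, , drop = FALSE], cfg, folds = 6,
                        seed = 11, grid = lc$grid)
  expect_equal(base, shuf, tolerance = 1e-12)
})

test_that("regression diagnostics behave at their reference points", {
  # perfect fit: pooled coefficient of determination is 1
  lc <- linearScoreCohort(25, slope = 2, noise = 0)
  m <- fitStructureModel(lc$ged, lc$dvh, lc$features,
                         kbConfig(minCases = 20), grid = lc$grid)
  d <- regressionDiagnostics(m)
  expect_equal(d$modelFit, 1, tolerance = 1e-9)

  # pure-noise predictors: fit near zero at large n
  set.seed(17)
  n <- 300
  lcN <- linearScoreCohort(n, slope = 0, noise = 0.3, seed = 17)
  mN <- fitStructureModel(lcN$ged * 0 +
                            matrix(rnorm(n * 100, sd = 0.01), n) +
                            rep(exp(-2 * lcN$grid), each = n),
                          lcN$dvh, lcN$features, kbConfig(minCases = 20),
                          grid = lcN$grid)
  dN <- regressionDiagnostics(mN)
  expect_lt(dN$modelFit, 0.15)
  expect_error(regressionDiagnostics(handModel(residualSE = 0.1)),
               "no regression fits")
})

test_that("influence diagnostics match explicit leave-one-out refits", {
  for (n in c(12, 20, 30)) {
    lc <- linearScoreCohort(n, slope = 1.2, noise = 0.2, seed = n)
    cfg <- kbConfig(minCases = 2, cooksThreshold = 1e-9,
                    studentizedThreshold = 1e9)
    m <- fitStructureModel(lc$ged, lc$dvh, lc$features, cfg,
                           grid = lc$grid)
    out <- detectOutliers(m, cooksThreshold = 1e-9,
                          studentizedThreshold = 1e9,
                          patientIds = sprintf("case%03d", seq_len(n)))
    # oracle: refit without each case; Cook's distance from the shift of
    # the fitted values, studentized residual from the held-out sigma
    fit <- m@fits[[1]]
    X <- stats::model.matrix(fit)
    y <- fitted(fit) + residuals(fit)
    p <- ncol(X)
    s2 <- sum(residuals(fit)^2) / (n - p)
    h <- stats::hatvalues(fit)
    for (i in seq_len(n)) {
      bi <- qr.coef(qr(X[-i, ]), y[-i])
      dFit <- X %*% bi - fitted(fit)
      dOracle <- sum(dFit^2) / (p * s2)
      si <- sqrt(sum((y[-i] - X[-i, ] %*% bi)^2) / (n - 1 - p))
      tOracle <- residuals(fit)[i] / (si * sqrt(1 - h[i]))
      row <- out[out$patientId == sprintf("case%03d", i), ]
      expect_equal(unname(row$cooksDistance), unname(dOracle),
                   tolerance = 1e-8)
      expect_equal(unname(row$studentizedResidual), unname(tOracle),
                   tolerance = 1e-8)
    }
  }
})

test_that("outlier flagging follows residual size and leverage", {
  lc <- linearScoreCohort(25, slope = 2, noise = 0, seed = 8)
  cfg <- kbConfig(minCases = 2)
  m <- fitStructureModel(lc$ged, lc$dvh, lc$features, cfg, grid = lc$grid)
  expect_equal(nrow(detectOutliers(m)), 0L)  # all points on the line

  # plant one gross outlier: it gets the maximal Cook's distance
  lc2 <- lc
  lc2$dvh[7, ] <- lc2$dvh[7, ] + 0.25 * lc$dShape
  m2 <- fitStructureModel(lc2$ged, lc2$dvh, lc2$features, cfg,
                          grid = lc$grid)
  all2 <- detectOutliers(m2, cooksThreshold = 1e-12,
                         studentizedThreshold = 1e12,
                         patientIds = sprintf("case%03d", 1:25))
  expect_equal(all2$patientId[which.max(all2$cooksDistance)], "case007")

  # duplicating a case lowers its leverage and its Cook's distance
  dup <- seq_len(25)
  idx <- c(dup, rep(7, 5))
  lc3 <- list(ged = lc2$ged[idx, ], dvh = lc2$dvh[idx, ],
              features = lc2$features[idx, , drop = FALSE])
  rownames(lc3$ged) <- rownames(lc3$dvh) <- rownames(lc3$features) <-
    sprintf("case%03d", seq_along(idx))
  m3 <- fitStructureModel(lc3$ged, lc3$dvh, lc3$features, cfg,
                          grid = lc$grid)
  all3 <- detectOutliers(m3, cooksThreshold = 1e-12,
                         studentizedThreshold = 1e12,
                         patientIds = sprintf("case%03d", seq_along(idx)))
  d2 <- all2$cooksDistance[all2$patientId == "case007"]
  d3 <- all3$cooksDistance[all3$patientId == "case007"]
  expect_lt(d3, d2)
})

test_that("the training report applies the case-count rules", {
  expect_equal(recommendedCases(12, 45), 60L)   # reported: 45 < 60
  expect_true(is.na(recommendedCases(6, 45)))   # 45 >= 30: not reported
  cfg <- cohortConfig(nPatients = 19, seed = 2, structures = "spinal_cord")
  co <- suppressMessages(generateCohort(cfg))
  expect_warning(kb <- fitKBModel(co, kbConfig(minCases = 20)),
                 "excluded")
  expect_equal(length(kb@structures), 0L)
})
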