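test_that("a model with no uncertainty predicts a zero-width band", {
  # all training DVHs identical: no components, no residual, no SD
  lc <- linearScoreCohort(25, slope = 0, noise = 0)
  lc$dvh <- matrix(lc$dvh[1, ], 25, ncol(lc$dvh), byrow = TRUE)
  rownames(lc$dvh) <- rownames(lc$ged)
  m <- fitStructureModel(lc$ged, lc$dvh, lc$features,
                         kbConfig(minCases = 20), grid = lc$grid)
  pred <- predictDVH(m, lc$ged[1, ], lc$features[1, , drop = FALSE],
                     prescription = 60)
  expect_equal(lowerBand(pred), mostProbable(pred))
  expect_equal(upperBand(pred), mostProbable(pred))
})

test_that("the most probable curve is the regression reconstruction", {
  m <- handModel(residualSE = 0, coefGed1 = 1.5)
  gedCurve <- m@gedBasis@meanCurve + 0.2 * m@gedBasis@components[, 1]
  pred <- predictDVH(m, gedCurve, handFeatures(), prescription = 60)
  sHat <- 1.5 * 0.2
  expected <- 100 * pmin(1, pmax(0, m@dvhBasis@meanCurve +
                                   sHat * m@dvhBasis@components[, 1]))
  expect_equal(mostProbable(pred), expected, tolerance = 1e-9)
  expect_equal(doseGrid(pred), m@dvhBasis@grid * 60)
})

test_that("the band adds component uncertainties in quadrature", {
  m <- handModel(residualSE = c(0.05, 0.02), nComp = 2)
  gedCurve <- m@gedBasis@meanCurve
  pred <- predictDVH(m, gedCurve, handFeatures(), prescription = 60)
  half <- sqrt((0.05 * m@dvhBasis@components[, 1])^2 +
                 (0.02 * m@dvhBasis@components[, 2])^2)
  mp <- m@dvhBasis@meanCurve
  inside <- mp + half < 1 & mp - half > 0  # away from the [0,1] clamp
  expect_equal((upperBand(pred) - lowerBand(pred))[inside],
               (100 * 2 * half)[inside], tolerance = 1e-6)
})

test_that("band ordering holds for randomized models", {
  set.seed(33)
  for (draw in 1:1000) {
    se <- runif(2, 0, 0.2)
    m <- handModel(residualSE = se, nComp = 2,
                   coefGed1 = runif(1, -2, 2))
    ged <- m@gedBasis@meanCurve +
      rnorm(1, sd = 0.3) * m@gedBasis@components[, 1]
    pred <- predictDVH(m, ged, handFeatures(), prescription = 50)
    expect_true(all(lowerBand(pred) <= mostProbable(pred) + 1e-9))
    expect_true(all(mostProbable(pred) <= upperBand(pred) + 1e-9))
    expect_true(all(diff(mostProbable(pred)) <= 1e-9))
  }
})

test_that("widening a regression standard error widens the band", {
  m1 <- handModel(residualSE = c(0.03, 0.02), nComp = 2)
  m2 <- handModel(residualSE = c(0.08, 0.02), nComp = 2)
  ged <- m1@gedBasis@meanCurve + 0.1 * m1@gedBasis@components[, 1]
  p1 <- predictDVH(m1, ged, handFeatures(), 60)
  p2 <- predictDVH(m2, ged, handFeatures(), 60)
  w1 <- upperBand(p1) - lowerBand(p1)
  w2 <- upperBand(p2) - lowerBand(p2)
  expect_true(all(w2 >= w1 - 1e-9))
  expect_gt(max(w2 - w1), 1e-3)
})

test_that("objectives sit strictly below the lower band for OARs", {
  m <- handModel(residualSE = 0.04)
  ged <- m@gedBasis@meanCurve
  pred <- predictDVH(m, ged, handFeatures(), prescription = 60)
  rules <- data.frame(structure = "hand", kind = "upper_point",
                      volumePct = c(10, 50, 90), priority = 70)
  obj <- generateObjectives(pred, rules, prescription = 60)
  expect_equal(nrow(obj), 3L)
  for (i in seq_len(nrow(obj))) {
    lowerDose <- kbplan:::curveDoseAtVolume(doseGrid(pred),
                                            lowerBand(pred),
                                            obj$volumePct[i])
    expect_lt(obj$doseGy[i], lowerDose)
  }

  # zero-width band: objectives at the most probable curve minus margin
  m0 <- handModel(residualSE = 0)
  p0 <- predictDVH(m0, ged, handFeatures(), 60)
  o0 <- generateObjectives(p0, rules, prescription = 60,
                           marginFraction = 0.02)
  mpDose <- kbplan:::curveDoseAtVolume(doseGrid(p0), mostProbable(p0), 50)
  expect_equal(o0$doseGy[o0$volumePct == 50], mpDose - 0.02 * 60,
               tolerance = 1e-9)

  # target coverage rule: lower point at the band's coverage level
  tRules <- data.frame(structure = "hand", kind = "lower_point",
                       volumePct = 98, priority = 120)
  ot <- generateObjectives(pred, tRules, prescription = 60)
  expect_equal(ot$kind, "lower_point")
  expect_equal(ot$doseGy,
               kbplan:::curveDoseAtVolume(doseGrid(pred), lowerBand(pred),
                                          98),
               tolerance = 1e-9)

  badRules <- data.frame(structure = "hand", kind = "upper_point",
                         volumePct = 100, priority = 1)
  expect_error(generateObjectives(pred, badRules, 60), "outside")
})

test_that("structure names are matched through the ontology", {
  model <- c("spinal_cord", "normal_liver", "ptv")
  got <- mapOntology(c("Spinal cord", "Liver-PTV", "Duodenum"), model)
  expect_equal(unname(got$matched["Spinal cord"]), "spinal_cord")
  expect_equal(unname(got$matched["Liver-PTV"]), "normal_liver")
  expect_equal(got$unmatched, "Duodenum")
  expect_error(mapOntology(c("Liver-PTV", "normal liver"), model),
               "ambiguous")
})

test_that("predicting an unmodelled structure is an error", {
  kbCfg <- cohortConfig(nPatients = 25, seed = 12,
                        structures = "spinal_cord")
  co <- suppressMessages(generateCohort(kbCfg))
  kb <- suppressMessages(fitKBModel(co, kbConfig(minCases = 20)))
  p <- co[[1]]
  expect_error(predictStructure(kb, "stomach",
                                p$structures$spinal_cord$geometry,
                                p$field, p$targetVolume),
               "no model for structure")
  pred <- predictStructure(kb, "spinal_cord",
                           p$structures$spinal_cord$geometry,
                           p$field, p$targetVolume)
  expect_s4_class(pred, "PredictedDVH")
})
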