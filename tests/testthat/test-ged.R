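kern <- kernelParams(kIn = 0.05, kOut = 0.15, fOut = 0.3)
fld <- fieldConfig(nArcs = 3, coplanar = FALSE, prescription = 60)

test_that("the voxel kernel reproduces its defining fall-off", {
  expect_equal(gedVoxelDose(-5, TRUE, fld, kern), 60)   # inside target
  expect_equal(gedVoxelDose(-5, FALSE, fld, kern), 60)
  expect_lt(gedVoxelDose(500, TRUE, fld, kern), 1e-8)   # asymptote
  expect_equal(gedVoxelDose(20, TRUE, fld, kern), 60 * exp(-0.05 * 20))
  expect_equal(gedVoxelDose(20, FALSE, fld, kern),
               60 * 0.3 * exp(-0.15 * 20))
})

test_that("the GED curve accumulates the distance histogram", {
  inside <- structureGeometry("in", 30, distanceMm = -3, fraction = 1,
                              inFieldFraction = 1)
  g <- computeGED(inside, fld, kern)
  expect_equal(volumePct(g), ifelse(doseGrid(g) <= 60, 100, 0))

  one <- structureGeometry("one", 10, distanceMm = 10, fraction = 1,
                           inFieldFraction = 1)
  g1 <- computeGED(one, fld, kern)
  lvl <- 60 * exp(-0.05 * 10)
  expect_equal(volumePct(g1),
               ifelse(doseGrid(g1) <= lvl + 1e-12, 100, 0))

  # multi-bin histogram vs. explicit per-bin accumulation
  set.seed(3)
  dist <- sort(runif(25, 0, 80))
  frac <- runif(25); frac <- frac / sum(frac)
  geo <- structureGeometry("multi", 120, dist, frac, inFieldFraction = 0.6)
  g2 <- computeGED(geo, fld, kern)
  oracle <- vapply(doseGrid(g2), function(d) {
    acc <- 0
    for (i in seq_along(dist)) {
      if (gedVoxelDose(dist[i], TRUE, fld, kern) >= d - 1e-12)
        acc <- acc + 0.6 * frac[i]
      if (gedVoxelDose(dist[i], FALSE, fld, kern) >= d - 1e-12)
        acc <- acc + 0.4 * frac[i]
    }
    100 * acc
  }, numeric(1))
  expect_equal(volumePct(g2), oracle, tolerance = 1e-9)

  expect_error(structureGeometry("bad", 10, numeric(0), numeric(0), 0.5),
               "empty")
})

test_that("the in/out-of-field split enumerates the histogram", {
  inside <- structureGeometry("in", 30, -3, 1, 1)
  expect_equal(splitInOutField(inside, fld),
               c(inField = 1, outField = 0))
  far <- structureGeometry("far", 30, 1500, 1, 0)
  expect_equal(splitInOutField(far, fld), c(inField = 0, outField = 1))

  set.seed(5)
  dist <- runif(15, 0, 60)
  frac <- runif(15); frac <- frac / sum(frac)
  geo <- structureGeometry("mix", 50, dist, frac, inFieldFraction = 0.35)
  got <- splitInOutField(geo, fld, gedThreshold = 0.2)
  cut <- 0.2 * 60
  oracle <- sum(frac * 0.35 * (gedVoxelDose(dist, TRUE, fld, kern) >= cut)) +
    sum(frac * 0.65 * (gedVoxelDose(dist, FALSE, fld, kern) >= cut))
  expect_equal(unname(got["inField"]), oracle, tolerance = 1e-12)
  expect_equal(sum(got), 1)
  expect_error(splitInOutField(geo, fld, gedThreshold = 1.2), "gedThreshold")
})

test_that("GED curves respect dominance and refinement invariances", {
  set.seed(9)
  dist <- sort(rgamma(20, 3, scale = 10))
  frac <- runif(20); frac <- frac / sum(frac)
  geo <- structureGeometry("s", 80, dist, frac, 0.5)
  g <- computeGED(geo, fld, kern)
  # pointwise below the step curve at prescription
  expect_true(all(volumePct(g) <= ifelse(doseGrid(g) <= 60, 100, 0) + 1e-9))
  # shifting the whole histogram away from the target lowers the curve
  farGeo <- structureGeometry("s", 80, dist + 15, frac, 0.5)
  gFar <- computeGED(farGeo, fld, kern)
  expect_true(all(volumePct(gFar) <= volumePct(g) + 1e-9))
  # splitting a bin into two equal halves changes nothing
  split <- structureGeometry("s", 80, c(dist, dist),
                             c(frac, frac) / 2, 0.5)
  gSplit <- computeGED(split, fld, kern)
  expect_equal(volumePct(gSplit), volumePct(g), tolerance = 1e-9)
})
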