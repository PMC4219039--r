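test_that("the closed-loop violation table reproduces the published counts", {
  clinical <- evaluateTable5("closed_loop", "clinical")
  t <- violationTotals(clinical)
  expect_equal(t$violations, 11L)
  expect_equal(round(t$ratePct, 1), 3.1)
  expect_equal(t$patientsWithViolations, 7L)
  expect_equal(t$maxSimultaneous, 4L)

  test <- evaluateTable5("closed_loop", "closed_loop")
  tt <- violationTotals(test)
  expect_equal(tt$violations, 4L)
  expect_equal(round(tt$ratePct, 1), 1.1)
  expect_equal(tt$patientsWithViolations, 3L)
  expect_equal(tt$maxSimultaneous, 2L)

  s <- violationSummary(clinical, test)
  expect_equal(s$sharedFailures, 4L)   # every test failure already clinical
  expect_equal(s$newFailures, 0L)
  expect_equal(s$resolvedFailures, 7L)
  expect_equal(s$netImprovementPct, 2.0)
})

test_that("the open-loop violation table reproduces the published counts", {
  clinical <- suppressMessages(evaluateTable5("open_loop", "clinical"))
  tab <- clinical@table
  expect_equal(violationTotals(clinical)$violations, 9L)
  expect_equal(sum(tab$violated & tab$endpoint == "right_kidney_v15"), 6L)
  expect_equal(sum(tab$violated & tab$endpoint == "liver_v30"), 3L)

  ol1 <- suppressMessages(evaluateTable5("open_loop", "open_loop_1"))
  expect_equal(violationTotals(ol1)$violations, 6L)
  ol2 <- suppressMessages(evaluateTable5("open_loop", "open_loop_2"))
  expect_equal(violationTotals(ol2)$violations, 4L)
})

test_that("values exactly at their limit pass", {
  ep <- defaultEndpoints("protocol")
  values <- data.frame(
    patient = "p1",
    endpoint = c("liver_v30", "spine_d1cc", "ptv_d98"),
    value = c(30, 45, 90))
  rep <- evaluateEndpoints(values, ep, nPatients = 1)
  expect_equal(violationTotals(rep)$violations, 0L)
})

test_that("endpoint totals equal a brute-force recount", {
  ep <- defaultEndpoints("protocol")
  set.seed(40)
  for (trial in 1:10) {
    values <- expand.grid(patient = sprintf("p%02d", 1:10),
                          endpoint = ep$id, stringsAsFactors = FALSE)
    values$value <- runif(nrow(values), 0, 120)
    rep <- evaluateEndpoints(values, ep, nPatients = 10)
    # brute force, cell by cell
    nv <- 0
    per <- setNames(integer(10), sprintf("p%02d", 1:10))
    for (r in seq_len(nrow(values))) {
      e <- ep[ep$id == values$endpoint[r], ]
      bad <- if (e$comparator == "<") values$value[r] > e$limit else
        values$value[r] < e$limit
      nv <- nv + bad
      per[values$patient[r]] <- per[values$patient[r]] + bad
    }
    t <- violationTotals(rep)
    expect_equal(t$violations, nv)
    expect_equal(t$patientsWithViolations, sum(per > 0))
    expect_equal(t$maxSimultaneous, max(per))
    expect_equal(t$ratePct, 100 * nv / 80)
  }
})

test_that("evaluate_endpoints ignores patient ordering", {
  ep <- defaultEndpoints("tables")
  fx <- table5Fixture("closed_loop")
  values <- data.frame(patient = fx$patient, endpoint = fx$endpoint,
                       value = fx$clinical)
  a <- evaluateEndpoints(values, ep, nPatients = 45)
  b <- evaluateEndpoints(values[rev(seq_len(nrow(values))), ], ep,
                         nPatients = 45)
  expect_equal(violationTotals(a), violationTotals(b))
})

test_that("violation summaries satisfy the set-algebra identities", {
  ep <- defaultEndpoints("protocol")
  set.seed(41)
  for (trial in 1:10) {
    values <- expand.grid(patient = sprintf("p%02d", 1:8),
                          endpoint = ep$id, stringsAsFactors = FALSE)
    vA <- values; vA$value <- runif(nrow(values), 0, 100)
    vB <- values; vB$value <- runif(nrow(values), 0, 100)
    a <- evaluateEndpoints(vA, ep, nPatients = 8)
    b <- evaluateEndpoints(vB, ep, nPatients = 8)
    s <- violationSummary(a, b)
    expect_equal(s$sharedFailures + s$newFailures,
                 violationTotals(b)$violations)
    expect_equal(s$sharedFailures + s$resolvedFailures,
                 violationTotals(a)$violations)
  }
  # identical reports: nothing new, nothing resolved
  a <- evaluateEndpoints(vA, ep, nPatients = 8)
  s0 <- violationSummary(a, a)
  expect_equal(s0$newFailures, 0L)
  expect_equal(s0$resolvedFailures, 0L)
  expect_equal(s0$netImprovementPct, 0)
})

test_that("paired cohort comparison matches its definitions", {
  set.seed(42)
  a <- runif(12, 10, 20)
  # identical samples: no difference, non-significant
  same <- compareCohorts(a, a)
  expect_equal(same$meanDifference, 0)
  expect_equal(same$pValue, 1)

  # mean/SD/range are the plain summaries
  b <- a + rnorm(12)
  cc <- compareCohorts(a, b)
  expect_equal(cc$meanA, mean(a))
  expect_equal(cc$sdB, sd(b))
  expect_equal(cc$rangeA, range(a))

  # uniformly positive differences: all ranks positive, the exact
  # minimal two-sided p for each n (2 / 2^n)
  for (n in 5:10) {
    x <- runif(n)
    shift <- runif(n, 0.5, 1.5)  # distinct, so the exact test applies
    p <- compareCohorts(x + shift, x)$pValue
    expect_equal(p, 2 / 2^n)
    # oracle: exact sign-flip enumeration of the signed-rank statistic
    ranks <- seq_len(n)
    stats <- vapply(0:(2^n - 1), function(mask) {
      sum(ranks[bitwAnd(mask, 2^(ranks - 1)) > 0])
    }, numeric(1))
    vObs <- n * (n + 1) / 2
    pOracle <- min(1, 2 * mean(stats >= vObs))
    expect_equal(p, pOracle, tolerance = 1e-12)
  }
  expect_error(compareCohorts(1, numeric(0)), "equal length")
})
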