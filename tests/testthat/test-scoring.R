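# Outcome classification, failure-mode tagging and cohort aggregation.

softMetrics <- function(gamma = 98, lr = 0.2, ap = -0.2, pt = 1) {
  list(gammaPassRate = gamma, dtaMeanLR = lr, dtaMeanAP = ap,
       pointDiffPct = pt)
}

test_that("gamma bands classify with inclusive lower bounds", {
  expect_equal(auditOutcome(classifyOutcome(softMetrics(96),
                                            caseId = "soft_tissue")),
               "optimal")
  expect_equal(auditOutcome(classifyOutcome(softMetrics(95.0),
                                            caseId = "soft_tissue")),
               "optimal")
  expect_equal(auditOutcome(classifyOutcome(softMetrics(94.99),
                                            caseId = "soft_tissue")),
               "action")
  expect_equal(auditOutcome(classifyOutcome(softMetrics(90.0),
                                            caseId = "soft_tissue")),
               "action")
  r <- classifyOutcome(softMetrics(89.99), caseId = "soft_tissue")
  expect_equal(auditOutcome(r), "out_of_tolerance")
  expect_true("gamma" %in% r@triggers)
})

test_that("DTA and point limits force out-of-tolerance past the gamma band", {
  r <- classifyOutcome(softMetrics(92, pt = 9), caseId = "soft_tissue")
  expect_equal(auditOutcome(r), "out_of_tolerance")
  expect_true("point_dose" %in% r@triggers)
  # strict upper limits: exactly at the limit passes
  expect_equal(auditOutcome(classifyOutcome(softMetrics(96, pt = 8.0),
                                            caseId = "soft_tissue")),
               "optimal")
  expect_equal(auditOutcome(classifyOutcome(softMetrics(96, pt = 8.01),
                                            caseId = "soft_tissue")),
               "out_of_tolerance")
  expect_equal(auditOutcome(classifyOutcome(softMetrics(96, ap = -3.0),
                                            caseId = "soft_tissue")),
               "optimal")
  expect_equal(auditOutcome(classifyOutcome(softMetrics(96, ap = 3.01),
                                            caseId = "soft_tissue")),
               "out_of_tolerance")
  # spine interface uses the tighter 2 mm limit
  sm <- list(gammaPassRate = 97, dtaMaxInterface = 2.0, dtaMeanLR = 0.5,
             pointDiffPct = 1)
  expect_equal(auditOutcome(classifyOutcome(sm, caseId = "spine")),
               "optimal")
  sm$dtaMaxInterface <- 2.01
  expect_equal(auditOutcome(classifyOutcome(sm, caseId = "spine")),
               "out_of_tolerance")
  # negative displacements are scored on magnitude
  expect_equal(auditOutcome(classifyOutcome(softMetrics(96, lr = -3.2),
                                            caseId = "soft_tissue")),
               "out_of_tolerance")
})

test_that("missing required metrics are an error", {
  m <- softMetrics(); m$dtaMeanAP <- NULL
  expect_error(classifyOutcome(m, caseId = "soft_tissue"), "missing")
  expect_error(classifyOutcome(list(gammaPassRate = 95),
                               caseId = "lung"), "missing")
})

test_that("failure-mode rules map injected modes and refuse passing plans", {
  oot <- function(extra) {
    m <- c(softMetrics(85), extra)
    classifyOutcome(m, caseId = "soft_tissue")
  }
  r <- classifyFailureMode(oot(list()))
  expect_equal(failureMode(r), "unclassified")
  m <- softMetrics(85); m$dtaMeanLR <- -2.9
  expect_equal(failureMode(classifyFailureMode(
    classifyOutcome(m, caseId = "soft_tissue"))), "IGRT mismatch")
  expect_equal(failureMode(classifyFailureMode(
    oot(list(ptvGlobalDiffPct = 10.6)))),
    "In-volume dose difference (low)")
  expect_equal(failureMode(classifyFailureMode(
    oot(list(ptvGlobalDiffPct = -10.6)))),
    "In-volume dose difference (high)")
  expect_equal(failureMode(classifyFailureMode(
    oot(list(outfieldGlobalDiffPct = -8)))), "Out of field dose (high)")
  expect_equal(failureMode(classifyFailureMode(
    oot(list(rotationDeg = 2)))), "Other shift/misalignment")
  pass <- classifyOutcome(softMetrics(97), caseId = "soft_tissue")
  expect_error(classifyFailureMode(pass), "out-of-tolerance")
})

test_that("cohort percentages reproduce the printed tabulations", {
  # overall pass rates from the out-of-tolerance counts
  expect_equal(unname(cohortPercentages(c(271, 10))), c(96.4, 3.6))
  expect_equal(unname(cohortPercentages(c(215, 23))), c(90.3, 9.7))
  expect_equal(unname(cohortPercentages(c(236, 27))), c(89.7, 10.3))
  # failure-mode shares over the 60 failures
  fm <- cohortPercentages(c(22, 13, 12, 6, 5, 1, 1))
  expect_equal(unname(fm), c(36.7, 21.7, 20.0, 10.0, 8.3, 1.7, 1.7))
  # single plan
  expect_equal(unname(cohortPercentages(c(1))), 100)
})

test_that("aggregation conserves counts and partitions outcomes", {
  mk <- function(gamma, cid = "soft_tissue") {
    m <- softMetrics(gamma)
    if (cid == "spine")
      m <- list(gammaPassRate = gamma, dtaMaxInterface = 0.4,
                dtaMeanLR = 0.1, pointDiffPct = 1)
    r <- classifyOutcome(m, caseId = cid)
    if (r@outcome == "out_of_tolerance") r <- classifyFailureMode(r)
    r
  }
  res <- c(lapply(c(97, 96, 93, 85), mk),
           lapply(c(99, 88), mk, cid = "spine"))
  cs <- aggregateCohort(res)
  expect_equal(cs@nTotal, 6L)
  expect_equal(sum(cs@outcomes$n), 6)
  soft <- cs@outcomes[cs@outcomes$case == "soft_tissue", ]
  expect_equal(soft$n[soft$outcome == "optimal"], 2)
  expect_equal(soft$n[soft$outcome == "action"], 1)
  expect_equal(soft$n[soft$outcome == "out_of_tolerance"], 1)
  # one outcome per plan, percentages sum to ~100 within each case
  for (cc in unique(cs@outcomes$case))
    expect_lt(abs(sum(cs@outcomes$pct[cs@outcomes$case == cc]) - 100), 0.15)
  expect_equal(sum(cs@failureModes$n), 2)
  expect_error(aggregateCohort(list()), "empty")
})

test_that("pooled-variance comparison matches the closed form", {
  r <- compareSeries(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(round(r$statistic, 3), -3.674)
  expect_equal(r$p.value, 0.02131164, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_true(r$significant)  # p < 0.05 strictly
  same <- compareSeries(c(2, 2), c(2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_false(same$significant)
  deg <- compareSeries(c(2, 2), c(3, 3))
  expect_true(deg$degenerate)
  expect_error(compareSeries(1, c(1, 2)), "at least 2")
})

test_that("results and summaries serialize to CSV/JSON", {
  res <- lapply(c(97, 85), function(g) {
    r <- classifyOutcome(softMetrics(g), caseId = "soft_tissue")
    if (r@outcome == "out_of_tolerance") classifyFailureMode(r) else r
  })
  p <- withr::local_tempfile(fileext = ".csv")
  writeResultsCsv(res, p)
  df <- read.csv(p)
  expect_equal(nrow(df), 2)
  expect_true(all(c("case", "outcome", "gammaPassRate") %in% names(df)))
  dir <- withr::local_tempdir()
  writeCohortSummary(aggregateCohort(res), dir)
  expect_true(file.exists(file.path(dir, "outcomes.csv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
})
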