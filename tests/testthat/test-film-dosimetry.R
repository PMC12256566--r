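# Film dosimetry: calibration fitting, darkening correction, check-film
# QC and dose conversion.

test_that("calibration fit recovers the generator parameters", {
  for (ch in 1:3) {
    expect_lt(abs(cal0@params[[ch]][["a"]] - fm0@a[ch]) / fm0@a[ch], 1e-3)
    expect_lt(abs(cal0@params[[ch]][["b"]] - fm0@b[ch]) / fm0@b[ch], 1e-3)
  }
  expect_lt(cal0@residual, 1e-6)
  # predicted dose at netOD 0 is 0
  for (ch in 1:3) expect_equal(predictDose(cal0, 0, ch), 0)
})

test_that("calibration dataset invariants are enforced", {
  expect_error(new("CalibrationDataset", dose = c(0, 1, 2),
                   netOD = matrix(0.1, 3, 3), beam = ""),
               "at least 5")
  expect_error(new("CalibrationDataset", dose = c(1, 2, 5, 9, 13, 20),
                   netOD = matrix(0.1, 6, 3), beam = ""),
               "zero-dose")
  bad <- makeCalibrationDataset(fm0)
  bad@netOD[4, 1] <- bad@netOD[6, 1]  # non-monotone channel
  expect_error(fitCalibration(bad), "increasing")
})

test_that("noisy 12-level calibration stays within the film uncertainty", {
  d <- makeCalibrationDataset(filmForwardModel(), noise = 0.005, seed = 21)
  cal <- fitCalibration(d)
  expect_lt(cal@residual, 0.025)
})

test_that("power form is available through the form registry", {
  cal <- fitCalibration(makeCalibrationDataset(fm0), form = "power")
  expect_identical(cal@form, "power")
  expect_lt(cal@residual, 0.03)
  # registry rejects unknown forms
  expect_error(fitCalibration(makeCalibrationDataset(fm0), form = "cubic"),
               "unknown calibration form")
})

test_that("darkening correction refers netOD to the reference time", {
  pd <- logisticPlane(norm = 10)
  ref <- renderFilmScan(pd, fm0, scanDelayHours = fm0@tRef)
  # identity at tRef
  expect_equal(netOD(applyDarkeningCorrection(ref, cal0)), netOD(ref))
  # inverse of the generator darkening at 2x tRef
  late <- renderFilmScan(pd, fm0, scanDelayHours = 2 * fm0@tRef)
  corr <- applyDarkeningCorrection(late, cal0)
  expect_lt(max(abs(netOD(corr) - netOD(ref)) / pmax(netOD(ref), 1e-3)),
            5e-4)
  # corrected netOD below raw for delay > tRef
  expect_true(all(netOD(corr) <= netOD(late)))
  # out-of-range delay warns but still corrects
  expect_warning(applyDarkeningCorrection(ref, cal0,
                                          scanDelayHours = 20 * fm0@tRef),
                 "validated")
})

test_that("check-film QC computes the through-origin scale factor", {
  qc <- checkFilmQC(checkFilmPair(c(10, 15), c(10.4, 15.6)))
  expect_equal(scaleFactor(qc), 10 / 10.4, tolerance = 1e-9)
  expect_equal(round(scaleFactor(qc), 4), 0.9615)
  expect_true(withinLimit(qc))

  ident <- checkFilmQC(checkFilmPair(c(10, 15), c(10, 15)))
  expect_equal(scaleFactor(ident), 1)
  expect_equal(ident@residual, 0)

  qc2 <- checkFilmQC(checkFilmPair(c(10, 15), c(10.6, 15.9)))
  expect_equal(round(scaleFactor(qc2), 4), 0.9434)
  expect_false(withinLimit(qc2))

  # |factor - 1| exactly at the limit counts as within (inclusive bound)
  qc3 <- checkFilmQC(checkFilmPair(c(10, 15), c(10, 15) / 0.95))
  expect_equal(abs(scaleFactor(qc3) - 1), 0.05, tolerance = 1e-9)
  expect_true(withinLimit(qc3))

  # internally inconsistent pair (non-linear mismatch) is rejected
  expect_error(checkFilmQC(checkFilmPair(c(10, 15), c(10.8, 14.6))),
               "inconsistent")
})

test_that("scan-to-dose applies the scale factor and refuses bad QC", {
  u <- DosePlane(matrix(10, 21, 21), spacing = 1)
  scan <- renderFilmScan(u, fm0)
  rec <- scanToDose(scan, cal0, qc1)
  expect_lt(max(abs(doseValues(rec) - 10)) / 10, 0.001)

  qc104 <- new("ScalingQC", scaleFactor = 1.04, withinLimit = TRUE,
               controlLimit = 0.05, residual = 0)
  rec104 <- scanToDose(scan, cal0, qc104)
  expect_equal(doseValues(rec104), 1.04 * doseValues(rec),
               tolerance = 1e-12)

  qc106 <- new("ScalingQC", scaleFactor = 1.06, withinLimit = FALSE,
               controlLimit = 0.05, residual = 0)
  expect_error(scanToDose(scan, cal0, qc106), "rescan required")
})

test_that("red-only conversion matches the red-channel response", {
  u <- DosePlane(matrix(6, 11, 11), spacing = 1)
  scan <- renderFilmScan(u, fm0)
  rec <- scanToDose(scan, cal0, qc1, channels = "red")
  expect_lt(max(abs(doseValues(rec) - 6)) / 6, 0.001)
})

test_that("full film chain holds 0.5% at zero noise across delays", {
  pd <- logisticPlane(norm = 12)
  for (delay in c(fm0@tRef, 1.7 * fm0@tRef, 3 * fm0@tRef)) {
    scan <- renderFilmScan(pd, fm0, scanDelayHours = delay)
    rec <- scanToDose(applyDarkeningCorrection(scan, cal0), cal0, qc1)
    rel <- abs(doseValues(rec) - doseValues(pd)) / pmax(doseValues(pd), 1)
    expect_lt(max(rel, na.rm = TRUE), 0.005)
  }
})

test_that("per-pixel dose noise stays within the stated film uncertainty", {
  fmN <- filmForwardModel()  # default scanner noise
  u <- DosePlane(matrix(12, 60, 60), spacing = 1)
  rec <- scanToDose(renderFilmScan(u, fmN, seed = 17), cal0, qc1)
  expect_lte(sd(doseValues(rec)) / 12, 0.025)
})

test_that("calibration artifacts survive CSV/JSON round trips", {
  d <- makeCalibrationDataset(fm0)
  p1 <- withr::local_tempfile(fileext = ".csv")
  writeCalibrationCsv(d, p1)
  d2 <- readCalibrationCsv(p1)
  expect_equal(d2@dose, d@dose)
  expect_equal(d2@netOD, d@netOD, ignore_attr = TRUE)
  p2 <- withr::local_tempfile(fileext = ".json")
  writeCalibrationModel(cal0, p2)
  cal2 <- readCalibrationModel(p2)
  expect_equal(cal2@params, cal0@params, tolerance = 1e-12)
  expect_equal(predictDose(cal2, 0.4, 1), predictDose(cal0, 0.4, 1))
})
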