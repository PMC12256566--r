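# Synthetic-data generator: phantom geometry, planned-dose constraints,
# perturbations and the forward film model.

test_that("phantom planes have the case geometry", {
  pp <- makePhantomPlane("soft_tissue", c(200, 200), 0.5)
  a <- sum(structureMask(pp, "PTV")) * 0.5^2
  # disc area by pixel-centre counting: within a fraction of a one-pixel
  # boundary band of the analytic circle area pi * 12.5^2
  expect_lt(abs(a - pi * 12.5^2), pi * 2 * 12.5 * 0.5 / 4)
  expect_true(all(materialLabels(pp) == "plastic_water"))

  lung <- makePhantomPlane("lung", c(200, 200), 0.5)
  m <- structureMask(lung, "PTV")
  ext <- (diff(range(which(apply(m, 2, any)))) + 1) * 0.5
  expect_lt(abs(ext - 40), 0.5 + 1e-9)  # 2 cm target + 1 cm margin
  expect_setequal(unique(as.vector(materialLabels(lung))),
                  c("inhale_lung", "lung_target"))

  spine <- makePhantomPlane("spine")
  expect_identical(sum(structureMask(spine, "PTV") &
                         structureMask(spine, "cord_PRV")), 0L)
  expect_true(all(c("cortical_bone", "trabecular_bone", "plastic_water")
                  %in% unique(as.vector(materialLabels(spine)))))
  expect_error(makePhantomPlane("brain"), "arg")
  expect_error(makePhantomPlane("lung", spacing = 5), "spacing")
})

test_that("fiducials are valid registration targets", {
  for (cid in c("soft_tissue", "spine", "lung")) {
    f <- fiducials(makePhantomPlane(cid))
    expect_gte(nrow(f), 3)
    v1 <- f[2, ] - f[1, ]
    cr <- (f[-1, 1] - f[1, 1]) * v1[2] - (f[-1, 2] - f[1, 2]) * v1[1]
    expect_gt(max(abs(cr)), 1)  # non-collinear
  }
})

test_that("planned doses satisfy every case constraint", {
  for (cid in c("soft_tissue", "spine", "lung")) {
    pp <- makePhantomPlane(cid)
    cd <- caseDefinition(cid)
    pd <- makePlannedDose(pp, cd)  # errors if any constraint fails
    chk <- checkPlanConstraints(pd, pp, cd)
    expect_true(all(vapply(chk, `[[`, TRUE, "ok")), label = cid)
    dp <- prescriptionPerFraction(cd)
    expect_lte(max(doseValues(pd)), 1.40 * dp)
    expect_gte(mean(doseValues(pd)[structureMask(pp, "PTV")] >= dp),
               cd@coverageRequirement)
  }
  # spine-specific: cord trough respects the PRV limit at its centre
  pp <- makePhantomPlane("spine")
  pd <- makePlannedDose(pp, caseDefinition("spine"))
  expect_lte(doseAt(pd, 0, 0), 14 / 2)
  # infeasible request reports the violated constraint
  expect_error(makePlannedDose(pp, caseDefinition("spine"), maxFactor = 1.5),
               "max_dose")
})

test_that("identity and scaling perturbations are exact", {
  pd <- logisticPlane()
  expect_identical(doseValues(perturbDose(pd, perturbationSpec())),
                   doseValues(pd))
  sc <- perturbDose(pd, perturbationSpec(globalScale = 1.05))
  expect_equal(doseValues(sc), 1.05 * doseValues(pd), tolerance = 1e-12)
  expect_error(perturbDose(pd, perturbationSpec(shift = c(40, 0))),
               "25%")
})

test_that("shift perturbation moves profile crossings by the shift", {
  v <- outer(rep(1, 101), seq(0, 20, length.out = 101))  # x gradient
  gr <- DosePlane(v, spacing = 0.5)
  sh <- perturbDose(gr, perturbationSpec(shift = c(2, 0)))
  pos <- seq(-24, 24, by = 0.05)
  d0 <- doseAt(gr, pos, rep(0, length(pos)))
  d1 <- doseAt(sh, pos, rep(0, length(pos)))
  c0 <- approx(d0, pos, xout = 10, ties = "ordered")$y
  keep <- !is.na(d1) & d1 > 0
  c1 <- approx(d1[keep], pos[keep], xout = 10, ties = "ordered")$y
  expect_lt(abs((c1 - c0) - 2), 0.5 / 10)
})

test_that("generator outputs are deterministic given the seed", {
  sp <- perturbationSpec(shift = c(1, -1), noiseSigma = 0.01, seed = 42)
  pd <- logisticPlane()
  a <- perturbDose(pd, sp, normalization = 12)
  b <- perturbDose(pd, sp, normalization = 12)
  expect_identical(doseValues(a), doseValues(b))
  s1 <- renderFilmScan(pd, filmForwardModel(), seed = 7)
  s2 <- renderFilmScan(pd, filmForwardModel(), seed = 7)
  expect_identical(netOD(s1), netOD(s2))
  s3 <- renderFilmScan(pd, filmForwardModel(), seed = 8)
  expect_false(identical(netOD(s1), netOD(s3)))
})

test_that("forward film model behaves physically", {
  fm <- fm0
  # zero dose -> zero netOD
  z <- renderFilmScan(DosePlane(matrix(0, 11, 11), spacing = 1), fm)
  expect_equal(max(abs(netOD(z))), 0)
  # netOD strictly increasing in dose over [0, 20]
  d <- seq(0, 20, by = 0.25)
  for (ch in 1:3) expect_true(all(diff(filmNetOD(fm, d, ch)) > 0))
  # darkening strictly increases netOD with delay
  pd <- DosePlane(matrix(8, 11, 11), spacing = 1)
  odRef <- netOD(renderFilmScan(pd, fm, scanDelayHours = fm@tRef))
  od2 <- netOD(renderFilmScan(pd, fm, scanDelayHours = 2 * fm@tRef))
  expect_true(all(od2 > odRef))
  # doses beyond the calibration range are refused
  expect_error(renderFilmScan(DosePlane(matrix(21, 5, 5), spacing = 1), fm),
               "20 Gy")
})

test_that("render -> convert round trip inverts the film model", {
  pd <- logisticPlane(norm = 12)
  scan <- renderFilmScan(pd, fm0, scanDelayHours = fm0@tRef)
  rec <- scanToDose(scan, cal0, qc1)
  rel <- abs(doseValues(rec) - doseValues(pd)) / pmax(doseValues(pd), 0.5)
  expect_lt(max(rel, na.rm = TRUE), 0.001)
})
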