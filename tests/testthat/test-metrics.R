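# DTA profiles, point and region dose differences, conformity indices.

test_that("identical planes give zero DTA on every profile", {
  pd <- logisticPlane()
  for (ax in c("LR", "AP")) {
    r <- profileDTA(pd, pd, ax, normalization = 12)
    expect_equal(max(abs(r@edges$displacement_mm)), 0, tolerance = 1e-9)
  }
})

test_that("a translated measurement returns minus the shift", {
  pd <- logisticPlane()
  tr <- perturbDose(pd, perturbationSpec(shift = c(0, 1.3)))
  r <- profileDTA(pd, tr, "AP", normalization = 12)
  expect_equal(r@meanAP, -1.3, tolerance = 0.02)
  # both edges move the same way under a pure translation
  expect_lt(diff(range(r@edges$displacement_mm)), 0.05)
})

test_that("DTA responds linearly to injected shifts", {
  pd <- logisticPlane()
  for (s in c(0.5, 1, 2, 3)) {
    tr <- perturbDose(pd, perturbationSpec(shift = c(s, 0)))
    r <- profileDTA(pd, tr, "LR", normalization = 12)
    expect_lt(abs(r@meanLR - (-s)), 0.1)
  }
})

test_that("a global scale moves crossings outward by dose over gradient", {
  norm <- 12
  pd <- logisticPlane(norm = norm)
  sc <- perturbDose(pd, perturbationSpec(globalScale = 1.05))
  r <- profileDTA(pd, sc, "LR", normalization = norm)
  # closed form: crossing radius of level 0.7/1.05 vs 0.7 of the logistic
  k <- 1.2
  shift <- k * (log(1.15 / (0.7 / 1.05) - 1) - log(1.15 / 0.7 - 1))
  expect_equal(sort(r@edges$displacement_mm), sort(c(shift, -shift)),
               tolerance = 0.02)
  expect_lt(abs(r@meanLR), 0.02)  # symmetric outward motion cancels
})

test_that("missing crossings are reported with the failing side", {
  pd <- logisticPlane()
  low <- DosePlane(doseValues(pd) * 0.3, spacing = 1)
  expect_error(profileDTA(pd, low, "LR", normalization = 12), "measured")
})

test_that("case DTA protocol fills the case-relevant fields", {
  soft <- makePhantomPlane("soft_tissue")
  cd <- caseDefinition("soft_tissue")
  pd <- makePlannedDose(soft, cd)
  r <- caseDTA(pd, pd, cd)
  expect_equal(abs(r@meanLR), 0, tolerance = 1e-9)
  expect_equal(abs(r@meanAP), 0, tolerance = 1e-9)
  expect_true(is.na(r@maxAtInterface))

  lungP <- makePhantomPlane("lung")
  cdl <- caseDefinition("lung")
  pdl <- makePlannedDose(lungP, cdl)
  rl <- caseDTA(pdl, pdl, cdl)
  expect_true(is.na(rl@meanLR))  # L-R not assessed for lung
  expect_false(is.na(rl@meanAP))

  spineP <- makePhantomPlane("spine")
  cds <- caseDefinition("spine")
  pds <- makePlannedDose(spineP, cds)
  shifted <- perturbDose(pds, perturbationSpec(shift = c(0, 1.5)))
  rs <- caseDTA(pds, shifted, cds)
  expect_equal(rs@maxAtInterface, 1.5, tolerance = 0.1)
  # interface crossings sit at the cord trough, not the outer field edge
  expect_true(all(abs(rs@edges$planned_mm) < 13))
})

test_that("point dose differences follow the printed definitions", {
  d <- pointDoseDiff(10.5, 10.0, 15)
  expect_equal(d@local, 5.0, tolerance = 1e-9)
  expect_equal(d@global, 100 * 0.5 / 15, tolerance = 1e-9)
  z <- pointDoseDiff(10, 10, 15)
  expect_equal(z@local, 0)
  expect_equal(z@global, 0)
  expect_error(pointDoseDiff(10, 0, 15), "positive")
})

test_that("region statistics use the prescription-isodose PTV", {
  pd <- logisticPlane(norm = 12)
  same <- regionDoseStats(pd, pd, 12)
  expect_equal(same@local, 0)
  expect_equal(same@global, 0)
  # measured 3% low inside the region
  meas <- DosePlane(doseValues(pd) * 0.97, spacing = 1)
  r <- regionDoseStats(pd, meas, 12)
  expect_equal(r@local, 100 * (1 / 0.97 - 1), tolerance = 1e-6)
  expect_error(regionDoseStats(pd, pd, 12, mask = matrix(FALSE, 61, 61)),
               "empty")
})

test_that("out-of-field changes do not leak into PTV statistics", {
  pd <- logisticPlane(norm = 12)
  out <- perturbDose(pd, perturbationSpec(outfieldScale = 1.2),
                     normalization = 12)
  ptv <- regionDoseStats(pd, out, 12)
  expect_equal(ptv@global, 0, tolerance = 1e-9)
  ofMask <- doseValues(pd) < 0.5 * 12 & doseValues(pd) > 0.05 * 12
  of <- regionDoseStats(pd, out, 12, mask = ofMask,
                        region = "outfield_mean")
  expect_lt(of@global, -1)  # measured exceeds plan out of field
})

test_that("conformity indices match analytic circle areas", {
  # 100% isodose exactly on the PTV boundary
  ptv <- radiusMapTest <- NULL
  pd0 <- logisticPlane(norm = 12)
  mask100 <- doseValues(pd0) >= 12
  expect_equal(unname(conformityIndices(pd0, mask100, 12)["CI100"]), 1)
  # analytic radii: CI = (r_level / r_PTV)^2
  soft <- makePhantomPlane("soft_tissue")
  cd <- caseDefinition("soft_tissue")
  pd <- makePlannedDose(soft, cd)
  ci <- conformityIndices(pd, structureMask(soft, "PTV"), 15)
  r100 <- analyticIsodoseRadius(1, 12.5)
  r50 <- analyticIsodoseRadius(0.5, 12.5)
  expect_equal(unname(ci["CI100"]), (r100 / 12.5)^2, tolerance = 0.01)
  expect_equal(unname(ci["CI50"]), (r50 / 12.5)^2, tolerance = 0.02)
  # compliant defaults for every case
  for (cid in c("soft_tissue", "spine", "lung")) {
    pp <- makePhantomPlane(cid)
    cdd <- caseDefinition(cid)
    pdd <- makePlannedDose(pp, cdd)
    cii <- conformityIndices(pdd, structureMask(pp, "PTV"),
                             prescriptionPerFraction(cdd))
    expect_lte(cii[["CI100"]], 1.2)
    expect_lte(cii[["CI50"]], 5.0)
  }
  expect_error(conformityIndices(pd, matrix(FALSE, 3, 3), 15), "empty")
})
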