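# Landmark registration: rigid fits, observer agreement, resampling.

test_that("noiseless rigid recovery is exact", {
  set.seed(11)
  P <- randomLandmarks()
  tr <- rigidTransform2D(3, c(1.2, -0.7))
  fit <- fitRigid(landmarkSet(P, applyTransform(tr, P)))
  expect_lt(abs(fit@rotationDeg - 3), 1e-6)
  expect_lt(max(abs(fit@translation - c(1.2, -0.7))), 1e-6)
  expect_lt(fit@rmsResidual, 1e-9)
  # identity correspondence
  id <- fitRigid(landmarkSet(P, P))
  expect_equal(id@rotationDeg, 0)
  expect_equal(id@translation, c(0, 0))
})

test_that("rigid fit is invariant to landmark ordering", {
  set.seed(12)
  P <- randomLandmarks(5)
  tr <- rigidTransform2D(-2.5, c(0.4, 2.1))
  Q <- applyTransform(tr, P)
  f1 <- fitRigid(landmarkSet(P, Q))
  ord <- c(4, 1, 5, 3, 2)
  f2 <- fitRigid(landmarkSet(P[ord, ], Q[ord, ]))
  expect_identical(f1@rotationDeg, f2@rotationDeg)
  expect_identical(f1@translation, f2@translation)
})

test_that("fits compose like the transforms that generated the data", {
  set.seed(13)
  P <- randomLandmarks()
  t1 <- rigidTransform2D(2, c(1, 2))
  t2 <- rigidTransform2D(-5, c(-3, 0.5))
  Q <- applyTransform(t2, applyTransform(t1, P))
  fit <- fitRigid(landmarkSet(P, Q))
  comp <- composeTransforms(t2, t1)
  expect_lt(max(abs(applyTransform(fit, P) - applyTransform(comp, P))),
            1e-9)
})

test_that("noisy landmark fits recover the transform to sub-pixel", {
  set.seed(99)
  errs <- replicate(100, {
    P <- randomLandmarks()
    tr <- rigidTransform2D(2, c(1.5, -0.5))
    Pn <- P + matrix(rnorm(8, 0, 0.1), 4, 2)
    f <- suppressWarnings(fitRigid(landmarkSet(Pn, applyTransform(tr, P))))
    sqrt(sum((applyTransform(f, c(0, 0)) -
                applyTransform(tr, c(0, 0)))^2))
  })
  expect_lt(median(errs), 0.15)
})

test_that("degenerate landmark sets are rejected or flagged", {
  P <- rbind(c(0, 0), c(10, 10), c(20, 20))  # collinear
  expect_error(fitRigid(landmarkSet(P, P)), "collinear")
  set.seed(14)
  P <- randomLandmarks()
  Q <- applyTransform(rigidTransform2D(1, c(0, 0)), P)
  Q[1, ] <- Q[1, ] + c(3, 0)  # gross entry error
  expect_warning(fitRigid(landmarkSet(P, Q)), "suspect")
})

test_that("observer agreement uses corner discrepancy with a strict bound", {
  t0 <- rigidTransform2D(0, c(0, 0))
  same <- observerAgreement(t0, t0, extentMm = 60)
  expect_equal(same$maxDiscrepancyMm, 0)
  expect_true(same$agreed)
  # pure translation difference
  tr <- observerAgreement(t0, rigidTransform2D(0, c(0.6, 0)), extentMm = 60)
  expect_equal(tr$maxDiscrepancyMm, 0.6)
  expect_false(tr$agreed)
  # 0.1 degree over a 60 mm corner radius: r * dtheta
  rot <- observerAgreement(t0, rigidTransform2D(0.1, c(0, 0)), extentMm = 60)
  expect_equal(rot$maxDiscrepancyMm, 60 * 0.1 * pi / 180, tolerance = 1e-6)
  expect_true(rot$agreed)
  # the flag flips exactly at the 0.5 mm tolerance
  expect_true(observerAgreement(t0, rigidTransform2D(0, c(0.4999, 0)))$agreed)
  expect_false(observerAgreement(t0, rigidTransform2D(0, c(0.5, 0)))$agreed)
})

test_that("resampling onto the plan grid is exact on lattice shifts", {
  set.seed(15)
  v <- matrix(rnorm(41 * 41, 10, 1)^2 / 10, 41, 41)
  pd <- DosePlane(v, spacing = 1)
  id <- resampleToPlan(pd, rigidTransform2D(0, c(0, 0)), pd)
  expect_equal(doseValues(id), v)
  sh <- resampleToPlan(pd, rigidTransform2D(0, c(1, 0)), pd)
  expect_lt(max(abs(doseValues(sh)[5:35, 5:35] - v[5:35, 4:34])), 1e-9)
})

test_that("resampling round trip stays within the interpolation bound", {
  # smooth plane: saturated plateau and wide penumbra sampled at 0.5 mm
  pd <- logisticPlane(norm = 12, k = 2.5, edge = 20, half = 36,
                      spacing = 0.5)
  tr <- rigidTransform2D(1.5, c(1.3, -0.8))
  fwd <- resampleToPlan(pd, tr, pd)
  back <- resampleToPlan(fwd, invertTransform(tr), pd)
  n <- nrow(doseValues(pd))
  interior <- abs(doseValues(back) - doseValues(pd))[21:(n - 20), 21:(n - 20)]
  expect_lt(max(interior, na.rm = TRUE), 0.002 * 12)
  # insufficient overlap is rejected
  expect_error(resampleToPlan(pd, rigidTransform2D(0, c(45, 0)), pd),
               "50%")
})

test_that("landmark and transform files round trip", {
  set.seed(16)
  s1 <- landmarkSet(randomLandmarks(), randomLandmarks(), "obsA")
  s2 <- landmarkSet(randomLandmarks(), randomLandmarks(), "obsB")
  p <- withr::local_tempfile(fileext = ".csv")
  writeLandmarksCsv(list(s1, s2), p)
  back <- readLandmarksCsv(p)
  expect_setequal(names(back), c("obsA", "obsB"))
  expect_equal(back$obsA@film, s1@film, ignore_attr = TRUE)
  pt <- withr::local_tempfile(fileext = ".json")
  writeTransform(rigidTransform2D(1.5, c(2, -3), 0.1), pt)
  t2 <- readTransform(pt)
  expect_equal(t2@rotationDeg, 1.5)
  expect_equal(t2@translation, c(2, -3))
})
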