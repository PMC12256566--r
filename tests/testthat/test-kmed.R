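# Medium-dependent corrections: k_med maps and point corrections.

# a synthetic table with known non-unity factors for both reporting modes
testTable <- function() {
  tb <- kmedTable()
  f <- tb@factors
  set <- function(m, mode, v) f$factor[f$material == m & f$mode == mode] <<- v
  set("cortical_bone", "Dmm", 1.08); set("cortical_bone", "Dww", 0.93)
  set("trabecular_bone", "Dmm", 1.03); set("trabecular_bone", "Dww", 0.97)
  set("inhale_lung", "Dmm", 1.01); set("inhale_lung", "Dww", 0.99)
  set("lung_target", "Dmm", 1.02); set("lung_target", "Dww", 0.98)
  kmedTable(f, waterToTissue = 0.992)
}

test_that("unity table leaves doses bit-identical except water regions", {
  spine <- makePhantomPlane("spine", c(120, 120), 1)
  pd <- makePlannedDose(spine, caseDefinition("spine"))
  tb <- kmedTable(waterToTissue = 1)  # all factors 1
  out <- applyKmedMap(pd, spine, tb, "Dmm")
  expect_identical(doseValues(out), doseValues(pd))
})

test_that("water-to-tissue factor applies to plastic-water film regions", {
  pp <- makePhantomPlane("soft_tissue", c(60, 60), 1)
  u <- DosePlane(matrix(10, 60, 60), spacing = 1)
  out <- applyKmedMap(u, pp, kmedTable(), "Dmm")
  expect_equal(unique(as.vector(doseValues(out))), 9.92)
  # lung plastic regions get no water-to-tissue factor
  lung <- makePhantomPlane("lung", c(60, 60), 1)
  outL <- applyKmedMap(u, lung, kmedTable(), "Dmm")
  expect_identical(doseValues(outL), doseValues(u))
})

test_that("mode tailoring is multiplicatively consistent", {
  tb <- testTable()
  spine <- makePhantomPlane("spine", c(120, 120), 1)
  pd <- makePlannedDose(spine, caseDefinition("spine"))
  dmm <- applyKmedMap(pd, spine, tb, "Dmm")
  dww <- applyKmedMap(pd, spine, tb, "Dww")
  # ratio table (Dww/Dmm entries, water factor already applied once)
  f <- tb@factors
  ratio <- f[f$mode == "Dmm", ]
  for (i in seq_len(nrow(ratio)))
    ratio$factor[i] <- f$factor[f$material == ratio$material[i] &
                                  f$mode == "Dww"] / ratio$factor[i]
  ratio2 <- ratio; ratio2$mode <- "Dww"
  tbRatio <- kmedTable(rbind(ratio, ratio2), waterToTissue = 1)
  via <- applyKmedMap(dmm, spine, tbRatio, "Dmm")
  expect_equal(doseValues(via), doseValues(dww), tolerance = 1e-12)
})

test_that("generator-embedded factors are recovered exactly", {
  tb <- testTable()
  spine <- makePhantomPlane("spine", c(120, 120), 1)
  pd <- makePlannedDose(spine, caseDefinition("spine"))
  embedded <- applyKmedMap(pd, spine, tb, "Dmm", invert = TRUE)
  restored <- applyKmedMap(embedded, spine, tb, "Dmm")
  expect_equal(doseValues(restored), doseValues(pd), tolerance = 1e-12)
})

test_that("region locality: unity-factor pixels are untouched", {
  tb <- testTable()
  lung <- makePhantomPlane("lung", c(80, 80), 1)
  f <- tb@factors
  f$factor[f$material == "inhale_lung"] <- 1
  tb2 <- kmedTable(f, waterToTissue = 1)
  pd <- DosePlane(matrix(runif(6400, 1, 10), 80, 80), spacing = 1)
  out <- applyKmedMap(pd, lung, tb2, "Dmm")
  bg <- materialLabels(lung) == "inhale_lung"
  expect_identical(doseValues(out)[bg], doseValues(pd)[bg])
  expect_false(identical(doseValues(out)[!bg], doseValues(pd)[!bg]))
})

test_that("missing table entries are reported", {
  f <- kmedTable()@factors
  expect_error(kmedTable(f[f$material != "inhale_lung", ]),
               "both reporting modes")
  expect_error(kmedFactor(kmedTable(), "inhale_lung", "Dwm"), "no k_med")
})

test_that("point corrections multiply", {
  id <- pointCorrectionSet()
  expect_equal(correctPointReading(12.3, id), 12.3)
  soft <- pointCorrectionSet(kmed = 0.992)
  expect_equal(correctPointReading(15, soft), 14.88)
  pc <- pointCorrectionSet(1.02, 0.99, 0.97)
  expect_equal(pc@combined, 1.02 * 0.99 * 0.97, tolerance = 1e-12)
  expect_equal(correctPointReading(10, pc), 10 * 1.02 * 0.99 * 0.97)
  expect_error(correctPointReading(-1, pc), "positive")
})

test_that("k_med tables round trip through YAML", {
  tb <- testTable()
  p <- withr::local_tempfile(fileext = ".yaml")
  writeKmedYaml(tb, p)
  back <- readKmedYaml(p)
  expect_equal(back@waterToTissue, 0.992)
  for (m in c("cortical_bone", "lung_target"))
    for (mode in c("Dmm", "Dww"))
      expect_equal(kmedFactor(back, m, mode), kmedFactor(tb, m, mode))
})
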