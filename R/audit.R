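# End-to-end synthetic audit: plan generation, perturbed delivery, film
# chain, registration, medium corrections, metrics and scoring for one
# plan, plus cohort simulation.

# Simulate the two check films of a scanning session: uniform 10 and
# 15 Gy exposures rendered through the film chain and converted with the
# calibration (unscaled), against ideal chamber doses. `drift` emulates a
# global scanner response change between calibration and audit scan.
.simulateCheckFilms <- function(cal, filmModel, scanDelayHours, drift = 1,
                                seed = 1L) {
  doses <- c(10, 15)
  filmDose <- vapply(seq_along(doses), function(i) {
    plane <- DosePlane(matrix(doses[i], 8, 8), spacing = 2)
    scan <- renderFilmScan(plane, filmModel, scanDelayHours,
                           seed = seed + 11L * i)
    scan@netOD <- scan@netOD * drift
    idQC <- new("ScalingQC", scaleFactor = 1, withinLimit = TRUE,
                controlLimit = 0.05, residual = 0)
    mean(doseValues(scanToDose(scan, cal, idQC)), na.rm = TRUE)
  }, 0)
  checkFilmPair(chamberDose = doses, filmDose = filmDose)
}

#' Run one synthetic end-to-end audit
#'
#' Executes the full audit chain for one plan: digital phantom and
#' analytic planned dose; perturbed "delivered" dose; forward film model
#' (medium effects embedded through the reciprocal k_med map, film
#' response, darkening, scanner noise, film placement on the scanner);
#' film calibration, check-film QC and scan-to-dose conversion; dual
#' observer landmark registration back to the plan grid; tailored medium
#' corrections; gamma, DTA, point- and region-dose metrics and conformity
#' indices; tiered outcome classification and, for out-of-tolerance plans,
#' failure-mode tagging.
#'
#' @param caseId `"soft_tissue"`, `"spine"` or `"lung"`.
#' @param perturb a [PerturbationSpec-class] (identity by default).
#' @param seed integer master seed for the run's stochastic components
#'   (scanner noise, film placement, landmark entry); defaults to
#'   `perturb@seed`.
#' @param gridShape,spacing plan grid geometry.
#' @param reportingMode plan algorithm reporting mode (`"Dmm"`/`"Dww"`).
#' @param kmed a [KmedTable-class]; the generator embeds its reciprocal,
#'   the corrector removes it.
#' @param filmModel a [FilmForwardModel-class].
#' @param scanDelayHours audit-film scan delay (default 1.5x the
#'   calibration reference time, exercising the darkening correction).
#' @param calibration optional pre-fitted [CalibrationModel-class]
#'   (fitted fresh when NULL).
#' @param scannerDrift multiplicative scanner response drift applied to
#'   the audit session's scans; picked up by the check-film QC.
#' @param placement film-on-scanner [RigidTransform2D-class] (film-to-plan
#'   sense), or NULL for a small seeded default.
#' @param landmarkNoiseMm SD of the observers' landmark entry noise.
#' @param gamma optional [GammaParams-class] override.
#' @return An [AuditResult-class]; the full metric set is in
#'   `auditMetrics()`.
#' @export
#' @examples
#' \donttest{
#' res <- runAudit("soft_tissue", seed = 7)
#' auditOutcome(res)
#' auditMetrics(res)$gammaPassRate
#' }
runAudit <- function(caseId = .CASE_IDS, perturb = perturbationSpec(),
                     seed = perturb@seed, gridShape = c(200L, 200L),
                     spacing = 0.5, reportingMode = "Dmm",
                     kmed = kmedTable(), filmModel = filmForwardModel(),
                     scanDelayHours = 1.5 * filmModel@tRef,
                     calibration = NULL, scannerDrift = 1,
                     placement = NULL, landmarkNoiseMm = 0.05,
                     gamma = NULL) {
  caseId <- match.arg(caseId)
  case <- caseDefinition(caseId, reportingMode)
  plane <- makePhantomPlane(caseId, gridShape, spacing)
  dp <- prescriptionPerFraction(case)
  planned <- makePlannedDose(plane, case)
  ptv <- structureMask(plane, "PTV")

  delivered <- perturbDose(planned, perturb, ptvMask = ptv,
                           normalization = dp)

  # film records dose divided by the medium factors the correction restores
  filmDose <- applyKmedMap(delivered, plane, kmed, reportingMode,
                           invert = TRUE)

  # film placement on the scanner (film-frame = placement^-1 of plan-frame)
  if (is.null(placement))
    placement <- withSeed(seed, rigidTransform2D(
      rotationDeg = rnorm(1, 0, 1),
      translation = rnorm(2, 0, 1.5)), counter = 4L)
  filmFrameDose <- resampleToPlan(filmDose, invertTransform(placement),
                                  filmDose)
  v <- filmFrameDose@values; v[is.na(v)] <- 0  # off-film: unexposed
  filmFrameDose@values <- v

  scan <- renderFilmScan(filmFrameDose, filmModel, scanDelayHours,
                         seed = seed)
  scan@netOD <- scan@netOD * scannerDrift

  if (is.null(calibration))
    calibration <- fitCalibration(makeCalibrationDataset(filmModel),
                                  darkening = filmModel@darkening,
                                  tRef = filmModel@tRef)
  pair <- .simulateCheckFilms(calibration, filmModel, scanDelayHours,
                              drift = scannerDrift, seed = seed)
  qc <- checkFilmQC(pair)
  measuredFilm <- scanToDose(scan, calibration, qc,
                             plane = case@filmPlane)

  # dual-observer landmark registration film -> plan
  fid <- plane@fiducials
  filmFid <- applyTransform(invertTransform(placement), fid)
  obs <- lapply(1:2, function(k) withSeed(seed, {
    noisy <- filmFid + matrix(rnorm(length(fid), 0, landmarkNoiseMm),
                              nrow(fid), 2)
    fitRigid(landmarkSet(noisy, fid, paste0("obs", k)))
  }, counter = 5L + k))
  halfDiag <- sqrt(sum(((dim(v)[2:1] - 1) / 2 * spacing)^2))
  agree <- observerAgreement(obs[[1]], obs[[2]], extentMm = halfDiag)
  measuredPlan <- resampleToPlan(measuredFilm, obs[[1]], planned)

  corrected <- applyKmedMap(measuredPlan, plane, kmed, reportingMode)

  if (is.null(gamma)) gamma <- gammaParams(normalization = dp)
  gr <- gammaGlobal(planned, corrected, gamma)
  dta <- caseDTA(planned, corrected, case)

  # microDiamond point at the PTV centre: physical reading in medium,
  # restored by the point correction set
  pointFactor <- if (caseId == "soft_tissue") kmed@waterToTissue
                 else kmedFactor(kmed, materialLabels(plane)[
                   dim(v)[1] %/% 2 + 1, dim(v)[2] %/% 2 + 1], reportingMode)
  corrSet <- pointCorrectionSet(kmed = pointFactor)
  rawReading <- doseAt(delivered, 0, 0) / corrSet@combined
  pointMeasured <- correctPointReading(rawReading, corrSet)
  pointPlanned <- doseAt(planned, 0, 0)
  pt <- pointDoseDiff(pointPlanned, pointMeasured, dp)

  ptvStats <- regionDoseStats(planned, corrected, dp)
  outfieldMask <- planned@values < 0.5 * dp & planned@values > 0.05 * dp
  outStats <- regionDoseStats(planned, corrected, dp, mask = outfieldMask,
                              region = "outfield_mean")
  ci <- conformityIndices(planned, ptv, dp)

  metrics <- list(gammaPassRate = gr@passRate,
                  gammaNValid = gr@nValid,
                  dtaMeanLR = dta@meanLR, dtaMeanAP = dta@meanAP,
                  dtaMaxInterface = dta@maxAtInterface,
                  pointDiffPct = pt@local,
                  pointGlobalDiffPct = pt@global,
                  ptvGlobalDiffPct = ptvStats@global,
                  ptvLocalDiffPct = ptvStats@local,
                  outfieldGlobalDiffPct = outStats@global,
                  ci100 = unname(ci["CI100"]), ci50 = unname(ci["CI50"]),
                  qcScaleFactor = qc@scaleFactor,
                  calibrationResidual = calibration@residual,
                  observerMaxDiscrepancyMm = agree$maxDiscrepancyMm,
                  observersAgree = agree$agreed,
                  registrationRmsMm = obs[[1]]@rmsResidual,
                  injectedMode = perturb@injectedMode,
                  seed = as.numeric(seed))
  if (caseId == "spine") {
    cordStats <- regionDoseStats(planned, corrected, dp,
                                 mask = cordRoiMask(plane),
                                 region = "cord_ROI_mean")
    metrics$cordRoiLocalDiffPct <- cordStats@local
    metrics$cordRoiGlobalDiffPct <- cordStats@global
  }
  res <- classifyOutcome(metrics, scoringThresholds(caseId))
  res@injectedMode <- perturb@injectedMode
  res@seed <- as.numeric(seed)
  if (res@outcome == "out_of_tolerance")
    res <- classifyFailureMode(res)
  res
}

#' Simulate an audit cohort
#'
#' Runs [runAudit()] over `n` plans with per-plan seeds derived from the
#' cohort seed. A perturbation generator can inject failure modes into a
#' chosen fraction of plans; the injected ground truth is carried into
#' each result for agreement checking.
#'
#' @param n number of plans.
#' @param caseIds cases to cycle through.
#' @param perturbFn `function(i, caseId, seed)` returning a
#'   [PerturbationSpec-class], or NULL for unperturbed plans.
#' @param seed cohort master seed.
#' @param ... further arguments passed to [runAudit()].
#' @return List of [AuditResult-class] objects.
#' @export
simulateCohort <- function(n, caseIds = .CASE_IDS, perturbFn = NULL,
                           seed = 1L, ...) {
  cal <- NULL
  args <- list(...)
  if (is.null(args$filmModel)) args$filmModel <- filmForwardModel()
  if (is.null(args$calibration))
    args$calibration <- fitCalibration(
      makeCalibrationDataset(args$filmModel),
      darkening = args$filmModel@darkening, tRef = args$filmModel@tRef)
  lapply(seq_len(n), function(i) {
    cid <- caseIds[(i - 1L) %% length(caseIds) + 1L]
    si <- seed + 1000L * i
    sp <- if (is.null(perturbFn)) perturbationSpec(seed = si)
          else perturbFn(i, cid, si)
    do.call(runAudit, c(list(caseId = cid, perturb = sp, seed = si), args))
  })
}
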