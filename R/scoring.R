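# Tiered audit outcome classification and failure-mode tagging.
#
# Boundary semantics: the gamma bands use ">=" (95.0 is optimal, 90.0 is
# action); the DTA and point-dose upper limits use strict ">" (a value
# exactly at the limit passes). DTA limits are applied to the absolute
# value of the signed displacements.

.FAILURE_MODES <- c("IGRT mismatch",
                    "In-volume dose difference (low)",
                    "In-volume dose difference (high)",
                    "Other shift/misalignment",
                    "Out of field dose (high)",
                    "Fusion of structure set to planning CT",
                    "Dose calculation grid size",
                    "unclassified")

#' Audit scoring thresholds
#'
#' Defaults per case: gamma pass rate >= 95% optimal, 90-95% action,
#' < 90% out of tolerance; DTA upper limit 3.0 mm (soft tissue and lung)
#' or 2.0 mm (spine interface); point-dose difference upper limit 8%.
#'
#' @param caseId `"soft_tissue"`, `"spine"` or `"lung"`.
#' @return A [ScoringThresholds-class].
#' @export
scoringThresholds <- function(caseId = .CASE_IDS) {
  caseId <- match.arg(caseId)
  new("ScoringThresholds", caseId = caseId, gammaOptimal = 95,
      gammaAction = 90,
      dtaOotMm = if (caseId == "spine") 2.0 else 3.0,
      pointOotPct = 8.0)
}

# DTA values scored against the upper limit, per case
.scoredDta <- function(metrics, caseId) {
  switch(caseId,
    soft_tissue = c(meanLR = metrics$dtaMeanLR, meanAP = metrics$dtaMeanAP),
    spine = c(maxInterfaceAP = metrics$dtaMaxInterface,
              meanLRInterface = metrics$dtaMeanLR),
    lung = c(meanAP = metrics$dtaMeanAP))
}

#' Classify an audit outcome
#'
#' The gamma pass-rate band sets the base outcome; a breach of any DTA or
#' point-dose upper limit forces out-of-tolerance regardless of the gamma
#' result, with the triggering metrics listed.
#'
#' @param metrics named list of scored metrics; requires `gammaPassRate`,
#'   `pointDiffPct` and the case's DTA values (`dtaMeanLR`/`dtaMeanAP`
#'   for soft tissue, `dtaMaxInterface` and `dtaMeanLR` for spine,
#'   `dtaMeanAP` for lung). Further metrics are carried through.
#' @param thresholds a [ScoringThresholds-class]; defaults per case.
#' @param caseId case identifier (defaults to `thresholds@caseId`).
#' @return An [AuditResult-class] (failure mode untagged).
#' @export
#' @examples
#' m <- list(gammaPassRate = 96, dtaMeanLR = 0.2, dtaMeanAP = -0.1,
#'           pointDiffPct = 1.5)
#' auditOutcome(classifyOutcome(m, caseId = "soft_tissue"))
classifyOutcome <- function(metrics, thresholds = NULL, caseId = NULL) {
  if (is.null(caseId)) {
    if (is.null(thresholds)) stop("caseId or thresholds required")
    caseId <- thresholds@caseId
  }
  if (is.null(thresholds)) thresholds <- scoringThresholds(caseId)
  dtaNeed <- switch(caseId,
    soft_tissue = c("dtaMeanLR", "dtaMeanAP"),
    spine = c("dtaMaxInterface", "dtaMeanLR"),
    lung = "dtaMeanAP")
  need <- c("gammaPassRate", "pointDiffPct", dtaNeed)
  have <- vapply(need, function(nm)
    !is.null(metrics[[nm]]) && !is.na(metrics[[nm]]), TRUE)
  if (!all(have))
    stop("missing required metric(s) for case ", caseId, ": ",
         paste(need[!have], collapse = ", "))
  dta <- .scoredDta(metrics, caseId)
  triggers <- character()
  g <- metrics$gammaPassRate
  if (g < thresholds@gammaAction) triggers <- c(triggers, "gamma")
  bad <- abs(dta) > thresholds@dtaOotMm + 1e-12
  if (any(bad))
    triggers <- c(triggers, paste0("DTA_", names(dta)[bad]))
  if (abs(metrics$pointDiffPct) > thresholds@pointOotPct + 1e-12)
    triggers <- c(triggers, "point_dose")
  outcome <- if (length(triggers)) "out_of_tolerance"
             else if (g >= thresholds@gammaOptimal) "optimal"
             else "action"
  new("AuditResult", caseId = caseId, metrics = metrics,
      outcome = outcome, triggers = triggers, failureMode = "none",
      injectedMode = if (is.null(metrics$injectedMode)) "none"
                     else metrics$injectedMode,
      seed = if (is.null(metrics$seed)) NA_real_ else metrics$seed)
}

#' Rule-based failure-mode classification
#'
#' Operationalizes the post-audit failure analysis for out-of-tolerance
#' plans. Default rules, checked in order:
#' \itemize{
#'   \item mean |DTA| (or registration-recovered shift) at or beyond
#'     `shiftMm` (2 mm) with a consistent direction: "IGRT mismatch";
#'   \item a large rotation or an inconsistent shift: "Other
#'     shift/misalignment";
#'   \item mean in-PTV global difference beyond +-`involPct` (2.5%):
#'     "In-volume dose difference (low)" when planned exceeds measured
#'     (positive, under-delivery), "(high)" when measured exceeds planned;
#'   \item mean out-of-field global difference with the measurement
#'     exceeding the plan by more than `outfieldPct` (5%) of
#'     prescription: "Out of field dose (high)";
#'   \item otherwise "unclassified".
#' }
#' When the synthetic ground truth is known, agreement with the injected
#' mode is reported.
#'
#' @param result an out-of-tolerance [AuditResult-class] (classifying a
#'   passing plan is an error).
#' @param shiftMm,involPct,outfieldPct,rotationDeg rule thresholds.
#' @return The [AuditResult-class] with `failureMode` set and, when an
#'   injected mode exists, `metrics$failureModeMatchesInjected`.
#' @export
classifyFailureMode <- function(result, shiftMm = 2, involPct = 2.5,
                                outfieldPct = 5, rotationDeg = 1) {
  stopifnot(is(result, "AuditResult"))
  if (result@outcome != "out_of_tolerance")
    stop("failure-mode classification applies to out-of-tolerance plans only")
  m <- result@metrics
  val <- function(x) if (is.null(x) || is.na(x)) 0 else x
  dtaMag <- max(abs(val(m$dtaMeanLR)), abs(val(m$dtaMeanAP)),
                abs(val(m$dtaMaxInterface)))
  shift <- max(dtaMag, val(m$registrationShiftMm))
  mode <- if (shift >= shiftMm) {
    "IGRT mismatch"
  } else if (abs(val(m$rotationDeg)) > rotationDeg) {
    "Other shift/misalignment"
  } else if (val(m$ptvGlobalDiffPct) > involPct) {
    "In-volume dose difference (low)"
  } else if (val(m$ptvGlobalDiffPct) < -involPct) {
    "In-volume dose difference (high)"
  } else if (-val(m$outfieldGlobalDiffPct) > outfieldPct) {
    "Out of field dose (high)"
  } else "unclassified"
  result@failureMode <- mode
  if (result@injectedMode != "none")
    result@metrics$failureModeMatchesInjected <-
      identical(mode, result@injectedMode)
  result
}
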