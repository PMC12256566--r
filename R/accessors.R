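# Accessor methods and show() methods.

#' @rdname accessors
#' @export
setMethod("doseValues", "DosePlane", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("gridSpacing", "DosePlane", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("gridSpacing", "PhantomPlane", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("gridSpacing", "FilmScan", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("gridOrigin", "DosePlane", function(x) x@origin)

#' @rdname accessors
#' @export
setMethod("gridOrigin", "PhantomPlane", function(x) x@origin)

#' @rdname accessors
#' @export
setMethod("gridOrigin", "FilmScan", function(x) x@origin)

#' @rdname accessors
#' @export
setMethod("caseId", "PhantomPlane", function(x) x@caseId)

#' @rdname accessors
#' @export
setMethod("caseId", "CaseDefinition", function(x) x@caseId)

#' @rdname accessors
#' @export
setMethod("caseId", "AuditResult", function(x) x@caseId)

#' @rdname accessors
#' @export
setMethod("passRate", "GammaResult", function(x) x@passRate)

#' @rdname accessors
#' @export
setMethod("gammaMap", "GammaResult", function(x) x@gammaMap)

#' @rdname accessors
#' @export
setMethod("auditOutcome", "AuditResult", function(x) x@outcome)

#' @rdname accessors
#' @export
setMethod("failureMode", "AuditResult", function(x) x@failureMode)

#' @rdname accessors
#' @export
setMethod("auditMetrics", "AuditResult", function(x) x@metrics)

#' @rdname accessors
#' @export
setMethod("scaleFactor", "ScalingQC", function(x) x@scaleFactor)

#' @rdname accessors
#' @export
setMethod("withinLimit", "ScalingQC", function(x) x@withinLimit)

#' @rdname accessors
#' @export
setMethod("netOD", "FilmScan", function(x) x@netOD)

#' @rdname accessors
#' @export
setMethod("materialLabels", "PhantomPlane", function(x) {
  m <- x@materials
  matrix(m@levels[m@labels], nrow(m@labels), ncol(m@labels))
})

#' @rdname accessors
#' @param name structure name (e.g. `"PTV"`, `"cord_PRV"`, `"esophagus"`).
#' @export
setMethod("structureMask", "PhantomPlane", function(x, name) {
  if (!name %in% names(x@structures))
    stop("no structure named '", name, "'; available: ",
         paste(names(x@structures), collapse = ", "))
  x@structures[[name]]
})

#' @rdname accessors
#' @export
setMethod("fiducials", "PhantomPlane", function(x) x@fiducials)

setMethod("show", "DosePlane", function(object) {
  d <- dim(object@values)
  rng <- range(object@values, na.rm = TRUE)
  cat(sprintf("DosePlane %d x %d @ %.3g mm (%s)\n", d[1], d[2],
              object@spacing, object@plane))
  cat(sprintf("  dose range: %.3f - %.3f Gy; origin (%.2f, %.2f) mm; %d NA\n",
              rng[1], rng[2], object@origin[1], object@origin[2],
              sum(is.na(object@values))))
})

setMethod("show", "PhantomPlane", function(object) {
  d <- dim(object@materials@labels)
  cat(sprintf("PhantomPlane [%s] %d x %d @ %.3g mm\n", object@caseId,
              d[1], d[2], object@spacing))
  cat("  materials:", paste(object@materials@levels, collapse = ", "), "\n")
  cat("  structures:", paste(names(object@structures), collapse = ", "), "\n")
  cat(sprintf("  %d fiducials\n", nrow(object@fiducials)))
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel (form: %s)\n", object@form))
  cat(sprintf("  valid dose range %.1f - %.1f Gy; max level residual %.3f%%\n",
              object@doseRange[1], object@doseRange[2],
              100 * object@residual))
  cat(sprintf("  darkening c = (%.4f, %.4f, %.4f), tRef = %.1f h\n",
              object@darkening[1], object@darkening[2], object@darkening[3],
              object@tRef))
})

setMethod("show", "GammaResult", function(object) {
  cat(sprintf("GammaResult: pass rate %.2f%% over %d valid pixels\n",
              object@passRate, object@nValid))
})

setMethod("show", "RigidTransform2D", function(object) {
  cat(sprintf(
    "RigidTransform2D: rotation %.4f deg, translation (%.4f, %.4f) mm, rms %.4g mm\n",
    object@rotationDeg, object@translation[1], object@translation[2],
    object@rmsResidual))
})

setMethod("show", "AuditResult", function(object) {
  cat(sprintf("AuditResult [%s]: %s\n", object@caseId, object@outcome))
  m <- object@metrics
  if (!is.null(m$gammaPassRate))
    cat(sprintf("  gamma pass rate: %.2f%%\n", m$gammaPassRate))
  if (length(object@triggers))
    cat("  triggers:", paste(object@triggers, collapse = ", "), "\n")
  if (object@failureMode != "none")
    cat("  failure mode:", object@failureMode, "\n")
})

setMethod("show", "CohortSummary", function(object) {
  cat(sprintf("CohortSummary of %d plans\n", object@nTotal))
  print(object@outcomes)
  if (nrow(object@failureModes)) {
    cat("Failure modes:\n")
    print(object@failureModes)
  }
})
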