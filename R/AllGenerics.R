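#' Accessor generics
#'
#' Slot access for the pipeline classes goes through these accessors.
#'
#' @param x an object of one of the package's classes.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("doseValues", function(x) standardGeneric("doseValues"))

#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname accessors
#' @export
setGeneric("caseId", function(x) standardGeneric("caseId"))

#' @rdname accessors
#' @export
setGeneric("passRate", function(x) standardGeneric("passRate"))

#' @rdname accessors
#' @export
setGeneric("gammaMap", function(x) standardGeneric("gammaMap"))

#' @rdname accessors
#' @export
setGeneric("auditOutcome", function(x) standardGeneric("auditOutcome"))

#' @rdname accessors
#' @export
setGeneric("failureMode", function(x) standardGeneric("failureMode"))

#' @rdname accessors
#' @export
setGeneric("auditMetrics", function(x) standardGeneric("auditMetrics"))

#' @rdname accessors
#' @export
setGeneric("scaleFactor", function(x) standardGeneric("scaleFactor"))

#' @rdname accessors
#' @export
setGeneric("withinLimit", function(x) standardGeneric("withinLimit"))

#' @rdname accessors
#' @export
setGeneric("netOD", function(x) standardGeneric("netOD"))

#' @rdname accessors
#' @export
setGeneric("materialLabels", function(x) standardGeneric("materialLabels"))

#' @rdname accessors
#' @export
setGeneric("structureMask", function(x, name) standardGeneric("structureMask"))

#' @rdname accessors
#' @export
setGeneric("fiducials", function(x) standardGeneric("fiducials"))
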