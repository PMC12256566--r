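# 1D isodose distance-to-agreement between planned and measured dose
# profiles, including the spine cord-interface variant.

# All isodose-line crossings of a 1D profile, by linear interpolation
# between dense samples. Returns positions (mm) sorted along the profile.
.profileCrossings <- function(pos, dose, level) {
  ok <- !is.na(dose)
  pos <- pos[ok]; dose <- dose[ok]
  s <- dose - level
  idx <- which(s[-1] * s[-length(s)] < 0)
  cross <- pos[idx] + (pos[idx + 1] - pos[idx]) *
    (0 - s[idx]) / (s[idx + 1] - s[idx])
  exact <- pos[abs(s) < 1e-12]
  sort(unique(c(cross, exact)))
}

# Greedy proximity pairing of planned and measured crossings; unmatched
# crossings are dropped. Returns data.frame(planned, measured).
.pairCrossings <- function(planned, measured, maxSepMm = 10) {
  if (!length(planned) || !length(measured))
    return(data.frame(planned = numeric(), measured = numeric()))
  d <- abs(outer(planned, measured, "-"))
  pairs <- list()
  while (length(d) && min(d) <= maxSepMm) {
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    pairs[[length(pairs) + 1L]] <- c(planned[ij[1]], measured[ij[2]])
    d[ij[1], ] <- Inf; d[, ij[2]] <- Inf
    if (all(!is.finite(d))) break
  }
  if (!length(pairs))
    return(data.frame(planned = numeric(), measured = numeric()))
  m <- do.call(rbind, pairs)
  data.frame(planned = m[, 1], measured = m[, 2])
}

# Sample a plane along a horizontal (LR) or vertical (AP) line at a dense
# pitch (spacing/10).
.sampleProfile <- function(plane, axis, line) {
  cc <- gridCoords(dim(plane@values), plane@spacing, plane@origin)
  if (axis == "LR") {
    pos <- seq(min(cc$x), max(cc$x), by = plane@spacing / 10)
    dose <- doseAt(plane, pos, rep(line, length(pos)))
  } else {
    pos <- seq(min(cc$y), max(cc$y), by = plane@spacing / 10)
    dose <- doseAt(plane, rep(line, length(pos)), pos)
  }
  list(pos = pos, dose = dose)
}

#' 1D isodose distance-to-agreement along a profile
#'
#' Extracts planned and measured dose profiles along a horizontal (`LR`)
#' or vertical (`AP`) line, finds the crossings of the isodose level
#' (default 70% of the per-fraction prescription) by linear interpolation,
#' pairs planned and measured crossings by proximity, and reports the
#' signed displacement `planned - measured` per crossing together with the
#' axis mean.
#'
#' @param planned,measured congruent [DosePlane-class] objects.
#' @param axis `"LR"` (profile along x) or `"AP"` (along y).
#' @param normalization per-fraction prescription in Gy.
#' @param levelFraction isodose level, fraction of `normalization`
#'   (default 0.70).
#' @param line profile location in mm on the perpendicular axis.
#' @param window optional `(lo, hi)` mm range restricting crossing
#'   positions (used for the cord-interface variant).
#' @return A [DTAResult-class]; the mean for the requested axis is
#'   filled, the other is NA.
#' @export
profileDTA <- function(planned, measured, axis = c("LR", "AP"),
                       normalization, levelFraction = 0.70, line = 0,
                       window = NULL) {
  axis <- match.arg(axis)
  stopifnot(is(planned, "DosePlane"), is(measured, "DosePlane"))
  level <- levelFraction * normalization
  pp <- .sampleProfile(planned, axis, line)
  mp <- .sampleProfile(measured, axis, line)
  cp <- .profileCrossings(pp$pos, pp$dose, level)
  cm <- .profileCrossings(mp$pos, mp$dose, level)
  if (!is.null(window)) {
    cp <- cp[cp >= window[1] & cp <= window[2]]
    cm <- cm[cm >= window[1] & cm <= window[2]]
  }
  if (!length(cp) || !length(cm))
    stop(sprintf(
      "no %.0f%% isodose crossing on the %s profile at %.1f mm (%s)",
      100 * levelFraction, axis, line,
      if (!length(cp)) "planned" else "measured"))
  pairs <- .pairCrossings(cp, cm)
  edges <- data.frame(axis = axis, line_mm = line,
                      planned_mm = pairs$planned,
                      measured_mm = pairs$measured,
                      displacement_mm = pairs$planned - pairs$measured)
  new("DTAResult", edges = edges,
      meanLR = if (axis == "LR") mean(edges$displacement_mm) else NA_real_,
      meanAP = if (axis == "AP") mean(edges$displacement_mm) else NA_real_,
      maxAtInterface = NA_real_, isodoseLevel = levelFraction)
}

#' Case-specific DTA assessment
#'
#' Applies the per-case DTA protocol at the 70% isodose:
#' \describe{
#'   \item{soft_tissue}{mean DTA along the L-R and A-P profiles through
#'     the PTV centre.}
#'   \item{spine}{max |DTA| over A-P profiles sampled across the
#'     PTV/spinal-cord interface span, and mean L-R DTA at the same
#'     interface (crossings restricted to the trough).}
#'   \item{lung}{mean DTA along the A-P profile only (the film pin
#'     obstructs the 70% isodose in the L-R direction).}
#' }
#'
#' @param planned,measured congruent per-fraction [DosePlane-class]
#'   objects on the plan grid.
#' @param case a [CaseDefinition-class].
#' @param levelFraction isodose level, fraction of the per-fraction
#'   prescription.
#' @return A [DTAResult-class] with the case-relevant fields filled.
#' @export
caseDTA <- function(planned, measured, case, levelFraction = 0.70) {
  dp <- prescriptionPerFraction(case)
  if (case@caseId == "soft_tissue") {
    lr <- profileDTA(planned, measured, "LR", dp, levelFraction, 0)
    ap <- profileDTA(planned, measured, "AP", dp, levelFraction, 0)
    return(new("DTAResult", edges = rbind(lr@edges, ap@edges),
               meanLR = lr@meanLR, meanAP = ap@meanAP,
               maxAtInterface = NA_real_, isodoseLevel = levelFraction))
  }
  if (case@caseId == "lung") {
    ap <- profileDTA(planned, measured, "AP", dp, levelFraction, 0)
    return(ap)
  }
  # spine: trough crossings near the cord
  g <- .GEOM$spine
  win <- c(-1, 1) * (g$cord_prv_r + 7)
  span <- seq(-0.8 * g$cord_prv_r, 0.8 * g$cord_prv_r,
              by = planned@spacing)
  apEdges <- do.call(rbind, lapply(span, function(x) {
    r <- tryCatch(profileDTA(planned, measured, "AP", dp, levelFraction,
                             line = x, window = win),
                  error = function(e) NULL)
    if (is.null(r)) NULL else r@edges
  }))
  if (is.null(apEdges) || !nrow(apEdges))
    stop("no interface crossings found on the A-P profiles")
  lr <- profileDTA(planned, measured, "LR", dp, levelFraction, 0,
                   window = win)
  new("DTAResult", edges = rbind(apEdges, lr@edges),
      meanLR = lr@meanLR, meanAP = mean(apEdges$displacement_mm),
      maxAtInterface = max(abs(apEdges$displacement_mm)),
      isodoseLevel = levelFraction)
}
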