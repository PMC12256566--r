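# Point and region dose-difference metrics and conformity indices.
#
# Sign convention throughout: difference = planned - measured, expressed
# locally relative to the measured dose and globally relative to the
# per-fraction prescription.

#' Point dose difference
#'
#' Local difference `(planned - measured)/measured` and global difference
#' `(planned - measured)/prescription-per-fraction`, both in percent.
#'
#' @param plannedAtPoint planned dose at the detector point, Gy.
#' @param measuredCorrected corrected measured point dose, Gy (> 0).
#' @param prescriptionPerFraction per-fraction prescription, Gy.
#' @return A [DoseDiffResult-class] with `region = "point"`.
#' @export
#' @examples
#' d <- pointDoseDiff(10.5, 10.0, 15)
#' d@local   # +5.0 %
#' d@global  # +3.33 %
pointDoseDiff <- function(plannedAtPoint, measuredCorrected,
                          prescriptionPerFraction) {
  if (measuredCorrected <= 0) stop("measured dose must be positive")
  new("DoseDiffResult",
      local = 100 * (plannedAtPoint - measuredCorrected) /
        measuredCorrected,
      global = 100 * (plannedAtPoint - measuredCorrected) /
        prescriptionPerFraction,
      region = "point")
}

#' Mean dose difference over a region
#'
#' Mean local and global planned-minus-measured differences over a pixel
#' region. With `mask = NULL` the region defaults to the in-plane PTV,
#' defined as the area bound by the prescription isodose of the planned
#' plane.
#'
#' @param planned,measured congruent [DosePlane-class] objects.
#' @param prescriptionPerFraction per-fraction prescription, Gy.
#' @param mask logical matrix selecting the region, or `NULL` for the
#'   prescription-isodose PTV.
#' @param region region label carried in the result.
#' @return A [DoseDiffResult-class].
#' @export
regionDoseStats <- function(planned, measured, prescriptionPerFraction,
                            mask = NULL, region = "PTV_mean") {
  stopifnot(is(planned, "DosePlane"), is(measured, "DosePlane"))
  p <- planned@values; m <- measured@values
  if (is.null(mask)) mask <- p >= prescriptionPerFraction
  mask <- mask & !is.na(p) & !is.na(m)
  if (!any(mask)) stop("empty region: no pixels to average")
  pm <- p[mask]; mm <- m[mask]
  lo <- mm > 0.05 * prescriptionPerFraction  # local ratio needs dose
  new("DoseDiffResult",
      local = if (any(lo)) 100 * mean((pm[lo] - mm[lo]) / mm[lo])
              else NA_real_,
      global = 100 * mean(pm - mm) / prescriptionPerFraction,
      region = region)
}

#' Circular cord region-of-interest mask
#'
#' Disc of 6 mm diameter at the spinal-cord centre, the film surrogate
#' for the cord point dose.
#'
#' @param plane a [PhantomPlane-class] or [DosePlane-class] defining the
#'   grid.
#' @param centre cord centre in mm (default the plane origin centre,
#'   `(0, 0)`).
#' @param diameterMm ROI diameter, mm.
#' @return Logical matrix.
#' @export
cordRoiMask <- function(plane, centre = c(0, 0), diameterMm = 6) {
  dim <- if (is(plane, "DosePlane")) dim(plane@values)
         else dim(plane@materials@labels)
  radiusMap(dim, plane@spacing, plane@origin, centre) <= diameterMm / 2
}

#' Conformity indices on the film plane
#'
#' 2D surrogates of the volumetric conformity indices: the ratio of the
#' area enclosed by the 100% (50%) isodose to the PTV area.
#'
#' @param planned planned per-fraction [DosePlane-class].
#' @param ptvMask logical PTV matrix (non-empty).
#' @param prescriptionPerFraction per-fraction prescription, Gy.
#' @return Named numeric `c(CI100, CI50)`.
#' @export
#' @examples
#' pp <- makePhantomPlane("soft_tissue", c(120, 120), 1)
#' pd <- makePlannedDose(pp, caseDefinition("soft_tissue"))
#' conformityIndices(pd, structureMask(pp, "PTV"), 15)
conformityIndices <- function(planned, ptvMask, prescriptionPerFraction) {
  stopifnot(is(planned, "DosePlane"))
  if (!any(ptvMask)) stop("empty PTV mask")
  v <- planned@values
  aPTV <- sum(ptvMask)
  c(CI100 = sum(v >= prescriptionPerFraction, na.rm = TRUE) / aPTV,
    CI50 = sum(v >= 0.5 * prescriptionPerFraction, na.rm = TRUE) / aPTV)
}
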