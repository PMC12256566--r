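# Synthetic digital phantom: case definitions and phantom planes.
#
# Geometry is representative of a thorax audit phantom, not a replica of
# any physical device. Plane coordinates are mm with the target/cord centre
# at (0, 0); x is left-right (L-R), y is anterior-posterior (A-P).

# Fixed geometry constants (mm) of the synthetic phantom planes.
.GEOM <- list(
  soft_tissue = list(ptv_r = 12.5),
  spine = list(cord_prv_r = 5, canal_r = 6.5, trabecular_r = 14,
               cortical_r = 16, ptv_outer_r = 18,
               esoph_centre = c(0, 26), esoph_r = 4),
  lung = list(target_r = 10, ptv_r = 20)
)

# Default fiducial pin cut-out positions (mm); asymmetric so that flips
# cannot masquerade as rotations.
.FIDUCIALS <- rbind(c(-40, -40), c(40, -40), c(40, 40), c(-35, 35))

#' Audit case definitions
#'
#' Prescription, fractionation and plan constraint set for the three audit
#' cases: a 2.5 cm cylindrical soft-tissue target (45 Gy in 3 fractions,
#' prescription isodose covering >= 95% of the PTV), a wrap-around spine
#' target (24 Gy in 2 fractions, coverage >= 80%, spinal cord PRV 0.03 cc
#' max 14 Gy, esophagus 18 Gy) and a 2 cm lung sphere with a 1 cm margin
#' (48 Gy in 4 fractions, coverage >= 98%). All cases require the maximum
#' dose within 110-140% of prescription and conformity indices CI100 <= 1.2
#' and CI50 <= 5.0.
#'
#' @param caseId `"soft_tissue"`, `"spine"` or `"lung"`.
#' @param reportingMode dose-reporting mode of the plan algorithm,
#'   `"Dmm"` or `"Dww"`.
#' @return A [CaseDefinition-class].
#' @export
#' @examples
#' caseDefinition("spine")
caseDefinition <- function(caseId = .CASE_IDS, reportingMode = "Dmm") {
  caseId <- match.arg(caseId)
  oar0 <- data.frame(structure = character(), volume_cc = numeric(),
                     max_Gy = numeric())
  def <- switch(caseId,
    soft_tissue = list(total = 45, nfr = 3, cov = 0.95, oar = oar0,
                       film = "transverse", off = 0),
    spine = list(total = 24, nfr = 2, cov = 0.80,
                 oar = data.frame(structure = c("cord_PRV", "esophagus"),
                                  volume_cc = c(0.03, 0.03),
                                  max_Gy = c(14, 18)),
                 film = "transverse", off = 0),
    lung = list(total = 48, nfr = 4, cov = 0.98, oar = oar0,
                film = "coronal", off = 3))
  new("CaseDefinition", caseId = caseId, prescriptionTotal = def$total,
      nFractions = def$nfr, coverageRequirement = def$cov,
      maxDoseWindow = c(1.10, 1.40), ci100Limit = 1.2, ci50Limit = 5.0,
      oarLimits = def$oar, filmPlane = def$film, filmOffsetMm = def$off,
      reportingMode = reportingMode)
}

#' Per-fraction prescription dose
#'
#' All planes in the pipeline are single-fraction doses (the audit measures
#' one delivery), so metrics are normalized to
#' `prescriptionTotal / nFractions`.
#'
#' @param case a [CaseDefinition-class].
#' @return Per-fraction prescription dose in Gy.
#' @export
prescriptionPerFraction <- function(case) {
  case@prescriptionTotal / case@nFractions
}

#' Generate a digital phantom plane
#'
#' Builds the material-label mask, the anatomical structure masks and the
#' fiducial landmarks for the film plane of one audit case:
#' \describe{
#'   \item{soft_tissue}{uniform plastic water with a 2.5 cm diameter
#'     circular PTV cross-section.}
#'   \item{spine}{vertebral body with a cortical shell and trabecular
#'     interior, a plastic-water spinal canal, a circular cord PRV, the
#'     wrap-around PTV (vertebra + 2 mm margin, excluding the cord PRV) and
#'     an anterior esophagus disc.}
#'   \item{lung}{inhale-lung background with a 2 cm lung-target disc and
#'     the 4 cm PTV from the 1 cm isotropic margin.}
#' }
#'
#' @param caseId `"soft_tissue"`, `"spine"` or `"lung"`.
#' @param gridShape integer `(ny, nx)` grid dimensions.
#' @param spacing isotropic pixel spacing in mm, within `[0.1, 2]`.
#' @return A [PhantomPlane-class].
#' @export
#' @examples
#' pp <- makePhantomPlane("lung", c(120, 120), 1)
#' sum(structureMask(pp, "PTV")) * 1^2  # PTV area in mm^2
makePhantomPlane <- function(caseId = .CASE_IDS, gridShape = c(200L, 200L),
                             spacing = 0.5) {
  caseId <- match.arg(caseId)
  if (spacing < 0.1 || spacing > 2)
    stop("spacing must be within [0.1, 2] mm")
  dim <- as.integer(gridShape)
  origin <- centredOrigin(dim, spacing)
  r <- radiusMap(dim, spacing, origin)
  g <- .GEOM[[caseId]]
  lev <- .MATERIALS
  code <- function(nm) match(nm, lev)
  labels <- matrix(code("plastic_water"), dim[1], dim[2])
  structures <- list()
  if (caseId == "soft_tissue") {
    structures$PTV <- r <= g$ptv_r
  } else if (caseId == "spine") {
    labels[r <= g$cortical_r] <- code("cortical_bone")
    labels[r <= g$trabecular_r] <- code("trabecular_bone")
    labels[r <= g$canal_r] <- code("plastic_water")
    prv <- r <= g$cord_prv_r
    structures$PTV <- r <= g$ptv_outer_r & !prv
    structures$cord_PRV <- prv
    re <- radiusMap(dim, spacing, origin, g$esoph_centre)
    structures$esophagus <- re <= g$esoph_r
  } else {
    labels[] <- code("inhale_lung")
    labels[r <= g$target_r] <- code("lung_target")
    structures$PTV <- r <= g$ptv_r
    structures$GTV <- r <= g$target_r
  }
  mm <- new("MaterialMask", labels = labels, levels = lev,
            spacing = spacing, origin = origin)
  # keep fiducials inside the plane for small grids
  half <- (dim[2:1] - 1) / 2 * spacing
  fid <- .FIDUCIALS
  scale <- min(1, 0.9 * min(half) / max(abs(fid)))
  new("PhantomPlane", caseId = caseId, spacing = spacing, origin = origin,
      materials = mm, structures = structures, fiducials = fid * scale)
}
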