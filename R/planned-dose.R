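# Analytic planned-dose model.
#
# The planned per-fraction dose is a plateau multiplied by a logistic
# penumbra in distance from the target centre:
#
#   D(d) = A * Dp / (1 + exp((d - r0) / k))
#
# with A the maximum-dose factor (default 1.15 of the per-fraction
# prescription Dp), k set by the 80-20% penumbra width (default 3 mm,
# k = w / (2 log 4)), and r0 chosen so the prescription isodose sits at
# r100 = 1.03 * rPTV. The model is smooth and has closed-form isodose
# radii, which the tests exploit. The spine case multiplies in an angularly
# symmetric trough around the spinal cord,
#   T(d_cord) = tmin + (1 - tmin) / (1 + exp(-(d_cord - rc) / kc)),
# deep enough to respect the cord PRV maximum-dose limit while keeping
# PTV coverage above the case requirement.

.DOSE_MODEL <- list(maxFactor = 1.15, r100Factor = 1.03, penumbraMm = 3,
                    trough = list(tmin = 0.30, rc = 6, kc = 0.8))

# logistic slope parameter from an 80-20% penumbra width
.penumbraK <- function(widthMm) widthMm / (2 * log(4))

#' Closed-form isodose radius of the analytic dose model
#'
#' Radius (mm from the target centre) at which the planned dose model
#' crosses `level` times the per-fraction prescription, away from the
#' spine trough.
#'
#' @param level isodose level as a fraction of the per-fraction
#'   prescription (e.g. 1 for the prescription isodose, 0.5, 0.7).
#' @param ptvRadius PTV radius in mm.
#' @param maxFactor plateau maximum as a fraction of prescription.
#' @param penumbraMm 80-20% penumbra width in mm.
#' @return Isodose radius in mm.
#' @export
analyticIsodoseRadius <- function(level, ptvRadius,
                                  maxFactor = .DOSE_MODEL$maxFactor,
                                  penumbraMm = .DOSE_MODEL$penumbraMm) {
  if (level >= maxFactor) stop("level at or above the dose maximum")
  k <- .penumbraK(penumbraMm)
  r100 <- .DOSE_MODEL$r100Factor * ptvRadius
  r0 <- r100 - k * log(maxFactor - 1)  # s(r100) = 1/maxFactor
  r0 + k * log(maxFactor / level - 1)
}

#' Generate the planned per-fraction dose for an audit case
#'
#' Constructs the analytic planned dose on the phantom plane and verifies
#' the case's own plan constraints (PTV coverage, maximum-dose window,
#' conformity indices and OAR limits) with the metrics module; an
#' infeasible parameter combination raises an error naming the violated
#' constraint.
#'
#' @param plane a [PhantomPlane-class].
#' @param case the matching [CaseDefinition-class].
#' @param maxFactor plateau maximum as a fraction of the per-fraction
#'   prescription (within the case's maximum-dose window).
#' @param penumbraMm 80-20% penumbra width in mm.
#' @param check verify the constraint set (default TRUE).
#' @return A [DosePlane-class] of the per-fraction planned dose.
#' @export
#' @examples
#' pp <- makePhantomPlane("soft_tissue", c(120, 120), 1)
#' pd <- makePlannedDose(pp, caseDefinition("soft_tissue"))
#' max(doseValues(pd)) / (45 / 3)  # within the 110-140% window
makePlannedDose <- function(plane, case, maxFactor = .DOSE_MODEL$maxFactor,
                            penumbraMm = .DOSE_MODEL$penumbraMm,
                            check = TRUE) {
  stopifnot(is(plane, "PhantomPlane"), is(case, "CaseDefinition"))
  if (plane@caseId != case@caseId)
    stop("phantom plane and case definition disagree on the case id")
  dp <- prescriptionPerFraction(case)
  dim <- dim(plane@materials@labels)
  r <- radiusMap(dim, plane@spacing, plane@origin)
  k <- .penumbraK(penumbraMm)
  g <- .GEOM[[plane@caseId]]
  rP <- switch(plane@caseId, soft_tissue = g$ptv_r, lung = g$ptv_r,
               spine = g$ptv_outer_r)
  r100 <- .DOSE_MODEL$r100Factor * rP + if (plane@caseId == "spine") 0.5 else 0
  r0 <- r100 - k * log(maxFactor - 1)
  dose <- maxFactor * dp / (1 + exp((r - r0) / k))
  if (plane@caseId == "spine") {
    tr <- .DOSE_MODEL$trough
    dose <- dose * (tr$tmin + (1 - tr$tmin) /
                      (1 + exp(-(r - tr$rc) / tr$kc)))
  }
  planned <- DosePlane(dose, spacing = plane@spacing, origin = plane@origin,
                       plane = case@filmPlane)
  if (check) {
    chk <- checkPlanConstraints(planned, plane, case)
    bad <- names(chk)[!vapply(chk, `[[`, TRUE, "ok")]
    if (length(bad))
      stop("planned dose violates constraint(s): ",
           paste(bad, collapse = ", "))
  }
  planned
}

#' Verify a planned dose against its case constraint set
#'
#' Checks, on the film plane, the PTV coverage at the prescription isodose,
#' the maximum-dose window, the conformity indices and the OAR
#' maximum-dose limits (2D surrogate: maximum over the structure's pixels
#' against the per-fraction share of the total-dose limit).
#'
#' @param planned a per-fraction [DosePlane-class].
#' @param plane the [PhantomPlane-class] carrying the structure masks.
#' @param case the [CaseDefinition-class].
#' @return Named list of checks, each `list(ok = , value = , limit = )`.
#' @export
checkPlanConstraints <- function(planned, plane, case) {
  dp <- prescriptionPerFraction(case)
  v <- planned@values
  ptv <- structureMask(plane, "PTV")
  out <- list()
  cov <- mean(v[ptv] >= dp)
  out$coverage <- list(ok = cov >= case@coverageRequirement, value = cov,
                       limit = case@coverageRequirement)
  mx <- max(v, na.rm = TRUE) / dp
  out$max_dose <- list(ok = mx >= case@maxDoseWindow[1] &&
                         mx <= case@maxDoseWindow[2],
                       value = mx, limit = case@maxDoseWindow)
  ci <- conformityIndices(planned, ptv, dp)
  out$ci100 <- list(ok = ci[["CI100"]] <= case@ci100Limit,
                    value = ci[["CI100"]], limit = case@ci100Limit)
  out$ci50 <- list(ok = ci[["CI50"]] <= case@ci50Limit,
                   value = ci[["CI50"]], limit = case@ci50Limit)
  if (nrow(case@oarLimits)) {
    for (i in seq_len(nrow(case@oarLimits))) {
      st <- case@oarLimits$structure[i]
      lim <- case@oarLimits$max_Gy[i] / case@nFractions
      val <- max(v[structureMask(plane, st)], na.rm = TRUE)
      out[[paste0("oar_", st)]] <- list(ok = val <= lim, value = val,
                                        limit = lim)
    }
  }
  out
}
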