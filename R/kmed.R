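# Medium-dependent (k_med) corrections for film dose maps and scalar
# corrections for point-detector readings, tailored to the plan
# algorithm's dose-reporting mode (Dm,m or Dw,w). Dw,m reporting is
# unsupported by design.

#' Medium correction factor table
#'
#' Constructor for [KmedTable-class]. The shipped defaults are documented
#' placeholders: 1.0 for every (material, mode) pair, with the
#' water-to-tissue factor 0.992 for plastic-water film regions. Real use
#' requires a user-supplied table of measured or Monte-Carlo derived
#' factors; synthetic tests embed known non-unity values so the
#' correction arithmetic is testable regardless.
#'
#' @param factors data.frame with columns `material`, `mode`, `factor`,
#'   `provenance`; defaults to the placeholder table.
#' @param waterToTissue water-to-tissue correction factor for
#'   plastic-water regions (default 0.992).
#' @return A [KmedTable-class].
#' @export
#' @examples
#' kmedTable()  # placeholder defaults
kmedTable <- function(factors = NULL, waterToTissue = 0.992) {
  if (is.null(factors)) {
    factors <- expand.grid(material = .MATERIALS, mode = .REPORTING_MODES,
                           stringsAsFactors = FALSE)
    factors$factor <- 1
    factors$provenance <- "placeholder unity factor; supply measured values"
  }
  new("KmedTable", factors = factors, waterToTissue = waterToTissue)
}

#' Read/write a k_med table as YAML
#'
#' Layout: top-level `water_to_tissue` plus one block per material with
#' `Dmm`/`Dww` sub-blocks holding `factor` and `provenance`.
#'
#' @param table a [KmedTable-class].
#' @param path YAML file path.
#' @return `readKmedYaml` returns a [KmedTable-class].
#' @export
writeKmedYaml <- function(table, path) {
  out <- list(water_to_tissue = table@waterToTissue)
  for (m in unique(table@factors$material)) {
    sub <- table@factors[table@factors$material == m, ]
    out[[m]] <- setNames(lapply(seq_len(nrow(sub)), function(i)
      list(factor = sub$factor[i], provenance = sub$provenance[i])),
      sub$mode)
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname writeKmedYaml
#' @export
readKmedYaml <- function(path) {
  y <- yaml::read_yaml(path)
  wt <- y$water_to_tissue
  y$water_to_tissue <- NULL
  rows <- do.call(rbind, lapply(names(y), function(m)
    do.call(rbind, lapply(names(y[[m]]), function(mode)
      data.frame(material = m, mode = mode,
                 factor = y[[m]][[mode]]$factor,
                 provenance = y[[m]][[mode]]$provenance)))))
  kmedTable(rows, wt)
}

#' Look up a k_med factor
#'
#' @param table a [KmedTable-class].
#' @param material material label.
#' @param mode reporting mode, `"Dmm"` or `"Dww"`.
#' @return The correction factor.
#' @export
kmedFactor <- function(table, material, mode) {
  hit <- table@factors$material == material & table@factors$mode == mode
  if (!any(hit))
    stop("no k_med entry for (", material, ", ", mode, ")")
  table@factors$factor[hit][1]
}

#' Per-pixel correction factor map
#'
#' The factor applied to each film pixel: the (material, mode) k_med
#' factor, with plastic-water pixels additionally receiving the
#' water-to-tissue factor in the cases whose film lies in plastic water
#' (soft tissue and spine; the lung film plane gets no water-to-tissue
#' factor).
#'
#' @param plane a [PhantomPlane-class] (provides the material mask and the
#'   case id).
#' @param table a [KmedTable-class].
#' @param mode reporting mode, `"Dmm"` or `"Dww"`.
#' @return Numeric matrix of per-pixel factors.
#' @export
kmedFactorMap <- function(plane, table, mode = c("Dmm", "Dww")) {
  mode <- match.arg(mode)
  mm <- plane@materials
  present <- mm@levels[sort(unique(as.vector(mm@labels)))]
  fac <- vapply(mm@levels, function(m) {
    if (m %in% present) kmedFactor(table, m, mode) else 1
  }, 0)
  out <- matrix(fac[as.vector(mm@labels)], nrow(mm@labels), ncol(mm@labels))
  if (plane@caseId %in% c("soft_tissue", "spine")) {
    pw <- mm@labels == match("plastic_water", mm@levels)
    out[pw] <- out[pw] * table@waterToTissue
  }
  out
}

#' Apply the spatial medium correction to a film dose map
#'
#' Per-pixel multiplication of the dose by the (material, reporting-mode)
#' correction factor. Pixels whose factor is 1 are bit-identical before
#' and after. With `invert = TRUE` the reciprocal map is applied, which
#' the synthetic generator uses to embed the medium effect that the
#' correction then removes exactly.
#'
#' @param dose a [DosePlane-class] congruent with the mask grid.
#' @param plane the [PhantomPlane-class] carrying the material mask.
#' @param table a [KmedTable-class]; must cover every label present.
#' @param mode reporting mode, `"Dmm"` or `"Dww"`.
#' @param invert apply the reciprocal factors.
#' @return A corrected [DosePlane-class].
#' @export
applyKmedMap <- function(dose, plane, table, mode = c("Dmm", "Dww"),
                         invert = FALSE) {
  stopifnot(is(dose, "DosePlane"), is(plane, "PhantomPlane"))
  mode <- match.arg(mode)
  if (!all(dim(dose@values) == dim(plane@materials@labels)))
    stop("dose grid and material mask are not congruent")
  fac <- kmedFactorMap(plane, table, mode)
  v <- if (invert) dose@values / fac else dose@values * fac
  DosePlane(v, spacing = dose@spacing, origin = dose@origin,
            plane = dose@plane)
}

#' Point-detector correction set
#'
#' @param crossCalibration cross-calibration factor against the reference
#'   chamber.
#' @param orientation detector-orientation factor.
#' @param kmed material (or water-to-tissue) correction factor.
#' @return A [PointCorrectionSet-class]; the combined factor is the
#'   product of the components.
#' @export
#' @examples
#' pointCorrectionSet(kmed = 0.992)  # soft-tissue microDiamond point
pointCorrectionSet <- function(crossCalibration = 1, orientation = 1,
                               kmed = 1) {
  new("PointCorrectionSet", crossCalibration = crossCalibration,
      orientation = orientation, kmed = kmed,
      combined = crossCalibration * orientation * kmed)
}

#' Correct a point-detector reading
#'
#' @param rawReading uncorrected detector reading in Gy (> 0).
#' @param corrections a [PointCorrectionSet-class].
#' @return Corrected dose in Gy (`rawReading * combined`).
#' @export
correctPointReading <- function(rawReading, corrections) {
  stopifnot(is(corrections, "PointCorrectionSet"))
  if (any(rawReading <= 0)) stop("rawReading must be positive")
  rawReading * corrections@combined
}
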