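#' Class definitions for the SBRT audit pipeline
#'
#' The pipeline's universal currency is the [DosePlane-class]: a 2D dose
#' grid in Gy with isotropic pixel spacing and pixel-centre origin, both in
#' mm. All other objects (phantom planes, film scans, masks) share the same
#' grid convention: matrix rows index the y axis (anterior-posterior),
#' columns the x axis (left-right).
#'
#' @name sbrtaudit-classes
#' @keywords internal
NULL

#' 2D dose plane
#'
#' A planar dose distribution in Gy. `values[i, j]` is the dose at
#' `y = origin[2] + (i-1)*spacing`, `x = origin[1] + (j-1)*spacing` (mm,
#' pixel centres).
#'
#' @slot values numeric matrix of doses in Gy (NA marks invalid pixels).
#' @slot spacing isotropic pixel spacing in mm.
#' @slot origin mm coordinates `(x, y)` of the first pixel centre.
#' @slot plane orientation label, `"transverse"` or `"coronal"`.
#' @exportClass DosePlane
setClass("DosePlane",
  representation(values = "matrix", spacing = "numeric", origin = "numeric",
                 plane = "character"),
  prototype(plane = "transverse"),
  validity = function(object) {
    msg <- character()
    if (length(object@spacing) != 1 || !is.finite(object@spacing) ||
        object@spacing <= 0)
      msg <- c(msg, "spacing must be a single positive number")
    if (length(object@origin) != 2 || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be two finite mm coordinates")
    if (!is.numeric(object@values))
      msg <- c(msg, "values must be a numeric matrix")
    if (any(object@values < -1e-9, na.rm = TRUE))
      msg <- c(msg, "doses must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Per-pixel material labels
#'
#' Integer-coded material labels on a dose grid; `levels` maps codes to the
#' phantom material names.
#'
#' @slot labels integer matrix of codes into `levels`.
#' @slot levels character vector of material names.
#' @slot spacing,origin grid geometry as in [DosePlane-class].
#' @exportClass MaterialMask
setClass("MaterialMask",
  representation(labels = "matrix", levels = "character",
                 spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(object@levels %in% .MATERIALS))
      msg <- c(msg, sprintf("material levels must be drawn from: %s",
                            paste(.MATERIALS, collapse = ", ")))
    codes <- unique(as.vector(object@labels))
    if (any(!codes %in% seq_along(object@levels)))
      msg <- c(msg, "label codes outside the level dictionary")
    if (length(msg)) msg else TRUE
  })

#' Digital phantom plane
#'
#' Geometry of the audit phantom in the film plane: material labels,
#' anatomical structure masks (PTV, cord PRV, esophagus, ...) and fiducial
#' landmark positions used for film registration.
#'
#' @slot caseId one of `"soft_tissue"`, `"spine"`, `"lung"`.
#' @slot spacing,origin grid geometry (mm).
#' @slot materials a [MaterialMask-class].
#' @slot structures named list of logical matrices on the same grid.
#' @slot fiducials n x 2 matrix of landmark mm coordinates (n >= 3).
#' @exportClass PhantomPlane
setClass("PhantomPlane",
  representation(caseId = "character", spacing = "numeric",
                 origin = "numeric", materials = "MaterialMask",
                 structures = "list", fiducials = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!object@caseId %in% .CASE_IDS)
      msg <- c(msg, "unknown case id")
    if (object@spacing <= 0) msg <- c(msg, "spacing must be positive")
    if (nrow(object@fiducials) < 3)
      msg <- c(msg, "at least 3 fiducials required")
    if (nrow(object@fiducials) >= 3) {
      p <- object@fiducials
      # collinear if all cross products with the first edge are ~0
      v1 <- p[2, ] - p[1, ]
      cr <- (p[-1, 1, drop = TRUE] - p[1, 1]) * v1[2] -
        (p[-1, 2, drop = TRUE] - p[1, 2]) * v1[1]
      if (all(abs(cr) < 1e-9)) msg <- c(msg, "fiducials are collinear")
    }
    if (length(msg)) msg else TRUE
  })

#' Audit case definition
#'
#' Prescription, fractionation, plan constraint set and film-plane layout
#' for one of the three audit cases.
#'
#' @slot caseId case identifier.
#' @slot prescriptionTotal total prescription dose in Gy.
#' @slot nFractions number of fractions.
#' @slot coverageRequirement minimum fraction of the PTV covered by the
#'   prescription isodose.
#' @slot maxDoseWindow allowed `(low, high)` maximum dose as a fraction of
#'   prescription.
#' @slot ci100Limit,ci50Limit upper limits on the conformity indices.
#' @slot oarLimits data.frame with columns `structure`, `volume_cc`,
#'   `max_Gy` (total dose limits).
#' @slot filmPlane `"transverse"` or `"coronal"`.
#' @slot filmOffsetMm film-plane offset from the PTV centre, mm.
#' @slot reportingMode `"Dmm"` (dose-to-medium) or `"Dww"` (dose-to-water).
#' @exportClass CaseDefinition
setClass("CaseDefinition",
  representation(caseId = "character", prescriptionTotal = "numeric",
                 nFractions = "numeric", coverageRequirement = "numeric",
                 maxDoseWindow = "numeric", ci100Limit = "numeric",
                 ci50Limit = "numeric", oarLimits = "data.frame",
                 filmPlane = "character", filmOffsetMm = "numeric",
                 reportingMode = "character"),
  validity = function(object) {
    msg <- character()
    if (object@prescriptionTotal <= 0)
      msg <- c(msg, "prescription must be positive")
    if (object@nFractions < 1) msg <- c(msg, "nFractions must be >= 1")
    if (object@coverageRequirement <= 0 || object@coverageRequirement > 1)
      msg <- c(msg, "coverage requirement must be in (0, 1]")
    if (length(object@maxDoseWindow) != 2 ||
        object@maxDoseWindow[1] >= object@maxDoseWindow[2])
      msg <- c(msg, "max dose window must be (low, high) with low < high")
    if (!object@reportingMode %in% .REPORTING_MODES)
      msg <- c(msg, "reporting mode must be Dmm or Dww")
    if (length(msg)) msg else TRUE
  })

#' Delivery perturbation specification
#'
#' Parameterizes the error modes injected into a synthetic "delivered"
#' dose: rigid misalignment, dose scaling (global, in-PTV, out-of-field)
#' and noise. The identity spec leaves the plane untouched.
#'
#' @slot shift `(dx, dy)` translation in mm.
#' @slot rotation rotation about the plane centre, degrees.
#' @slot globalScale multiplicative scaling of the whole plane.
#' @slot infieldScale multiplicative scaling inside the PTV mask.
#' @slot outfieldScale multiplicative scaling outside the 50% isodose.
#' @slot noiseSigma Gaussian noise SD as a fraction of the per-fraction
#'   prescription.
#' @slot injectedMode ground-truth failure-mode label, or `"none"`.
#' @slot seed integer seed recorded in all outputs.
#' @exportClass PerturbationSpec
setClass("PerturbationSpec",
  representation(shift = "numeric", rotation = "numeric",
                 globalScale = "numeric", infieldScale = "numeric",
                 outfieldScale = "numeric", noiseSigma = "numeric",
                 injectedMode = "character", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(c(object@globalScale, object@infieldScale,
              object@outfieldScale) <= 0))
      msg <- c(msg, "scales must be positive")
    if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
    if (length(object@shift) != 2) msg <- c(msg, "shift must be (dx, dy)")
    if (length(msg)) msg else TRUE
  })

#' Forward film-response model
#'
#' Per-channel (R, G, B) saturating netOD response
#' `netOD(D) = a*D / (1 + b*D)`, a multiplicative darkening factor
#' `1 + c*log(t/tRef)` for post-irradiation time `t`, and Gaussian scanner
#' noise in netOD units. The calibration module shares the same family so
#' the film chain is invertible by construction.
#'
#' @slot a,b per-channel response parameters (length 3).
#' @slot darkening per-channel darkening coefficients `c` (length 3).
#' @slot tRef reference post-irradiation time, hours.
#' @slot noiseSigma scanner noise SD in netOD.
#' @exportClass FilmForwardModel
setClass("FilmForwardModel",
  representation(a = "numeric", b = "numeric", darkening = "numeric",
                 tRef = "numeric", noiseSigma = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@a) != 3 || length(object@b) != 3 ||
        length(object@darkening) != 3)
      msg <- c(msg, "a, b, darkening must have one entry per RGB channel")
    if (any(object@a <= 0) || any(object@b < 0))
      msg <- c(msg, "response must be strictly increasing on [0, 20] Gy")
    if (object@tRef <= 0) msg <- c(msg, "tRef must be positive")
    if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Simulated or scanned film
#'
#' Three-channel netOD grids with the grid geometry and the
#' post-irradiation scan delay.
#'
#' @slot netOD ny x nx x 3 array of net optical densities.
#' @slot spacing,origin grid geometry (mm).
#' @slot scanDelayHours post-irradiation time at scanning, hours.
#' @slot seed seed used for the scanner noise draw (NA for real scans).
#' @exportClass FilmScan
setClass("FilmScan",
  representation(netOD = "array", spacing = "numeric", origin = "numeric",
                 scanDelayHours = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@netOD)) != 3 || dim(object@netOD)[3] != 3)
      msg <- c(msg, "netOD must be an ny x nx x 3 array")
    if (object@scanDelayHours <= 0)
      msg <- c(msg, "scanDelayHours must be positive")
    if (length(msg)) msg else TRUE
  })

#' Film calibration dataset
#'
#' Dose levels (Gy) with per-channel netOD readings, nominally 12 levels
#' spanning 0-20 Gy including a zero-dose film.
#'
#' @slot dose delivered doses in Gy, strictly increasing, first is 0.
#' @slot netOD n x 3 matrix of per-channel netOD at each level.
#' @slot beam free-text beam metadata (field size, energy).
#' @exportClass CalibrationDataset
setClass("CalibrationDataset",
  representation(dose = "numeric", netOD = "matrix", beam = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@dose) < 5) msg <- c(msg, "at least 5 levels required")
    if (any(diff(object@dose) <= 0))
      msg <- c(msg, "doses must be strictly increasing")
    if (abs(object@dose[1]) > 1e-12)
      msg <- c(msg, "a zero-dose level is required")
    if (nrow(object@netOD) != length(object@dose) ||
        ncol(object@netOD) != 3)
      msg <- c(msg, "netOD must be length(dose) x 3")
    if (length(msg)) msg else TRUE
  })

#' Fitted film calibration model
#'
#' Per-channel dose(netOD) response with darkening-correction parameters.
#' The default `"rational"` form is `dose = netOD / (a - b*netOD)`; the
#' `"power"` form `dose = p1*netOD + p2*netOD^p3` is available through the
#' pluggable form registry.
#'
#' @slot form response form name (`"rational"` or `"power"`).
#' @slot params list of 3 per-channel parameter vectors.
#' @slot darkening per-channel darkening coefficients.
#' @slot tRef reference post-irradiation time, hours.
#' @slot residual maximum relative dose residual over the fitted levels.
#' @slot doseRange valid dose range `(lo, hi)` in Gy.
#' @exportClass CalibrationModel
setClass("CalibrationModel",
  representation(form = "character", params = "list",
                 darkening = "numeric", tRef = "numeric",
                 residual = "numeric", doseRange = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@params) != 3)
      msg <- c(msg, "one parameter vector per RGB channel required")
    if (length(object@doseRange) != 2 ||
        object@doseRange[1] >= object@doseRange[2])
      msg <- c(msg, "doseRange must be (lo, hi)")
    if (length(msg)) msg else TRUE
  })

#' Check-film pair
#'
#' Two films irradiated to chamber-verified control doses and co-scanned
#' with the audit films; anchors the calibration by a linear scale factor.
#'
#' @slot chamberDose chamber-measured doses, Gy (length 2).
#' @slot filmDose calibrated film doses, Gy (length 2).
#' @slot scanId identifier of the shared scanning session.
#' @exportClass CheckFilmPair
setClass("CheckFilmPair",
  representation(chamberDose = "numeric", filmDose = "numeric",
                 scanId = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@chamberDose) != 2 || length(object@filmDose) != 2)
      msg <- c(msg, "exactly two check films required")
    if (any(object@chamberDose <= 0) || any(object@filmDose <= 0))
      msg <- c(msg, "check-film doses must be positive")
    if (length(msg)) msg else TRUE
  })

#' Check-film linear-scaling QC result
#'
#' @slot scaleFactor through-origin factor mapping film doses onto chamber
#'   doses.
#' @slot withinLimit TRUE iff `|scaleFactor - 1| <= controlLimit`.
#' @slot controlLimit QC limit as a fraction (default 0.05).
#' @slot residual remaining relative mismatch after scaling.
#' @exportClass ScalingQC
setClass("ScalingQC",
  representation(scaleFactor = "numeric", withinLimit = "logical",
                 controlLimit = "numeric", residual = "numeric"),
  validity = function(object) {
    ok <- abs(object@scaleFactor - 1) <= object@controlLimit + 1e-12
    if (!identical(unname(object@withinLimit), unname(ok)))
      "withinLimit inconsistent with |scaleFactor - 1| vs controlLimit"
    else TRUE
  })

#' Registration landmark set
#'
#' Paired fiducial positions on the film plane and the planning grid for
#' one observer.
#'
#' @slot film n x 2 matrix of film-plane mm coordinates.
#' @slot plan n x 2 matrix of plan-grid mm coordinates.
#' @slot observer observer identifier.
#' @exportClass LandmarkSet
setClass("LandmarkSet",
  representation(film = "matrix", plan = "matrix", observer = "character"),
  validity = function(object) {
    msg <- character()
    n <- nrow(object@film)
    if (n < 3) msg <- c(msg, "at least 3 landmark pairs required")
    if (!all(dim(object@film) == dim(object@plan)))
      msg <- c(msg, "film and plan landmark matrices must match")
    if (n >= 3) {
      p <- object@film
      v1 <- p[2, ] - p[1, ]
      cr <- (p[-1, 1] - p[1, 1]) * v1[2] - (p[-1, 2] - p[1, 2]) * v1[1]
      if (all(abs(cr) < 1e-9)) msg <- c(msg, "film landmarks are collinear")
    }
    if (length(msg)) msg else TRUE
  })

#' 2D rigid transform
#'
#' Pure rotation + translation mapping film coordinates to plan
#' coordinates: `q = R(theta) p + t`.
#'
#' @slot rotationDeg rotation angle, degrees (counter-clockwise).
#' @slot translation `(dx, dy)` in mm.
#' @slot rmsResidual rms landmark residual after the fit, mm.
#' @exportClass RigidTransform2D
setClass("RigidTransform2D",
  representation(rotationDeg = "numeric", translation = "numeric",
                 rmsResidual = "numeric"),
  prototype(rmsResidual = 0),
  validity = function(object) {
    if (length(object@translation) != 2) "translation must be (dx, dy)"
    else TRUE
  })

#' Medium correction (k_med) table
#'
#' Multiplicative correction factors per (material, reporting mode), with a
#' provenance note per entry, plus the water-to-tissue factor applied to
#' plastic-water film regions where the case requires it.
#'
#' @slot factors data.frame with columns `material`, `mode`, `factor`,
#'   `provenance`.
#' @slot waterToTissue water-to-tissue factor for plastic-water regions
#'   (default 0.992).
#' @exportClass KmedTable
setClass("KmedTable",
  representation(factors = "data.frame", waterToTissue = "numeric"),
  validity = function(object) {
    msg <- character()
    need <- c("material", "mode", "factor", "provenance")
    if (!all(need %in% names(object@factors)))
      msg <- c(msg, "factors needs columns material, mode, factor, provenance")
    else {
      if (any(object@factors$factor < 0.8 | object@factors$factor > 1.2))
        msg <- c(msg, "k_med factors must lie in [0.8, 1.2]")
      have <- with(object@factors, paste(material, mode))
      want <- as.vector(outer(.MATERIALS, .REPORTING_MODES, paste))
      if (!all(want %in% have))
        msg <- c(msg, "every material needs an entry for both reporting modes")
    }
    if (object@waterToTissue < 0.8 || object@waterToTissue > 1.2)
      msg <- c(msg, "waterToTissue must lie in [0.8, 1.2]")
    if (length(msg)) msg else TRUE
  })

#' Point-detector correction set
#'
#' Scalar corrections applied to a point-detector (microDiamond) reading;
#' the combined factor is the product of the components.
#'
#' @slot crossCalibration cross-calibration factor against the reference
#'   chamber.
#' @slot orientation detector-orientation factor.
#' @slot kmed material correction factor.
#' @slot combined product of the components.
#' @exportClass PointCorrectionSet
setClass("PointCorrectionSet",
  representation(crossCalibration = "numeric", orientation = "numeric",
                 kmed = "numeric", combined = "numeric"),
  validity = function(object) {
    prod <- object@crossCalibration * object@orientation * object@kmed
    if (abs(prod - object@combined) > 1e-12)
      "combined factor must equal the product of its components"
    else TRUE
  })

#' Gamma-index analysis parameters
#'
#' Global gamma criteria: dose difference as a fraction of a fixed
#' normalization dose, distance-to-agreement in mm, and a low-dose
#' threshold below which measured pixels are not evaluated.
#'
#' @slot doseCriterion dose criterion as a fraction of `normalization`
#'   (default 0.05).
#' @slot dtaCriterion distance criterion in mm (default 2).
#' @slot threshold low-dose threshold as a fraction of `normalization`
#'   (default 0.10).
#' @slot normalization normalization dose in Gy (per-fraction
#'   prescription).
#' @slot searchRadiusFactor search radius in units of `dtaCriterion`
#'   (default 3).
#' @slot subsample requested sub-sampling pitch of the planned
#'   distribution, mm (default 0.2).
#' @exportClass GammaParams
setClass("GammaParams",
  representation(doseCriterion = "numeric", dtaCriterion = "numeric",
                 threshold = "numeric", normalization = "numeric",
                 searchRadiusFactor = "numeric", subsample = "numeric"),
  validity = function(object) {
    msg <- character()
    v <- c(object@doseCriterion, object@dtaCriterion, object@threshold,
           object@normalization, object@searchRadiusFactor, object@subsample)
    if (any(v <= 0)) msg <- c(msg, "all gamma parameters must be positive")
    if (object@threshold >= 1) msg <- c(msg, "threshold must be < 1")
    if (object@subsample > object@dtaCriterion / 2)
      msg <- c(msg, "subsample must not be coarser than dtaCriterion/2")
    if (length(msg)) msg else TRUE
  })

#' Gamma analysis result
#'
#' @slot gammaMap per-pixel gamma values; NA where below threshold, masked
#'   or where the search disc exits the planned grid.
#' @slot passRate percentage of valid pixels with gamma <= 1.
#' @slot nValid number of evaluated pixels.
#' @exportClass GammaResult
setClass("GammaResult",
  representation(gammaMap = "matrix", passRate = "numeric",
                 nValid = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@passRate < 0 || object@passRate > 100)
      msg <- c(msg, "passRate must be within [0, 100]")
    if (any(object@gammaMap < 0, na.rm = TRUE))
      msg <- c(msg, "gamma must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Isodose distance-to-agreement result
#'
#' Signed planned-minus-measured displacements of isodose-line crossings
#' along 1D profiles.
#'
#' @slot edges data.frame with one row per paired crossing: `axis`,
#'   `line_mm` (profile location), `planned_mm`, `measured_mm`,
#'   `displacement_mm`.
#' @slot meanLR,meanAP mean signed displacement per axis, mm (NA if the
#'   axis was not assessed).
#' @slot maxAtInterface maximum |displacement| over the interface profiles
#'   (spine variant), mm.
#' @slot isodoseLevel isodose level as a fraction of the per-fraction
#'   prescription (default 0.70).
#' @exportClass DTAResult
setClass("DTAResult",
  representation(edges = "data.frame", meanLR = "numeric",
                 meanAP = "numeric", maxAtInterface = "numeric",
                 isodoseLevel = "numeric"))

#' Dose-difference result
#'
#' Local difference `(planned - measured)/measured` and global difference
#' `(planned - measured)/prescription-per-fraction`, both in percent.
#'
#' @slot local local dose difference, %.
#' @slot global global dose difference, %.
#' @slot region `"point"`, `"PTV_mean"`, `"cord_ROI_mean"` or
#'   `"outfield_mean"`.
#' @exportClass DoseDiffResult
setClass("DoseDiffResult",
  representation(local = "numeric", global = "numeric",
                 region = "character"))

#' Audit scoring thresholds
#'
#' Tiered thresholds: the gamma pass rate sets the base outcome (optimal
#' at 95% and above, action 90-95%, out of tolerance below 90%); the DTA
#' and point-dose upper limits force an out-of-tolerance outcome when
#' breached.
#'
#' @slot caseId case the thresholds apply to.
#' @slot gammaOptimal optimal-level gamma pass rate, % (default 95).
#' @slot gammaAction action-level lower bound, % (default 90).
#' @slot dtaOotMm DTA upper limit, mm (3.0 soft tissue/lung, 2.0 spine
#'   interface); values strictly above fail.
#' @slot pointOotPct point-dose difference upper limit, % (8); values
#'   strictly above fail.
#' @exportClass ScoringThresholds
setClass("ScoringThresholds",
  representation(caseId = "character", gammaOptimal = "numeric",
                 gammaAction = "numeric", dtaOotMm = "numeric",
                 pointOotPct = "numeric"),
  validity = function(object) {
    if (!(object@gammaOptimal > object@gammaAction &&
          object@gammaAction > 0))
      "need gammaOptimal > gammaAction > 0"
    else TRUE
  })

#' Audit result for one plan
#'
#' All scored metrics plus the tiered outcome classification and, for
#' out-of-tolerance plans, the failure-mode tag.
#'
#' @slot caseId case identifier.
#' @slot metrics named list of computed metrics (gamma pass rate, DTA
#'   values, point and region dose differences, conformity indices).
#' @slot outcome `"optimal"`, `"action"` or `"out_of_tolerance"`.
#' @slot triggers metrics that forced an out-of-tolerance outcome.
#' @slot failureMode assigned failure-mode category, or `"none"`.
#' @slot injectedMode injected ground-truth mode for synthetic plans.
#' @slot seed seed of the synthetic plan (NA for measured data).
#' @exportClass AuditResult
setClass("AuditResult",
  representation(caseId = "character", metrics = "list",
                 outcome = "character", triggers = "character",
                 failureMode = "character", injectedMode = "character",
                 seed = "numeric"),
  prototype(failureMode = "none", injectedMode = "none", seed = NA_real_),
  validity = function(object) {
    if (!object@outcome %in% c("optimal", "action", "out_of_tolerance"))
      "outcome must be optimal, action or out_of_tolerance"
    else TRUE
  })

#' Cohort summary
#'
#' Aggregated audit results: per-case outcome tabulation, failure-mode
#' breakdown, per-metric summary statistics and any series comparisons.
#'
#' @slot outcomes data.frame of per-case outcome counts and percentages.
#' @slot failureModes data.frame of failure-mode counts and percentages.
#' @slot metrics data.frame of per-case metric summaries (mean, sd, median,
#'   quartiles).
#' @slot nTotal total number of plans.
#' @slot comparisons named list of two-sample t-test results.
#' @exportClass CohortSummary
setClass("CohortSummary",
  representation(outcomes = "data.frame", failureModes = "data.frame",
                 metrics = "data.frame", nTotal = "integer",
                 comparisons = "list"))
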