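# Film dosimetry: calibration-curve fitting, darkening correction,
# check-film linear-scaling QC and scan-to-dose conversion.

# --- pluggable calibration response forms ---------------------------------
# Each form provides fit(dose, netod) -> params and
# predict(params, netod) -> dose, with dose(0) = 0 and monotone dose(netOD)
# over the valid range.
.calForms <- new.env(parent = emptyenv())

#' Register a calibration response form
#'
#' The dose(netOD) response form is a pluggable interface; the package
#' ships `"rational"` (`dose = netOD/(a - b*netOD)`, the inverse of the
#' forward film model, fitted by exact linear least squares) and `"power"`
#' (`dose = p1*netOD + p2*netOD^p3`, fitted by relative least squares).
#'
#' @param name form name.
#' @param fit function `(dose, netod) -> params` for one channel.
#' @param predict function `(params, netod) -> dose`.
#' @return `name`, invisibly.
#' @export
registerCalibrationForm <- function(name, fit, predict) {
  assign(name, list(fit = fit, predict = predict), envir = .calForms)
  invisible(name)
}

registerCalibrationForm("rational",
  fit = function(dose, netod) {
    keep <- dose > 0
    D <- dose[keep]; x <- netod[keep]
    # x = a*D - b*(D*x): linear in (a, b)
    cf <- coef(lm(x ~ 0 + D + I(D * x)))
    c(a = unname(cf[1]), b = unname(-cf[2]))
  },
  predict = function(params, netod) {
    den <- params[["a"]] - params[["b"]] * netod
    ifelse(den > 0, netod / den, NA_real_)
  })

registerCalibrationForm("power",
  fit = function(dose, netod) {
    keep <- dose > 0
    D <- dose[keep]; x <- netod[keep]
    start <- list(p1 = D[1] / x[1], p2 = 5, p3 = 2.5)
    fit <- stats::nls(rep(1, length(D)) ~ (p1 * x + p2 * x^p3) / D,
                      start = start,
                      control = stats::nls.control(maxiter = 500,
                                                   warnOnly = TRUE))
    cf <- coef(fit)
    c(p1 = unname(cf[1]), p2 = unname(cf[2]), p3 = unname(cf[3]))
  },
  predict = function(params, netod) {
    params[["p1"]] * netod + params[["p2"]] * netod^params[["p3"]]
  })

# --- synthetic calibration data -------------------------------------------

# Default 12 calibration dose levels spanning 0-20 Gy.
.CAL_LEVELS <- c(0, 0.5, 1, 2, 3, 5, 7, 9, 11, 13, 16, 20)

#' Generate a synthetic calibration dataset
#'
#' Renders calibration-film netOD readings from the forward film model at
#' the reference scan time, with optional relative netOD noise.
#'
#' @param model a [FilmForwardModel-class].
#' @param dose calibration dose levels in Gy (default 12 levels, 0-20 Gy).
#' @param noise relative netOD noise SD (e.g. 0.005 for 0.5%).
#' @param seed integer seed for the noise draw.
#' @return A [CalibrationDataset-class].
#' @export
makeCalibrationDataset <- function(model = filmForwardModel(),
                                   dose = .CAL_LEVELS, noise = 0,
                                   seed = 1L) {
  od <- sapply(1:3, function(ch) filmNetOD(model, dose, ch))
  if (noise > 0)
    od <- withSeed(seed, od * (1 + matrix(rnorm(length(od), 0, noise),
                                          nrow(od), ncol(od))),
                   counter = 3L)
  new("CalibrationDataset", dose = dose, netOD = od,
      beam = "10x10 cm2, 6 MV (synthetic)")
}

#' Read/write a calibration dataset as CSV
#'
#' Columns: `dose_Gy`, `netOD_R`, `netOD_G`, `netOD_B`.
#'
#' @param data a [CalibrationDataset-class].
#' @param path CSV file path.
#' @return `readCalibrationCsv` returns a [CalibrationDataset-class].
#' @export
writeCalibrationCsv <- function(data, path) {
  df <- data.frame(dose_Gy = data@dose, netOD_R = data@netOD[, 1],
                   netOD_G = data@netOD[, 2], netOD_B = data@netOD[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCalibrationCsv
#' @export
readCalibrationCsv <- function(path) {
  df <- read.csv(path)
  new("CalibrationDataset", dose = df$dose_Gy,
      netOD = as.matrix(df[, c("netOD_R", "netOD_G", "netOD_B")]),
      beam = "unspecified")
}

# --- fitting ---------------------------------------------------------------

#' Fit the film calibration model
#'
#' Per-channel least-squares fit of the dose(netOD) response, with the
#' maximum relative dose residual over the calibration levels reported and
#' monotonicity verified on a dense netOD grid. Darkening-correction
#' coefficients are carried into the model so audit scans taken at other
#' post-irradiation times can be referred back to the calibration time.
#'
#' @param data a [CalibrationDataset-class].
#' @param form response form name (see [registerCalibrationForm()]).
#' @param darkening per-channel darkening coefficients.
#' @param tRef reference post-irradiation time, hours.
#' @param residualLimit maximum tolerated relative level residual
#'   (default 0.03); a worse fit raises a calibration-quality error.
#' @return A [CalibrationModel-class].
#' @export
#' @examples
#' cal <- fitCalibration(makeCalibrationDataset())
#' predictDose(cal, filmNetOD(filmForwardModel(), 10, 1), channel = 1)
fitCalibration <- function(data, form = "rational",
                           darkening = filmForwardModel()@darkening,
                           tRef = filmForwardModel()@tRef,
                           residualLimit = 0.03) {
  stopifnot(is(data, "CalibrationDataset"))
  if (any(apply(data@netOD, 2, function(x) any(diff(x) <= 0))))
    stop("calibration netOD must be strictly increasing with dose")
  f <- get0(form, envir = .calForms)
  if (is.null(f)) stop("unknown calibration form '", form, "'")
  params <- lapply(1:3, function(ch) f$fit(data@dose, data@netOD[, ch]))
  # residual over levels (dose terms, relative; zero level excluded)
  res <- max(vapply(1:3, function(ch) {
    pred <- f$predict(params[[ch]], data@netOD[-1, ch])
    max(abs(pred - data@dose[-1]) / data@dose[-1])
  }, 0))
  if (res > residualLimit)
    stop(sprintf(
      "calibration-quality error: max level residual %.2f%% exceeds %.0f%%",
      100 * res, 100 * residualLimit))
  # monotone dose(netOD) on a dense grid within the calibrated netOD range
  for (ch in 1:3) {
    xs <- seq(0, max(data@netOD[, ch]), length.out = 512)
    ds <- f$predict(params[[ch]], xs)
    if (any(!is.finite(ds)) || any(diff(ds) <= 0))
      stop("fitted response is not monotone over the valid range")
  }
  new("CalibrationModel", form = form, params = params,
      darkening = darkening, tRef = tRef, residual = res,
      doseRange = range(data@dose))
}

#' Predict dose from netOD
#'
#' @param model a [CalibrationModel-class].
#' @param netod netOD values (vector or matrix), already referred to the
#'   calibration scan time.
#' @param channel channel index 1-3.
#' @return Doses in Gy.
#' @export
predictDose <- function(model, netod, channel) {
  f <- get0(model@form, envir = .calForms)
  out <- f$predict(model@params[[channel]], netod)
  if (is.matrix(netod)) out <- matrix(out, nrow(netod), ncol(netod))
  out
}

# --- darkening correction --------------------------------------------------

#' Refer a netOD grid back to the reference scan time
#'
#' Inverts the dose-dependent darkening factor `1 + c*log(t/tRef)` so that
#' audit films scanned at `scanDelayHours` are compared against the
#' calibration established at `tRef`. The identity when
#' `scanDelayHours == tRef`. Delays outside the validated range
#' (tRef/4 to 10*tRef) are corrected but flagged with a warning.
#'
#' @param x a [FilmScan-class], or a single-channel netOD matrix.
#' @param model a [CalibrationModel-class] (or [FilmForwardModel-class])
#'   carrying the darkening coefficients and `tRef`.
#' @param scanDelayHours post-irradiation time of the scan; defaults to
#'   the scan's own metadata when `x` is a [FilmScan-class].
#' @param channel channel index, required when `x` is a matrix.
#' @return Same type as `x`, with netOD referred to `tRef` (for a
#'   [FilmScan-class], `scanDelayHours` is reset to `tRef`).
#' @export
applyDarkeningCorrection <- function(x, model,
                                     scanDelayHours = NULL,
                                     channel = NULL) {
  dark <- function(ch, t) 1 + model@darkening[ch] * log(t / model@tRef)
  checkRange <- function(t) {
    if (t <= 0) stop("scanDelayHours must be positive")
    if (t < model@tRef / 4 || t > 10 * model@tRef)
      warning("scan delay outside the validated darkening range")
  }
  if (is(x, "FilmScan")) {
    t <- if (is.null(scanDelayHours)) x@scanDelayHours else scanDelayHours
    checkRange(t)
    od <- x@netOD
    for (ch in 1:3) od[, , ch] <- od[, , ch] / dark(ch, t)
    return(new("FilmScan", netOD = od, spacing = x@spacing,
               origin = x@origin, scanDelayHours = model@tRef,
               seed = x@seed))
  }
  if (is.null(scanDelayHours) || is.null(channel))
    stop("matrix input requires scanDelayHours and channel")
  checkRange(scanDelayHours)
  x / dark(channel, scanDelayHours)
}

# --- check-film QC ---------------------------------------------------------

#' Check-film pair constructor
#'
#' @param chamberDose chamber-measured control doses in Gy (length 2;
#'   nominally 5 or 10, and 15 Gy).
#' @param filmDose calibrated film doses of the same films, Gy.
#' @param scanId identifier of the scan session shared with the audit
#'   films.
#' @return A [CheckFilmPair-class].
#' @export
checkFilmPair <- function(chamberDose, filmDose, scanId = "scan-1") {
  new("CheckFilmPair", chamberDose = chamberDose, filmDose = filmDose,
      scanId = scanId)
}

#' Check-film linear-scaling quality control
#'
#' Fits the single multiplicative factor (through-origin least squares
#' over both films jointly) that maps the calibrated film doses onto the
#' chamber doses, and tests it against the scaling control limit. The
#' limit is inclusive: a factor exactly at the boundary passes. A
#' through-origin residual above 2% flags the pair as internally
#' inconsistent (non-linear mismatch).
#'
#' @param pair a [CheckFilmPair-class].
#' @param limit control limit on `|factor - 1|` (default 0.05).
#' @return A [ScalingQC-class].
#' @export
#' @examples
#' qc <- checkFilmQC(checkFilmPair(c(10, 15), c(10.4, 15.6)))
#' scaleFactor(qc)  # 0.9615
checkFilmQC <- function(pair, limit = 0.05) {
  stopifnot(is(pair, "CheckFilmPair"))
  f <- sum(pair@filmDose * pair@chamberDose) / sum(pair@filmDose^2)
  resid <- max(abs(f * pair@filmDose - pair@chamberDose) /
                 pair@chamberDose)
  if (resid > 0.02)
    stop(sprintf(
      "inconsistent check films: %.1f%% residual after linear scaling",
      100 * resid))
  new("ScalingQC", scaleFactor = f,
      withinLimit = abs(f - 1) <= limit + 1e-12,
      controlLimit = limit, residual = resid)
}

# --- scan to dose ----------------------------------------------------------

#' Convert a film scan to absolute dose
#'
#' Applies the darkening correction, converts each channel to dose through
#' the calibration model, combines the channels (inverse-variance weighted
#' average by default, using the local slope of each channel's response;
#' red-only mode available) and applies the check-film scale factor. The
#' conversion refuses to run when the scaling QC is outside its control
#' limit ("rescan required"). Pixels outside the calibrated dose range are
#' masked NA.
#'
#' @param scan a [FilmScan-class] from the same session as `qc`.
#' @param model a [CalibrationModel-class].
#' @param qc a [ScalingQC-class] from [checkFilmQC()].
#' @param channels `"triple"` (default) or `"red"`.
#' @param plane orientation label for the output plane.
#' @return A [DosePlane-class] of absolute dose in Gy.
#' @export
scanToDose <- function(scan, model, qc, channels = c("triple", "red"),
                       plane = "transverse") {
  stopifnot(is(scan, "FilmScan"), is(model, "CalibrationModel"),
            is(qc, "ScalingQC"))
  channels <- match.arg(channels)
  if (!qc@withinLimit)
    stop(sprintf(
      "rescan required: check-film scaling %.1f%% outside the %.0f%% control limit",
      100 * abs(qc@scaleFactor - 1), 100 * qc@controlLimit))
  corrected <- applyDarkeningCorrection(scan, model)
  useCh <- if (channels == "red") 1L else 1:3
  doses <- lapply(useCh, function(ch)
    predictDose(model, corrected@netOD[, , ch], ch))
  if (length(useCh) == 1L) {
    dose <- doses[[1]]
  } else {
    # inverse-variance weights: scanner noise is per-channel-constant in
    # netOD, so var(dose) ~ (dDose/dnetOD)^2
    eps <- 1e-4
    wsum <- 0; dose <- 0
    for (k in seq_along(useCh)) {
      ch <- useCh[k]
      od <- corrected@netOD[, , ch]
      slope <- (predictDose(model, od + eps, ch) - doses[[k]]) / eps
      w <- 1 / pmax(slope, 1e-6)^2
      w[is.na(doses[[k]])] <- 0
      d0 <- doses[[k]]; d0[is.na(d0)] <- 0
      dose <- dose + w * d0
      wsum <- wsum + w
    }
    dose <- dose / wsum
    dose[wsum == 0] <- NA_real_
  }
  dose <- qc@scaleFactor * dose
  hi <- model@doseRange[2] * 1.05
  dose[!is.na(dose) & (dose < -1e-9 | dose > hi)] <- NA_real_
  dose[!is.na(dose) & dose < 0] <- 0
  DosePlane(dose, spacing = scan@spacing, origin = scan@origin,
            plane = plane)
}

# --- persistence -----------------------------------------------------------

#' Persist a calibration model as JSON
#'
#' @param model a [CalibrationModel-class].
#' @param path JSON file path.
#' @return `readCalibrationModel` returns a [CalibrationModel-class].
#' @export
writeCalibrationModel <- function(model, path) {
  jsonlite::write_json(
    list(form = model@form,
         params = setNames(lapply(model@params, as.list),
                           c("R", "G", "B")),
         darkening = model@darkening, tRef = model@tRef,
         residual = model@residual, doseRange = model@doseRange),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibrationModel
#' @export
readCalibrationModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- unname(lapply(j$params[c("R", "G", "B")], unlist))
  new("CalibrationModel", form = j$form, params = params,
      darkening = j$darkening, tRef = j$tRef, residual = j$residual,
      doseRange = j$doseRange)
}
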