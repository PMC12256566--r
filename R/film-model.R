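# Forward film-response model: dose -> netOD with time-dependent
# darkening and scanner noise. Shares its functional family with the
# calibration module, so the film chain is invertible by construction.

#' Forward film-response model
#'
#' Constructor for [FilmForwardModel-class]. Defaults emulate an EBT3-like
#' radiochromic film: a saturating per-channel response
#' `netOD(D) = a*D/(1 + b*D)` with the red channel most sensitive, slow
#' logarithmic post-irradiation darkening `1 + c*log(t/tRef)` referred to a
#' 24 h scan, and Gaussian scanner noise of 0.003 netOD.
#'
#' @param a,b per-channel (R, G, B) response parameters; `a` in 1/Gy.
#' @param darkening per-channel darkening coefficients `c`.
#' @param tRef reference post-irradiation time in hours.
#' @param noiseSigma scanner noise SD in netOD.
#' @return A [FilmForwardModel-class].
#' @export
#' @examples
#' m <- filmForwardModel()
#' filmNetOD(m, 10)  # netOD of a 10 Gy exposure at tRef
filmForwardModel <- function(a = c(0.085, 0.055, 0.030),
                             b = c(0.065, 0.035, 0.015),
                             darkening = c(0.018, 0.015, 0.012),
                             tRef = 24, noiseSigma = 0.003) {
  new("FilmForwardModel", a = a, b = b, darkening = darkening, tRef = tRef,
      noiseSigma = noiseSigma)
}

#' Evaluate the forward film response
#'
#' netOD of a dose at post-irradiation time `tHours`, per channel, without
#' noise. Strictly increasing in dose; `netOD(0) = 0`.
#'
#' @param model a [FilmForwardModel-class].
#' @param dose dose in Gy (vector or matrix).
#' @param channel channel index 1-3 (R, G, B) or `NULL` for all three.
#' @param tHours post-irradiation time, hours (default `tRef`).
#' @return netOD values; with `channel = NULL`, a list of three.
#' @export
filmNetOD <- function(model, dose, channel = NULL, tHours = model@tRef) {
  dark <- 1 + model@darkening * log(tHours / model@tRef)
  one <- function(ch) dark[ch] * model@a[ch] * dose / (1 + model@b[ch] * dose)
  if (is.null(channel)) lapply(1:3, one) else one(channel)
}

#' Render a synthetic film scan from a dose plane
#'
#' Forward-simulates the three-channel film scan of a delivered dose:
#' per-channel netOD from the response model, darkening for the scan
#' delay, and seeded Gaussian scanner noise. The result is invertible by
#' the film-dosimetry module within its stated tolerance.
#'
#' @param dose a [DosePlane-class] within the calibration range (0-20 Gy);
#'   doses above 20 Gy are rejected.
#' @param model a [FilmForwardModel-class].
#' @param scanDelayHours post-irradiation time at scanning, hours.
#' @param seed integer seed for the noise draw.
#' @return A [FilmScan-class].
#' @export
renderFilmScan <- function(dose, model = filmForwardModel(),
                           scanDelayHours = model@tRef, seed = 1L) {
  stopifnot(is(dose, "DosePlane"), is(model, "FilmForwardModel"))
  v <- dose@values
  if (any(v > 20 + 1e-9, na.rm = TRUE))
    stop("dose exceeds the 20 Gy calibration range")
  od <- array(0, c(nrow(v), ncol(v), 3))
  for (ch in 1:3)
    od[, , ch] <- filmNetOD(model, v, ch, scanDelayHours)
  if (model@noiseSigma > 0) {
    od <- withSeed(seed, {
      od + array(rnorm(length(od), 0, model@noiseSigma), dim(od))
    }, counter = 2L)
    od[od < 0] <- 0
  }
  new("FilmScan", netOD = od, spacing = dose@spacing, origin = dose@origin,
      scanDelayHours = scanDelayHours, seed = as.numeric(seed))
}

# Base (unexposed) optical densities used when serializing scans as
# transmission TIFFs.
.FILM_BASE_OD <- c(0.24, 0.21, 0.30)

#' Write/read a film scan as a 48-bit RGB TIFF
#'
#' The TIFF stores per-channel transmission `10^-(OD0 + netOD)` at 16 bits
#' per channel; grid geometry, scan delay and the base densities `OD0` go
#' to a JSON sidecar (`<path>.json`) so the scan round-trips exactly up to
#' 16-bit quantization.
#'
#' @param scan a [FilmScan-class].
#' @param path TIFF file path.
#' @return `readFilmTiff` returns a [FilmScan-class]; `writeFilmTiff`
#'   returns `path` invisibly.
#' @export
writeFilmTiff <- function(scan, path) {
  stopifnot(is(scan, "FilmScan"))
  tr <- scan@netOD
  for (ch in 1:3) tr[, , ch] <- 10^-(.FILM_BASE_OD[ch] + tr[, , ch])
  tiff::writeTIFF(tr, path, bits.per.sample = 16L)
  meta <- list(spacing_mm = scan@spacing, origin_mm = scan@origin,
               scan_delay_hours = scan@scanDelayHours,
               base_od = .FILM_BASE_OD, seed = scan@seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeFilmTiff
#' @export
readFilmTiff <- function(path) {
  tr <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  od <- tr
  for (ch in 1:3)
    od[, , ch] <- pmax(-log10(pmax(tr[, , ch], 1e-12)) - meta$base_od[ch], 0)
  new("FilmScan", netOD = od, spacing = meta$spacing_mm,
      origin = as.numeric(meta$origin_mm),
      scanDelayHours = meta$scan_delay_hours,
      seed = if (is.null(meta$seed)) NA_real_ else meta$seed)
}
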