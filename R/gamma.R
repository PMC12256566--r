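# Global 2D gamma-index analysis.
#
# Roles follow the audit convention: gamma is evaluated at measured-film
# pixels searching the planned distribution, and the low-dose threshold is
# applied to the measured dose (the audit scores the measurement). The
# dose term is global: differences are normalized to a fixed dose, the
# per-fraction prescription.

#' Gamma analysis parameters
#'
#' Audit defaults: 5% of the normalization dose, 2 mm DTA, 10% low-dose
#' threshold, search radius 3x DTA, planned distribution sub-sampled at
#' 0.2 mm.
#'
#' @param normalization normalization dose in Gy (per-fraction
#'   prescription).
#' @param doseCriterion dose criterion, fraction of `normalization`.
#' @param dtaCriterion distance criterion, mm.
#' @param threshold low-dose threshold, fraction of `normalization`.
#' @param searchRadiusFactor search radius in units of `dtaCriterion`.
#' @param subsample requested planned sub-sampling pitch, mm. The
#'   effective pitch is `spacing / ceiling(spacing / subsample)` so
#'   measured pixel centres lie on the sub-sampled lattice; it is never
#'   coarser than requested.
#' @return A [GammaParams-class].
#' @export
gammaParams <- function(normalization, doseCriterion = 0.05,
                        dtaCriterion = 2, threshold = 0.10,
                        searchRadiusFactor = 3, subsample = 0.2) {
  new("GammaParams", doseCriterion = doseCriterion,
      dtaCriterion = dtaCriterion, threshold = threshold,
      normalization = normalization,
      searchRadiusFactor = searchRadiusFactor, subsample = subsample)
}

# effective sub-pixel refinement factor and pitch for a grid spacing
.gammaPitch <- function(spacing, subsample) {
  k <- max(1L, as.integer(ceiling(spacing / subsample)))
  list(k = k, pitch = spacing / k)
}

# fine-pitch resampling of a plane by bilinear interpolation (vectorized)
.refinePlane <- function(v, spacing, origin, k) {
  if (k == 1L) return(v)
  dim <- dim(v)
  pitch <- spacing / k
  nxf <- (dim[2] - 1L) * k + 1L
  nyf <- (dim[1] - 1L) * k + 1L
  xf <- origin[1] + (seq_len(nxf) - 1) * pitch
  yf <- origin[2] + (seq_len(nyf) - 1) * pitch
  X <- matrix(xf, nyf, nxf, byrow = TRUE)
  Y <- matrix(yf, nyf, nxf)
  matrix(bilinear(v, as.vector(X), as.vector(Y), spacing, origin),
         nyf, nxf)
}

.checkCongruent <- function(planned, measured) {
  if (!all(dim(planned@values) == dim(measured@values)) ||
      abs(planned@spacing - measured@spacing) > 1e-9 ||
      any(abs(planned@origin - measured@origin) > 1e-6))
    stop("planned and measured grids are not congruent; register first")
}

#' Global 2D gamma analysis
#'
#' For each measured pixel at or above the low-dose threshold, the gamma
#' index is the minimum over planned positions within the search radius of
#' `sqrt((r/dta)^2 + (dDose/(doseCriterion*normalization))^2)`, with the
#' planned distribution bilinearly interpolated at the sub-sampling pitch.
#' Boundary pixels whose search disc exits the planned grid are marked
#' invalid (NA), not failed. The pass rate is the percentage of valid
#' pixels with gamma <= 1.
#'
#' @param planned planned [DosePlane-class], registered to the measured
#'   grid.
#' @param measured measured [DosePlane-class].
#' @param p a [GammaParams-class].
#' @return A [GammaResult-class].
#' @export
#' @examples
#' pl <- DosePlane(matrix(10, 41, 41), spacing = 1)
#' gammaGlobal(pl, pl, gammaParams(normalization = 10))
gammaGlobal <- function(planned, measured, p) {
  stopifnot(is(planned, "DosePlane"), is(measured, "DosePlane"),
            is(p, "GammaParams"))
  .checkCongruent(planned, measured)
  gp <- .gammaPitch(planned@spacing, p@subsample)
  fine <- .refinePlane(planned@values, planned@spacing, planned@origin,
                       gp$k)
  g <- gamma_engine_cpp(measured@values, fine, gp$k, gp$pitch,
                        p@dtaCriterion, p@doseCriterion * p@normalization,
                        p@threshold * p@normalization,
                        p@searchRadiusFactor * p@dtaCriterion)
  nValid <- sum(!is.na(g))
  if (nValid == 0L)
    stop("no valid pixels: empty region above the dose threshold")
  new("GammaResult", gammaMap = g,
      passRate = 100 * mean(g[!is.na(g)] <= 1 + 1e-9),
      nValid = as.integer(nValid))
}

#' Exhaustive gamma reference oracle
#'
#' Validation-only reference computation restricted to small grids
#' (<= 101 x 101): the same gamma definition evaluated by an exhaustive,
#' unpruned sweep over every node of the sub-sampled planned lattice,
#' implemented independently of the search engine (pure R, separable 1D
#' interpolation of the planned distribution). Used in tests to bound the
#' engine's per-pixel error.
#'
#' @inheritParams gammaGlobal
#' @return A [GammaResult-class].
#' @export
gammaOracle <- function(planned, measured, p) {
  stopifnot(is(planned, "DosePlane"), is(measured, "DosePlane"),
            is(p, "GammaParams"))
  .checkCongruent(planned, measured)
  dim <- dim(planned@values)
  if (any(dim > 101L)) stop("gammaOracle is restricted to grids <= 101x101")
  spacing <- planned@spacing
  gp <- .gammaPitch(spacing, p@subsample)
  k <- gp$k; pitch <- gp$pitch
  # independent fine-grid construction: two passes of 1D linear interpolation
  v <- planned@values
  nxf <- (dim[2] - 1L) * k + 1L
  nyf <- (dim[1] - 1L) * k + 1L
  xi <- seq_len(dim[2]); xf <- seq(1, dim[2], length.out = nxf)
  yi <- seq_len(dim[1]); yf <- seq(1, dim[1], length.out = nyf)
  tmp <- t(apply(v, 1, function(row) approx(xi, row, xout = xf)$y))
  fine <- apply(tmp, 2, function(col) approx(yi, col, xout = yf)$y)

  doseTol <- p@doseCriterion * p@normalization
  thr <- p@threshold * p@normalization
  R <- p@searchRadiusFactor * p@dtaCriterion
  # integer-lattice disc, the same candidate set as the search engine
  rmax <- floor(R / pitch + 1e-9)
  offs <- expand.grid(di = -rmax:rmax, dj = -rmax:rmax)
  offs <- offs[offs$di^2 + offs$dj^2 <= rmax^2, ]
  offs$rr <- (offs$di^2 + offs$dj^2) * pitch * pitch /
    (p@dtaCriterion * p@dtaCriterion)
  offs <- offs[order(offs$rr), ]

  M <- measured@values
  bi <- (seq_len(dim[1]) - 1L) * k + 1L  # fine row of each measured row
  bj <- (seq_len(dim[2]) - 1L) * k + 1L
  valid <- !is.na(M) & M >= thr
  # invalidate pixels whose search disc exits the fine grid
  inRow <- bi - rmax >= 1L & bi + rmax <= nyf
  inCol <- bj - rmax >= 1L & bj + rmax <= nxf
  valid <- valid & outer(inRow, inCol)
  best <- matrix(Inf, dim[1], dim[2])
  best[!valid] <- NA_real_
  rowIdx <- which(inRow); colIdx <- which(inCol)
  Msub <- M[rowIdx, colIdx, drop = FALSE]
  for (n in seq_len(nrow(offs))) {
    rr <- offs$rr[n]
    cur <- best[rowIdx, colIdx, drop = FALSE]
    if (rr >= max(cur[!is.na(cur)], 0)) break  # no pixel can improve
    Fsub <- fine[bi[rowIdx] + offs$di[n], bj[colIdx] + offs$dj[n],
                 drop = FALSE]
    cand <- rr + ((Msub - Fsub) / doseTol)^2
    best[rowIdx, colIdx] <- pmin(cur, cand)
  }
  g <- sqrt(best)
  nValid <- sum(!is.na(g))
  if (nValid == 0L)
    stop("no valid pixels: empty region above the dose threshold")
  new("GammaResult", gammaMap = g,
      passRate = 100 * mean(g[!is.na(g)] <= 1 + 1e-9),
      nValid = as.integer(nValid))
}
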