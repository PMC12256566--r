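#' Delivery perturbation specification
#'
#' Constructor for [PerturbationSpec-class]. The default is the identity
#' perturbation; each argument injects one delivery error mode. The seed
#' fixes the noise draw and is recorded in downstream outputs.
#'
#' @param shift `(dx, dy)` translation in mm.
#' @param rotation rotation about the plane centre in degrees.
#' @param globalScale global multiplicative dose scaling.
#' @param infieldScale multiplicative scaling inside the PTV mask.
#' @param outfieldScale multiplicative scaling outside the 50% isodose.
#' @param noiseSigma Gaussian noise SD, fraction of the per-fraction
#'   prescription.
#' @param injectedMode ground-truth failure-mode label (free text), or
#'   `"none"`; inferred from the dominant perturbation when missing.
#' @param seed integer seed.
#' @return A [PerturbationSpec-class].
#' @export
#' @examples
#' perturbationSpec(shift = c(3, 0), injectedMode = "IGRT mismatch")
perturbationSpec <- function(shift = c(0, 0), rotation = 0, globalScale = 1,
                             infieldScale = 1, outfieldScale = 1,
                             noiseSigma = 0, injectedMode = "none",
                             seed = 1L) {
  new("PerturbationSpec", shift = as.numeric(shift), rotation = rotation,
      globalScale = globalScale, infieldScale = infieldScale,
      outfieldScale = outfieldScale, noiseSigma = noiseSigma,
      injectedMode = injectedMode, seed = as.numeric(seed))
}

#' Apply a delivery perturbation to a planned dose
#'
#' Produces the synthetic "delivered" dose: rigid misalignment (rotation
#' about the plane centre, then translation) implemented by bilinear
#' resampling, followed by global, in-PTV and out-of-field dose scaling and
#' seeded Gaussian noise. The identity specification returns the input
#' plane unchanged, bit for bit. Deterministic given `spec@seed`.
#'
#' @param planned a [DosePlane-class] (finite, non-negative).
#' @param spec a [PerturbationSpec-class].
#' @param ptvMask logical matrix for `infieldScale` (required when it
#'   differs from 1).
#' @param normalization per-fraction prescription in Gy; required for
#'   `outfieldScale` (defines the 50% isodose) and for `noiseSigma`.
#' @return A [DosePlane-class] of the delivered dose.
#' @export
perturbDose <- function(planned, spec, ptvMask = NULL,
                        normalization = NULL) {
  stopifnot(is(planned, "DosePlane"), is(spec, "PerturbationSpec"))
  v <- planned@values
  if (any(!is.finite(v)) || any(v < 0))
    stop("planned dose must be finite and non-negative")
  fov <- (dim(v)[2:1] - 1) * planned@spacing
  if (any(abs(spec@shift) > 0.25 * fov))
    stop("shift exceeds 25% of the field of view")
  out <- v
  if (spec@rotation != 0 || any(spec@shift != 0)) {
    cc <- gridCoords(dim(v), planned@spacing, planned@origin)
    X <- matrix(cc$x, nrow(v), ncol(v), byrow = TRUE)
    Y <- matrix(cc$y, nrow(v), ncol(v))
    th <- spec@rotation * pi / 180
    # delivered(x) = planned(Rinv (x - shift)); rotation about grid centre
    ctr <- c(mean(range(cc$x)), mean(range(cc$y)))
    xs <- X - spec@shift[1] - ctr[1]
    ys <- Y - spec@shift[2] - ctr[2]
    xr <- cos(th) * xs + sin(th) * ys + ctr[1]
    yr <- -sin(th) * xs + cos(th) * ys + ctr[2]
    out <- matrix(bilinear(v, as.vector(xr), as.vector(yr),
                           planned@spacing, planned@origin),
                  nrow(v), ncol(v))
    out[is.na(out)] <- 0  # dose moved off the plane edge
  }
  if (spec@globalScale != 1) out <- out * spec@globalScale
  if (spec@infieldScale != 1) {
    if (is.null(ptvMask))
      stop("infieldScale != 1 requires ptvMask")
    out[ptvMask] <- out[ptvMask] * spec@infieldScale
  }
  if (spec@outfieldScale != 1) {
    if (is.null(normalization))
      stop("outfieldScale != 1 requires normalization")
    outfield <- v < 0.5 * normalization  # outside the planned 50% isodose
    out[outfield] <- out[outfield] * spec@outfieldScale
  }
  if (spec@noiseSigma > 0) {
    if (is.null(normalization))
      stop("noiseSigma > 0 requires normalization")
    out <- withSeed(spec@seed, {
      out + matrix(rnorm(length(out), 0, spec@noiseSigma * normalization),
                   nrow(out), ncol(out))
    }, counter = 1L)
    out[out < 0] <- 0
  }
  DosePlane(out, spacing = planned@spacing, origin = planned@origin,
            plane = planned@plane)
}
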