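# Shared fixtures, built in code at load time.

# noise-free forward model and a calibration fitted from it
fm0 <- filmForwardModel(noiseSigma = 0)
cal0 <- fitCalibration(makeCalibrationDataset(fm0), darkening = fm0@darkening,
                       tRef = fm0@tRef)

# an ideal check-film QC (factor exactly 1)
qc1 <- checkFilmQC(checkFilmPair(c(10, 15), c(10, 15)))

# a smooth logistic field on a 61x61, 1 mm grid: plateau `maxF*norm`
# falling through a 3 mm-ish penumbra at radius `edge`, centred at `ctr`.
# The 10% isodose stays >9 mm inside the grid edge so every above-threshold
# pixel keeps its full gamma search disc.
logisticPlane <- function(ctr = c(0, 0), edge = 10, norm = 12,
                          maxF = 1.15, k = 1.2, half = 30, spacing = 1) {
  x <- seq(-half, half, by = spacing)
  r <- sqrt(outer((x - ctr[2])^2, (x - ctr[1])^2, "+"))
  DosePlane(maxF * norm / (1 + exp((r - edge) / k)), spacing = spacing)
}

# random rigid landmark configuration
randomLandmarks <- function(n = 4, range = 40) {
  matrix(runif(2 * n, -range, range), n, 2)
}
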