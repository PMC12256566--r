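# Internal helpers shared across modules: seeded RNG scoping, grid
# coordinates and bilinear interpolation, round-half-up.

# Evaluate `expr` under a derived seed without disturbing the caller's RNG
# stream. Sub-seeds are derived from (seed, counter) so every stochastic
# artifact has its own reproducible stream.
withSeed <- function(seed, expr, counter = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  sub <- (as.double(seed) * 48271 + as.double(counter)) %% 2147483647
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(sub))
  force(expr)
}

# x (cols) and y (rows) pixel-centre coordinates of a grid.
gridCoords <- function(dim, spacing, origin) {
  list(x = origin[1] + (seq_len(dim[2]) - 1) * spacing,
       y = origin[2] + (seq_len(dim[1]) - 1) * spacing)
}

# Default origin placing the grid centre at (0, 0).
centredOrigin <- function(dim, spacing) {
  -c(dim[2] - 1, dim[1] - 1) / 2 * spacing
}

# Bilinear interpolation of matrix `m` (rows = y, cols = x) at points
# (px, py) in mm. Returns NA outside the grid.
bilinear <- function(m, px, py, spacing, origin) {
  fx <- (px - origin[1]) / spacing
  fy <- (py - origin[2]) / spacing
  nx <- ncol(m); ny <- nrow(m)
  j0 <- floor(fx); i0 <- floor(fy)
  tx <- fx - j0;  ty <- fy - i0
  # clamp the upper edge so points exactly on the last pixel centre are inside
  hit <- fx >= 0 & fx <= nx - 1 & fy >= 0 & fy <= ny - 1
  j0 <- pmin(pmax(j0, 0), nx - 2)
  i0 <- pmin(pmax(i0, 0), ny - 2)
  tx <- fx - j0; ty <- fy - i0
  i0 <- i0 + 1; j0 <- j0 + 1  # 1-based
  v <- (1 - tx) * (1 - ty) * m[cbind(i0, j0)] +
    tx * (1 - ty) * m[cbind(i0, j0 + 1)] +
    (1 - tx) * ty * m[cbind(i0 + 1, j0)] +
    tx * ty * m[cbind(i0 + 1, j0 + 1)]
  v[!hit] <- NA_real_
  v
}

#' Round half away from zero
#'
#' Rounds 0.05 up at the last kept digit, the convention of the audit's
#' printed percentage tables (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimals to keep.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' roundHalfUp(c(3.55, 21.65), 1)
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Distance-from-point map over a grid, in mm.
radiusMap <- function(dim, spacing, origin, centre = c(0, 0)) {
  cc <- gridCoords(dim, spacing, origin)
  dx <- matrix(cc$x - centre[1], dim[1], dim[2], byrow = TRUE)
  dy <- matrix(cc$y - centre[2], dim[1], dim[2])
  sqrt(dx^2 + dy^2)
}
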