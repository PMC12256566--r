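#' Construct a dose plane
#'
#' @param values numeric matrix of doses in Gy (rows = y, cols = x).
#' @param spacing isotropic pixel spacing in mm.
#' @param origin mm coordinates of the first pixel centre; defaults to
#'   placing the grid centre at (0, 0).
#' @param plane orientation label (`"transverse"` or `"coronal"`).
#' @return A [DosePlane-class].
#' @export
#' @examples
#' dp <- DosePlane(matrix(1, 11, 11), spacing = 1)
#' gridOrigin(dp)
DosePlane <- function(values, spacing = 0.5, origin = NULL,
                      plane = "transverse") {
  values <- as.matrix(values)
  if (is.null(origin)) origin <- centredOrigin(dim(values), spacing)
  new("DosePlane", values = values, spacing = spacing,
      origin = as.numeric(origin), plane = plane)
}

#' Interpolate a dose plane at arbitrary points
#'
#' Bilinear interpolation at mm coordinates; returns NA outside the grid.
#' This is the single interpolation rule shared by the synthetic generator,
#' the registration resampler and the metrics module.
#'
#' @param plane a [DosePlane-class].
#' @param x,y coordinates in mm (vectors of equal length).
#' @return Numeric vector of interpolated doses.
#' @export
doseAt <- function(plane, x, y) {
  bilinear(plane@values, x, y, plane@spacing, plane@origin)
}

#' Read/write the plain-text dose grid format
#'
#' The grid file holds a small `key: value` header (`nx`, `ny`,
#' `spacing_mm`, `origin_mm`, `units`, `plane`) followed by the dose values,
#' one grid row per line.
#'
#' @param plane a [DosePlane-class].
#' @param path file path.
#' @return `readDoseGrid` returns a [DosePlane-class];
#'   `writeDoseGrid` returns `path` invisibly.
#' @export
writeDoseGrid <- function(plane, path) {
  stopifnot(is(plane, "DosePlane"))
  v <- plane@values
  hdr <- c(sprintf("nx: %d", ncol(v)),
           sprintf("ny: %d", nrow(v)),
           sprintf("spacing_mm: %.9g", plane@spacing),
           sprintf("origin_mm: %.9g %.9g", plane@origin[1], plane@origin[2]),
           "units: Gy",
           sprintf("plane: %s", plane@plane))
  rows <- apply(v, 1, function(r) paste(formatC(r, format = "g", digits = 9),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname writeDoseGrid
#' @export
readDoseGrid <- function(path) {
  ln <- readLines(path)
  hdr <- grepl("^[a-z_]+:", ln)
  kv <- strsplit(sub(":", "\x01", ln[hdr]), "\x01")
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  nx <- as.integer(vals["nx"]); ny <- as.integer(vals["ny"])
  spacing <- as.numeric(vals["spacing_mm"])
  origin <- as.numeric(strsplit(vals["origin_mm"], "\\s+")[[1]])
  body <- ln[!hdr]
  if (length(body) != ny) stop("grid file: expected ", ny, " data rows")
  v <- do.call(rbind, lapply(body, function(r)
    as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
  if (ncol(v) != nx) stop("grid file: expected ", nx, " columns")
  DosePlane(v, spacing = spacing, origin = origin,
            plane = if (is.na(vals["plane"])) "transverse" else vals["plane"])
}
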