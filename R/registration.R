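# Rigid film-to-plan registration from fiducial landmarks, with the
# dual-observer agreement check. The manual GUI alignment of the audit
# workflow is replaced by landmark least squares (2D orthogonal
# Procrustes); the "two observers" check is modelled as two independently
# entered landmark sets.

#' Landmark set constructor
#'
#' @param film n x 2 matrix of film-plane positions, mm.
#' @param plan n x 2 matrix of the matching plan-grid positions, mm.
#' @param observer observer identifier.
#' @return A [LandmarkSet-class].
#' @export
landmarkSet <- function(film, plan, observer = "obs1") {
  new("LandmarkSet", film = as.matrix(film), plan = as.matrix(plan),
      observer = observer)
}

#' Read/write landmark CSVs
#'
#' Columns: `observer`, `film_x_mm`, `film_y_mm`, `plan_x_mm`,
#' `plan_y_mm`. Reading returns one [LandmarkSet-class] per observer.
#'
#' @param sets list of [LandmarkSet-class] objects.
#' @param path CSV path.
#' @return `readLandmarksCsv` returns a named list of
#'   [LandmarkSet-class] objects.
#' @export
writeLandmarksCsv <- function(sets, path) {
  if (is(sets, "LandmarkSet")) sets <- list(sets)
  df <- do.call(rbind, lapply(sets, function(s)
    data.frame(observer = s@observer, film_x_mm = s@film[, 1],
               film_y_mm = s@film[, 2], plan_x_mm = s@plan[, 1],
               plan_y_mm = s@plan[, 2])))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLandmarksCsv
#' @export
readLandmarksCsv <- function(path) {
  df <- read.csv(path)
  lapply(split(df, df$observer), function(d)
    landmarkSet(cbind(d$film_x_mm, d$film_y_mm),
                cbind(d$plan_x_mm, d$plan_y_mm), d$observer[1]))
}

#' Construct a rigid transform
#'
#' @param rotationDeg rotation in degrees (counter-clockwise).
#' @param translation `(dx, dy)` in mm.
#' @param rmsResidual rms landmark residual, mm.
#' @return A [RigidTransform2D-class].
#' @export
rigidTransform2D <- function(rotationDeg = 0, translation = c(0, 0),
                             rmsResidual = 0) {
  new("RigidTransform2D", rotationDeg = rotationDeg,
      translation = as.numeric(translation), rmsResidual = rmsResidual)
}

#' Apply, invert and compose rigid transforms
#'
#' `applyTransform` maps n x 2 film coordinates into the plan frame;
#' `invertTransform` and `composeTransforms` operate in the transform
#' group (composition applies `t1` first).
#'
#' @param t,t1,t2 [RigidTransform2D-class] objects.
#' @param points n x 2 matrix of mm coordinates.
#' @return Transformed points, or a new [RigidTransform2D-class].
#' @export
applyTransform <- function(t, points) {
  th <- t@rotationDeg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  p <- if (is.null(dim(points))) matrix(points, ncol = 2)
       else as.matrix(points)
  sweep(p %*% t(R), 2, -t@translation)
}

#' @rdname applyTransform
#' @export
invertTransform <- function(t) {
  th <- -t@rotationDeg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rigidTransform2D(-t@rotationDeg, as.vector(-R %*% t@translation))
}

#' @rdname applyTransform
#' @export
composeTransforms <- function(t2, t1) {
  th2 <- t2@rotationDeg * pi / 180
  R2 <- matrix(c(cos(th2), sin(th2), -sin(th2), cos(th2)), 2, 2)
  rigidTransform2D(t1@rotationDeg + t2@rotationDeg,
                   as.vector(R2 %*% t1@translation) + t2@translation)
}

#' Fit the film-to-plan rigid transform from landmarks
#'
#' Least-squares rigid (rotation + translation, no scale or shear)
#' transform mapping film landmark positions onto their plan-grid
#' counterparts: 2D orthogonal Procrustes via the SVD of the centred
#' cross-covariance, with the reflection excluded. The result is invariant
#' to landmark ordering. An rms residual above 1 mm flags suspect landmark
#' entry with a warning.
#'
#' @param landmarks a [LandmarkSet-class] (n >= 3, non-collinear).
#' @return A [RigidTransform2D-class] with its rms residual.
#' @export
#' @examples
#' lm <- landmarkSet(rbind(c(0, 0), c(10, 0), c(0, 10)),
#'                   rbind(c(1, 2), c(11, 2), c(1, 12)))
#' fitRigid(lm)  # pure translation (1, 2)
fitRigid <- function(landmarks) {
  stopifnot(is(landmarks, "LandmarkSet"))
  validObject(landmarks)
  P <- landmarks@film; Q <- landmarks@plan
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  th <- atan2(R[2, 1], R[1, 1])
  tr <- cq - as.vector(R %*% cp)
  fit <- rigidTransform2D(th * 180 / pi, tr)
  res <- applyTransform(fit, P) - Q
  rms <- sqrt(mean(rowSums(res^2)))
  if (rms > 1)
    warning(sprintf("rms landmark residual %.2f mm: suspect landmark entry",
                    rms))
  fit@rmsResidual <- rms
  fit
}

#' Dual-observer registration agreement
#'
#' Maximum discrepancy between two observers' transforms, evaluated at the
#' four film corners (the worst case for a rotation difference). `extentMm`
#' is the centre-to-corner distance (half-diagonal) of the film area;
#' corners are placed at `(+-extentMm/sqrt(2), +-extentMm/sqrt(2))`.
#' Agreement requires the maximum discrepancy to be strictly below 0.5 mm.
#'
#' @param t1,t2 [RigidTransform2D-class] fits of the two observers.
#' @param extentMm centre-to-corner distance of the film, mm.
#' @param tolerance agreement tolerance in mm (default 0.5; strict `<`).
#' @return List with `maxDiscrepancyMm` and logical `agreed`.
#' @export
observerAgreement <- function(t1, t2, extentMm = 60, tolerance = 0.5) {
  e <- extentMm / sqrt(2)
  corners <- rbind(c(-e, -e), c(e, -e), c(e, e), c(-e, e))
  d <- applyTransform(t1, corners) - applyTransform(t2, corners)
  maxd <- max(sqrt(rowSums(d^2)))
  list(maxDiscrepancyMm = maxd, agreed = maxd < tolerance)
}

#' Resample a measured film plane onto the plan grid
#'
#' Interpolates the measured dose (bilinear, the pipeline's shared
#' interpolation rule) onto the plan grid after mapping each plan pixel
#' back into the film frame through the inverse transform. Pixels that
#' fall outside the film are masked NA; if fewer than 50% of the plan
#' pixels are covered the registration is rejected.
#'
#' @param measured a [DosePlane-class] in film-frame coordinates.
#' @param t the film-to-plan [RigidTransform2D-class].
#' @param planGrid a [DosePlane-class] (or [PhantomPlane-class]) defining
#'   the target grid.
#' @return A [DosePlane-class] on the plan grid.
#' @export
resampleToPlan <- function(measured, t, planGrid) {
  stopifnot(is(measured, "DosePlane"), is(t, "RigidTransform2D"))
  dim <- if (is(planGrid, "DosePlane")) dim(planGrid@values)
         else dim(planGrid@materials@labels)
  spacing <- planGrid@spacing; origin <- planGrid@origin
  cc <- gridCoords(dim, spacing, origin)
  X <- matrix(cc$x, dim[1], dim[2], byrow = TRUE)
  Y <- matrix(cc$y, dim[1], dim[2])
  inv <- invertTransform(t)
  pf <- applyTransform(inv, cbind(as.vector(X), as.vector(Y)))
  v <- matrix(doseAt(measured, pf[, 1], pf[, 2]), dim[1], dim[2])
  if (mean(!is.na(v)) < 0.5)
    stop("less than 50% of the plan grid is covered by the film")
  DosePlane(v, spacing = spacing, origin = origin,
            plane = measured@plane)
}

#' Persist a rigid transform as JSON
#'
#' @param t a [RigidTransform2D-class].
#' @param path JSON file path.
#' @return `readTransform` returns a [RigidTransform2D-class].
#' @export
writeTransform <- function(t, path) {
  jsonlite::write_json(list(rotation_deg = t@rotationDeg,
                            translation_mm = t@translation,
                            rms_residual_mm = t@rmsResidual),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigidTransform2D(j$rotation_deg, j$translation_mm, j$rms_residual_mm)
}
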