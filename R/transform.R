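#' Construct a rigid-body transform
#'
#' @param rotations angles in radians about the world x, y, z axes, applied in
#'   that order about `center`.
#' @param translations offsets in mm, added after rotation.
#' @param center world point (mm) about which rotations apply.
#' @return A [RigidTransform-class].
#' @examples
#' t <- rigidTransform(rotations = c(0, 0, 0.05), translations = c(5, -3, 2))
#' rigidMatrix(t)
#' @export
rigidTransform <- function(rotations = c(0, 0, 0),
                           translations = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  new("RigidTransform", rotations = as.numeric(rotations),
      translations = as.numeric(translations), center = as.numeric(center))
}

rotationMatrix <- function(rotations) {
  a <- rotations[1]; b <- rotations[2]; g <- rotations[3]
  Rx <- matrix(c(1, 0, 0,  0, cos(a), sin(a),  0, -sin(a), cos(a)), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b),  0, 1, 0,  sin(b), 0, cos(b)), 3, 3)
  Rz <- matrix(c(cos(g), sin(g), 0,  -sin(g), cos(g), 0,  0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Homogeneous 4x4 matrix of a rigid transform
#'
#' A point p maps to `R (p - center) + center + translations` where R rotates
#' about x, then y, then z.
#'
#' @param t a [RigidTransform-class].
#' @return 4x4 matrix acting on homogeneous world coordinates.
#' @export
rigidMatrix <- function(t) {
  R <- rotationMatrix(t@rotations)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- t@center + t@translations - R %*% t@center
  M
}

# Euler angles (x-then-y-then-z convention, R = Rz Ry Rx) from a rotation
# matrix. Valid away from the |pitch| = 90 deg gimbal lock, far beyond the
# <= 10 deg perturbations this package deals in.
eulerFromRotation <- function(R) {
  b <- asin(max(-1, min(1, -R[3, 1])))
  a <- atan2(R[3, 2], R[3, 3])
  g <- atan2(R[2, 1], R[1, 1])
  c(a, b, g)
}

# Re-express a homogeneous rigid matrix as a RigidTransform about `center`.
rigidFromMatrix <- function(M, center = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  rot <- eulerFromRotation(R)
  # M maps p -> R p + d; with rotation about center the translation is
  # d - center + R center
  tr <- M[1:3, 4] - center + as.numeric(R %*% center)
  rigidTransform(rot, tr, center)
}

#' Invert a rigid transform
#'
#' @param t a [RigidTransform-class].
#' @return The inverse transform, expressed about the same center; composing
#'   the two gives identity within numerical precision.
#' @export
invertTransform <- function(t) {
  rigidFromMatrix(solve(rigidMatrix(t)), center = t@center)
}

# Average two transforms in the 6-parameter space about a common center
# (used to symmetrize forward and reverse registrations).
averageTransforms <- function(t1, t2) {
  t2c <- rigidFromMatrix(rigidMatrix(t2), center = t1@center)
  rigidTransform((t1@rotations + t2c@rotations) / 2,
                 (t1@translations + t2c@translations) / 2,
                 t1@center)
}

#' Resample a volume through a rigid transform
#'
#' Resamples `vol` onto `reference`'s grid. `t` maps `vol`'s world frame into
#' `reference`'s world frame, so each reference voxel is looked up at
#' `t^-1(world)` in `vol`. Interpolation is trilinear (`"linear"`) or
#' nearest-neighbour (`"nearest"`, for masks and label volumes). Voxels mapped
#' from outside `vol`'s support are 0 and flagged in the `support` attribute
#' (a logical array) so downstream masks can exclude them.
#'
#' @param vol the moving [BrainVolume-class].
#' @param t a [RigidTransform-class] mapping vol's world into reference's
#'   world.
#' @param reference the [BrainVolume-class] whose grid to resample onto.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return A [BrainVolume-class] on `reference`'s grid with a `support`
#'   attribute on its data.
#' @export
applyTransform <- function(vol, t, reference, interpolation = c("linear", "nearest")) {
  stopifnot(is(vol, "BrainVolume"), is(t, "RigidTransform"),
            is(reference, "BrainVolume"))
  interpolation <- match.arg(interpolation)
  M <- solve(vol@affine) %*% solve(rigidMatrix(t)) %*% reference@affine
  outDim <- dim(reference@data)
  # identity mapping onto the same grid: copy exactly (no interpolation noise)
  if (all(dim(vol@data) == outDim) && max(abs(M - diag(4))) < 1e-10) {
    out <- new("BrainVolume", data = vol@data, spacing = reference@spacing,
               affine = reference@affine, modality = vol@modality)
    attr(out@data, "support") <- array(TRUE, outDim)
    return(out)
  }
  res <- if (interpolation == "linear")
    resampleTrilinearC(as.numeric(vol@data), dim(vol@data), M, outDim)
  else
    resampleNearestC(as.numeric(vol@data), dim(vol@data), M, outDim)
  data <- array(res$values, outDim)
  out <- new("BrainVolume", data = data, spacing = reference@spacing,
             affine = reference@affine, modality = vol@modality)
  attr(out@data, "support") <- array(res$support == 1L, outDim)
  out
}

resampleSupport <- function(resampled) {
  s <- attr(resampled@data, "support")
  if (is.null(s)) array(TRUE, dim(resampled@data)) else s
}

#' Serialize a rigid transform to a plain-text sidecar
#'
#' Writes the 6 parameters plus the rotation center as documented key-value
#' lines (angles in radians, offsets and center in mm).
#'
#' @param t a [RigidTransform-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
saveTransform <- function(t, path) {
  lines <- c(
    "# rigid transform: rotations rad (x y z, applied x->y->z about center);",
    "# translations mm; center mm (world RAS+)",
    sprintf("rotations: %.17g %.17g %.17g", t@rotations[1], t@rotations[2], t@rotations[3]),
    sprintf("translations: %.17g %.17g %.17g", t@translations[1], t@translations[2], t@translations[3]),
    sprintf("center: %.17g %.17g %.17g", t@center[1], t@center[2], t@center[3]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname saveTransform
#' @export
loadTransform <- function(path) {
  lines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  getv <- function(key) {
    ln <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (length(ln) != 1L) stop("malformed transform file: missing ", key)
    as.numeric(strsplit(trimws(sub(".*:", "", ln)), "\\s+")[[1]])
  }
  rigidTransform(getv("rotations"), getv("translations"), getv("center"))
}
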