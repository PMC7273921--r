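#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib siscom, .registration = TRUE
NULL

#' BrainVolume: a 3-D scalar image with grid geometry
#'
#' The carrier for all image math in the package: a 3-D array of scalar
#' intensities (arbitrary units) together with voxel spacing in millimetres
#' and a 4x4 affine mapping 0-based voxel indices to RAS+ world millimetres.
#'
#' @slot data 3-D numeric array of intensities.
#' @slot spacing numeric(3), millimetres per voxel along each axis (all > 0).
#' @slot affine 4x4 invertible matrix; \code{affine \%*\% c(i, j, k, 1)} gives
#'   the world position (mm, RAS+) of the centre of 0-based voxel (i, j, k).
#' @slot modality free-text tag: one of \code{"ictal"}, \code{"interictal"},
#'   \code{"structural"}, \code{"diff"}, \code{"z"}, \code{"atlas"} or
#'   \code{"unknown"}.
#'
#' @seealso [brainVolume()], [readVolume()], [writeVolume()]
#' @export
setClass("BrainVolume",
  representation(data = "array", spacing = "numeric",
                 affine = "matrix", modality = "character"),
  prototype(modality = "unknown"))

setValidity("BrainVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3-D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive finite values")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  else if (abs(det(object@affine)) < .Machine$double.eps * 64)
    msg <- c(msg, "affine must be invertible")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    msg <- c(msg, "data must contain no non-finite values")
  if (length(msg)) msg else TRUE
})

#' Construct a BrainVolume
#'
#' @param data 3-D numeric array.
#' @param spacing voxel size in mm (length 3, or scalar recycled).
#' @param affine 4x4 voxel-to-world matrix; defaults to a diagonal affine with
#'   the given spacing and the world origin at the grid centre (RAS+).
#' @param modality free-text modality tag.
#' @return A [BrainVolume-class] object.
#' @examples
#' vol <- brainVolume(array(rnorm(8^3), c(8, 8, 8)), spacing = 2)
#' volSpacing(vol)
#' @export
brainVolume <- function(data, spacing = c(1, 1, 1), affine = NULL,
                        modality = "unknown") {
  spacing <- rep_len(as.numeric(spacing), 3L)
  data <- as.array(data)
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
    affine[1:3, 4] <- -(dim(data) - 1) / 2 * spacing
  }
  new("BrainVolume", data = data, spacing = spacing,
      affine = affine, modality = modality)
}

#' BrainMask: a boolean voxel set on a BrainVolume grid
#'
#' @slot mask logical 3-D array, same dimensions as its source volume.
#' @slot nVoxels integer count of TRUE voxels.
#' @seealso [computeBrainMask()]
#' @export
setClass("BrainMask",
  representation(mask = "array", nVoxels = "integer"))

setValidity("BrainMask", function(object) {
  msg <- character()
  if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
    msg <- c(msg, "mask must be a logical 3-D array")
  if (object@nVoxels != sum(object@mask))
    msg <- c(msg, "nVoxels must equal the number of TRUE voxels")
  if (length(msg)) msg else TRUE
})

#' Construct a BrainMask from a logical array
#'
#' @param mask logical 3-D array.
#' @return A [BrainMask-class].
#' @export
brainMask <- function(mask) {
  new("BrainMask", mask = mask, nVoxels = as.integer(sum(mask)))
}

#' RigidTransform: a 6-parameter rigid-body world transform
#'
#' Rotations are applied about the world axes in fixed order x, then y, then
#' z, around \code{center}; translation is added afterwards. A point p maps to
#' \code{R (p - center) + center + translation}.
#'
#' @slot rotations numeric(3) angles in radians (about x, y, z).
#' @slot translations numeric(3) offsets in mm.
#' @slot center numeric(3) world point (mm) about which rotations apply. It
#'   plays the role of the anatomical reference point for realignment.
#' @seealso [rigidTransform()], [rigidMatrix()], [invertTransform()]
#' @export
setClass("RigidTransform",
  representation(rotations = "numeric", translations = "numeric",
                 center = "numeric"))

setValidity("RigidTransform", function(object) {
  if (length(object@rotations) != 3L || length(object@translations) != 3L ||
      length(object@center) != 3L ||
      any(!is.finite(c(object@rotations, object@translations, object@center))))
    "rotations, translations and center must be finite numeric(3)"
  else TRUE
})

#' RegistrationResult: outcome of rigid registration
#'
#' @slot transform the estimated [RigidTransform-class] mapping the moving
#'   volume's world frame into the fixed volume's world frame.
#' @slot finalMetric mutual information (nats) at the solution.
#' @slot metricAtIdentity mutual information at the identity initialization;
#'   \code{finalMetric >= metricAtIdentity} always holds.
#' @slot nIterations total objective evaluations across resolution levels.
#' @slot converged logical; FALSE flags an optimizer failure (never silent).
#' @export
setClass("RegistrationResult",
  representation(transform = "RigidTransform", finalMetric = "numeric",
                 metricAtIdentity = "numeric", nIterations = "integer",
                 converged = "logical"))

#' ZScoreMap: standardized ictal-interictal difference image
#'
#' The difference image standardized by the mean and standard deviation of
#' the differences over all brain voxels; z is 0 outside the mask.
#'
#' @slot z [BrainVolume-class] of z-scores (modality \code{"z"}).
#' @slot mask the [BrainMask-class] over which the moments were taken.
#' @slot meanDiff mean of the difference image over the mask.
#' @slot sdDiff sample standard deviation (n-1) of the difference over the
#'   mask; always > 0.
#' @slot zThreshold significance threshold used downstream (default 2).
#' @seealso [zscoreMap()], [thresholdClusters()]
#' @export
setClass("ZScoreMap",
  representation(z = "BrainVolume", mask = "BrainMask", meanDiff = "numeric",
                 sdDiff = "numeric", zThreshold = "numeric"),
  prototype(zThreshold = 2))

setValidity("ZScoreMap", function(object) {
  if (object@sdDiff <= 0) "sdDiff must be > 0" else TRUE
})

#' Cluster: a connected supra-threshold voxel set
#'
#' @slot voxelIndices integer matrix (n x 3) of 0-based voxel indices.
#' @slot peakZ maximum z over members.
#' @slot peakVoxel 0-based voxel index (length 3) of the maximum; among tied
#'   maxima the lexicographically smallest index.
#' @slot peakWorld world-mm position of the peak voxel.
#' @slot sizeVoxels member count.
#' @slot sizeMl member count times voxel volume, in millilitres.
#' @slot regionLabel lobe name or \code{"unlabeled"}.
#' @slot side \code{"left"}, \code{"right"}, \code{"midline"} or
#'   \code{"unknown"}, from the world x-coordinate sign of the peak voxel.
#' @export
setClass("Cluster",
  representation(voxelIndices = "matrix", peakZ = "numeric",
                 peakVoxel = "integer", peakWorld = "numeric",
                 sizeVoxels = "integer", sizeMl = "numeric",
                 regionLabel = "character", side = "character"),
  prototype(regionLabel = "unlabeled", side = "unknown"))

setClassUnion("ClusterOrNULL", c("Cluster", "NULL"))

#' EZCall: ranked clusters split into an EZ candidate and propagation areas
#'
#' The cluster with the highest peak z is the epileptogenic-zone candidate;
#' every other supra-threshold cluster is a propagation area. When more than
#' one cluster is present the call is flagged for human review, mirroring the
#' clinical practice of adjudicating multiplicity with injection time and
#' clinical findings (which this package does not automate). When no voxel
#' exceeds the threshold the call has status \code{"no_hyperperfusion"} -
#' a valid result, not an error.
#'
#' @slot primary the EZ-candidate [Cluster-class], or NULL when none.
#' @slot propagation list of the remaining clusters, descending peak z.
#' @slot nClusters total cluster count.
#' @slot reviewFlag TRUE when more than one cluster.
#' @slot status \code{"ok"} or \code{"no_hyperperfusion"}.
#' @seealso [callEZ()]
#' @export
setClass("EZCall",
  representation(primary = "ClusterOrNULL", propagation = "list",
                 nClusters = "integer", reviewFlag = "logical",
                 status = "character"),
  prototype(status = "ok"))

setValidity("EZCall", function(object) {
  msg <- character()
  if (object@status == "ok") {
    if (is.null(object@primary))
      msg <- c(msg, "status 'ok' requires a primary cluster")
    else {
      if (object@nClusters != 1L + length(object@propagation))
        msg <- c(msg, "nClusters must be 1 + length(propagation)")
      pz <- vapply(object@propagation, function(cl) cl@peakZ, numeric(1))
      if (length(pz) && object@primary@peakZ < max(pz))
        msg <- c(msg, "primary peak z must be >= all propagation peak z")
    }
  } else if (object@nClusters != 0L) {
    msg <- c(msg, "no-hyperperfusion call must have 0 clusters")
  }
  if (length(msg)) msg else TRUE
})

#' LobeAtlas: an integer-labelled parcellation volume
#'
#' @slot volume [BrainVolume-class] whose data are integer lobe codes
#'   (0 = background).
#' @slot labels named character vector mapping code (as name) to lobe name.
#' @seealso [makeSyntheticAtlas()], [labelClusterRegion()]
#' @export
setClass("LobeAtlas",
  representation(volume = "BrainVolume", labels = "character"))

#' PhantomSpec: parameters of a simulated ictal/interictal SPECT pair
#'
#' @slot shape integer(3) grid dimensions.
#' @slot spacing numeric(3) voxel size, mm.
#' @slot brainSemiaxes numeric(3) ellipsoid semiaxes, mm.
#' @slot baselineIntensity baseline perfusion counts.
#' @slot foci list of foci, each \code{list(center = mm world, radius = mm,
#'   amplitude = relative increase)}; each centre must lie inside the brain
#'   ellipsoid.
#' @slot psfFwhm Gaussian point-spread FWHM in mm (effective resolution).
#' @slot noiseModel \code{list(type = "gaussian", sd_fraction = ...)} or
#'   \code{list(type = "poisson", scale = ...)} or \code{list(type = "none")}.
#' @slot misalignment [RigidTransform-class] applied to the ictal volume, or
#'   NULL for a perfectly aligned pair.
#' @slot seed integer RNG seed; simulation is fully reproducible from it.
#' @seealso [phantomSpec()], [simulateCase()]
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric",
                 brainSemiaxes = "numeric", baselineIntensity = "numeric",
                 foci = "list", psfFwhm = "numeric", noiseModel = "list",
                 misalignment = "ANY", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@psfFwhm < 0) msg <- c(msg, "psfFwhm must be >= 0")
  if (object@baselineIntensity <= 0)
    msg <- c(msg, "baselineIntensity must be > 0")
  nm <- object@noiseModel
  if (!is.list(nm) || is.null(nm$type) ||
      !nm$type %in% c("none", "gaussian", "poisson"))
    msg <- c(msg, "noiseModel$type must be 'none', 'gaussian' or 'poisson'")
  else if (nm$type == "gaussian" && (is.null(nm$sd_fraction) || nm$sd_fraction < 0))
    msg <- c(msg, "gaussian noise needs sd_fraction >= 0")
  else if (nm$type == "poisson" && (is.null(nm$scale) || nm$scale <= 0))
    msg <- c(msg, "poisson noise needs scale > 0")
  for (f in object@foci) {
    u <- f$center / object@brainSemiaxes
    if (sum(u^2) > 1)
      msg <- c(msg, "every focus center must lie inside the brain ellipsoid")
    if (f$radius <= 0) msg <- c(msg, "focus radius must be > 0")
  }
  if (!is.null(object@misalignment) &&
      !is(object@misalignment, "RigidTransform"))
    msg <- c(msg, "misalignment must be a RigidTransform or NULL")
  if (length(msg)) msg else TRUE
})

#' PhantomTruth: ground truth accompanying a simulated case
#'
#' @slot focusCenters list of world-mm centres in the canonical (interictal)
#'   frame.
#' @slot focusCentersIctal the same centres mapped through the applied
#'   misalignment into the ictal frame (where the analysis output lives).
#' @slot focusMasks list of logical arrays (one per focus, pairwise disjoint)
#'   on the canonical grid.
#' @slot appliedMisalignment the [RigidTransform-class] applied to the ictal
#'   volume (identity when none was requested).
#' @slot atlas a [LobeAtlas-class] of synthetic lobes on the canonical grid.
#' @export
setClass("PhantomTruth",
  representation(focusCenters = "list", focusCentersIctal = "list",
                 focusMasks = "list", appliedMisalignment = "RigidTransform",
                 atlas = "LobeAtlas"))
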