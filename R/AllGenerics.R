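#' Accessors for BrainVolume and BrainMask
#'
#' Slot access for the imaging classes goes through these accessors.
#'
#' @param x a [BrainVolume-class], [BrainMask-class] or [ZScoreMap-class].
#' @return `volData` the 3-D array; `volSpacing` mm per voxel; `volAffine`
#'   the 4x4 voxel-to-world matrix; `volModality` the modality tag;
#'   `maskArray` the logical array; `nMaskVoxels` the TRUE-voxel count.
#' @name volume-accessors
#' @examples
#' vol <- brainVolume(array(1, c(4, 4, 4)), spacing = 2)
#' dim(volData(vol))
NULL

#' @rdname volume-accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname volume-accessors
#' @export
setGeneric("volSpacing", function(x) standardGeneric("volSpacing"))
#' @rdname volume-accessors
#' @export
setGeneric("volAffine", function(x) standardGeneric("volAffine"))
#' @rdname volume-accessors
#' @export
setGeneric("volModality", function(x) standardGeneric("volModality"))
#' @rdname volume-accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @rdname volume-accessors
#' @export
setGeneric("nMaskVoxels", function(x) standardGeneric("nMaskVoxels"))

#' @rdname volume-accessors
setMethod("volData", "BrainVolume", function(x) x@data)
#' @rdname volume-accessors
setMethod("volSpacing", "BrainVolume", function(x) x@spacing)
#' @rdname volume-accessors
setMethod("volAffine", "BrainVolume", function(x) x@affine)
#' @rdname volume-accessors
setMethod("volModality", "BrainVolume", function(x) x@modality)
#' @rdname volume-accessors
setMethod("maskArray", "BrainMask", function(x) x@mask)
#' @rdname volume-accessors
setMethod("nMaskVoxels", "BrainMask", function(x) x@nVoxels)
#' @rdname volume-accessors
setMethod("volData", "ZScoreMap", function(x) x@z@data)

#' @describeIn volume-accessors grid dimensions of a volume
#' @export
setMethod("dim", "BrainVolume", function(x) dim(x@data))

setMethod("show", "BrainVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("BrainVolume [%s]: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              object@modality, d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "BrainMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("BrainMask: %d voxels on a %d x %d x %d grid\n",
              object@nVoxels, d[1], d[2], d[3]))
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform (x->y->z rotations about center)\n")
  cat(sprintf("  rotations   : %8.5f %8.5f %8.5f rad\n",
              object@rotations[1], object@rotations[2], object@rotations[3]))
  cat(sprintf("  translations: %8.3f %8.3f %8.3f mm\n",
              object@translations[1], object@translations[2],
              object@translations[3]))
  cat(sprintf("  center      : %8.3f %8.3f %8.3f mm\n",
              object@center[1], object@center[2], object@center[3]))
})

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf("RegistrationResult: MI %.5f nats (identity %.5f), %d evaluations, %s\n",
              object@finalMetric, object@metricAtIdentity, object@nIterations,
              if (object@converged) "converged" else "NOT converged"))
  show(object@transform)
})

setMethod("show", "ZScoreMap", function(object) {
  cat(sprintf("ZScoreMap: mean diff %.5g, SD diff %.5g over %d brain voxels, threshold z > %g\n",
              object@meanDiff, object@sdDiff, object@mask@nVoxels,
              object@zThreshold))
})

setMethod("show", "Cluster", function(object) {
  cat(sprintf("Cluster: %d voxels (%.2f mL), peak z %.3f at voxel (%d,%d,%d), %s %s\n",
              object@sizeVoxels, object@sizeMl, object@peakZ,
              object@peakVoxel[1], object@peakVoxel[2], object@peakVoxel[3],
              object@side, object@regionLabel))
})

setMethod("show", "EZCall", function(object) {
  if (object@status == "no_hyperperfusion") {
    cat("EZCall: no significant hyperperfusion\n")
  } else {
    cat(sprintf("EZCall: %d cluster(s)%s\n", object@nClusters,
                if (object@reviewFlag) " [multiple clusters - review]" else ""))
    cat("  primary: "); show(object@primary)
    for (cl in object@propagation) { cat("  propagation: "); show(cl) }
  }
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d x %d x %d grid @ %g mm, %d focus/foci, PSF %g mm FWHM, noise %s, seed %d\n",
              object@shape[1], object@shape[2], object@shape[3],
              object@spacing[1], length(object@foci), object@psfFwhm,
              object@noiseModel$type, object@seed))
})

setMethod("show", "LobeAtlas", function(object) {
  cat(sprintf("LobeAtlas: %s on a %d x %d x %d grid\n",
              paste(object@labels, collapse = ", "),
              dim(object@volume)[1], dim(object@volume)[2],
              dim(object@volume)[3]))
})
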