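#' Read a 3-D volume from a NIfTI-1 file
#'
#' Loads a `.nii`/`.nii.gz` image and carries its voxel spacing and
#' voxel-to-world affine into a [BrainVolume-class]. A 4-D image with a single
#' time point is squeezed to 3-D; more than one time point is an ambiguity and
#' an error. Non-finite voxels are mapped to 0 with a warning stating the
#' count.
#'
#' @param path path to an existing NIfTI-1 file with 3 spatial dimensions.
#' @param modality modality tag to attach (default `"unknown"`).
#' @return A [BrainVolume-class].
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path, modality = "unknown") {
  if (!file.exists(path)) stop("file does not exist: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L) {
    if (d[4] > 1L)
      stop("multiple frames: input has ", d[4],
           " time points; expected a single 3-D volume")
    img <- img[, , , 1L, drop = TRUE]
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop("expected a 3-D image, got ", length(d), " dimensions")
  data <- array(as.numeric(img), d)
  nbad <- sum(!is.finite(data))
  if (nbad > 0L) {
    data[!is.finite(data)] <- 0
    warning(nbad, " non-finite voxel(s) set to 0")
  }
  aff <- unclass(RNifti::xform(img))
  spacing <- abs(RNifti::pixdim(img))[1:3]
  new("BrainVolume", data = data, spacing = as.numeric(spacing),
      affine = matrix(as.numeric(aff), 4, 4), modality = modality)
}

#' Write a BrainVolume to a NIfTI-1 file
#'
#' Stores the data as float32 with the volume's spacing and affine in the
#' header, so that `readVolume(writeVolume(...))` is the identity on data,
#' spacing and affine up to float32 precision.
#'
#' @param vol a [BrainVolume-class].
#' @param path output path (`.nii` or `.nii.gz`); the parent directory must
#'   exist.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "BrainVolume"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(vol@data)
  RNifti::pixdim(img) <- vol@spacing
  RNifti::sform(img) <- structure(vol@affine, code = 2L)
  RNifti::qform(img) <- structure(vol@affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Compute a brain mask by robust thresholding
#'
#' The mask is the voxel set at or above `fracOfRobustMax` times the 99th
#' percentile intensity, reduced to its largest 26-connected component, with
#' interior holes filled. Deterministic, and invariant to multiplying the
#' volume by a positive constant. This makes "all brain voxels" operational
#' for perfusion volumes, where high counts are confined to brain tissue.
#'
#' @param vol a [BrainVolume-class] with non-constant intensities.
#' @param fracOfRobustMax fraction in (0, 1) of the robust maximum (99th
#'   percentile); default 0.3, a standard perfusion-SPECT heuristic.
#' @return A [BrainMask-class]; errors if the threshold leaves no voxels.
#' @examples
#' ph <- phantomSpec(seed = 1L, noiseModel = list(type = "none"))
#' sim <- simulateCase(ph)
#' m <- computeBrainMask(sim$interictal)
#' nMaskVoxels(m)
#' @export
computeBrainMask <- function(vol, fracOfRobustMax = 0.3) {
  stopifnot(is(vol, "BrainVolume"))
  if (fracOfRobustMax <= 0 || fracOfRobustMax >= 1)
    stop("fracOfRobustMax must be in (0, 1)")
  x <- vol@data
  if (max(x) == min(x)) stop("no contrast: volume is constant")
  thr <- fracOfRobustMax * as.numeric(stats::quantile(x, 0.99, names = FALSE))
  m <- x >= thr
  if (!any(m)) stop("empty mask after thresholding")
  lab <- labelComponents(m, connectivity = 26L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  m <- lab == keep
  m <- fillHoles(m)
  brainMask(m)
}

# Fill interior holes: background components (6-connected) that do not touch
# the array border become foreground.
fillHoles <- function(mask) {
  bg <- labelComponents(!mask, connectivity = 6L)
  d <- dim(mask)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  outside <- unique(bg[border & !mask])
  holes <- bg > 0L & !(bg %in% outside)
  mask | holes
}
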