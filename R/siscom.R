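# The subtraction analysis: whole-brain intensity normalization, voxel-wise
# subtraction, z-score standardization, threshold/cluster extraction and the
# epileptogenic-zone call.

#' Normalize a volume's uptake toward a whole-brain mean
#'
#' Scales the volume so that its mean intensity within the brain mask equals
#' `targetMean`. The z-score map downstream is invariant to `targetMean` and
#' to any positive rescaling of the input.
#'
#' @param vol a [BrainVolume-class].
#' @param mask a [BrainMask-class]; the within-mask mean must be positive.
#' @param targetMean target within-mask mean intensity (default 100).
#' @return The rescaled [BrainVolume-class].
#' @export
normalizeGlobal <- function(vol, mask, targetMean = 100) {
  stopifnot(is(vol, "BrainVolume"), is(mask, "BrainMask"))
  m <- mean(vol@data[mask@mask])
  if (!is.finite(m) || m <= 0)
    stop("non-positive within-mask mean: cannot normalize")
  out <- vol
  out@data <- vol@data * (targetMean / m)
  out
}

#' Voxel-wise subtraction of normalized volumes
#'
#' `ictal - interictal` inside the mask, 0 outside; both inputs must already
#' be normalized and on the same grid.
#'
#' @param ictalNorm,interictalNorm normalized [BrainVolume-class]s on one grid.
#' @param mask a [BrainMask-class] on the same grid.
#' @return A [BrainVolume-class] with modality `"diff"`.
#' @export
subtractVolumes <- function(ictalNorm, interictalNorm, mask) {
  stopifnot(is(ictalNorm, "BrainVolume"), is(interictalNorm, "BrainVolume"),
            is(mask, "BrainMask"))
  if (!all(dim(ictalNorm@data) == dim(interictalNorm@data)) ||
      !all(dim(ictalNorm@data) == dim(mask@mask)))
    stop("grid mismatch between ictal, interictal and mask")
  d <- array(0, dim(ictalNorm@data))
  d[mask@mask] <- ictalNorm@data[mask@mask] - interictalNorm@data[mask@mask]
  new("BrainVolume", data = d, spacing = ictalNorm@spacing,
      affine = ictalNorm@affine, modality = "diff")
}

#' Standardize a difference image to z-scores
#'
#' z = (diff - mean) / SD using the mean and sample standard deviation (n - 1
#' denominator) of the difference over all brain voxels. z is 0 outside the
#' mask. Identical inputs give a zero-SD difference, reported as an explicit
#' degenerate-difference error.
#'
#' @param diff the difference [BrainVolume-class].
#' @param mask a [BrainMask-class] with at least 2 voxels.
#' @param zThreshold threshold stored for downstream clustering (default 2).
#' @return A [ZScoreMap-class]; its within-mask mean is 0 and SD is 1.
#' @export
zscoreMap <- function(diff, mask, zThreshold = 2) {
  stopifnot(is(diff, "BrainVolume"), is(mask, "BrainMask"))
  if (mask@nVoxels < 2L) stop("mask must contain at least 2 voxels")
  v <- diff@data[mask@mask]
  mu <- mean(v)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop("degenerate difference: zero standard deviation over the mask")
  z <- array(0, dim(diff@data))
  z[mask@mask] <- (v - mu) / s
  zvol <- new("BrainVolume", data = z, spacing = diff@spacing,
              affine = diff@affine, modality = "z")
  new("ZScoreMap", z = zvol, mask = mask, meanDiff = mu, sdDiff = s,
      zThreshold = zThreshold)
}

#' Extract supra-threshold clusters from a z-score map
#'
#' Connected components of the voxel set strictly exceeding the z threshold
#' ("exceeding" read literally: z = threshold exactly is not significant).
#' Components smaller than `minSizeVoxels` are dropped. Clusters are returned
#' sorted by descending peak z; ties broken by larger size, then by
#' lexicographically smallest peak voxel index. With `negate = TRUE` the
#' same extraction runs on -z (hypoperfusion); such clusters are for
#' reporting only and never enter [callEZ()].
#'
#' @param zmap a [ZScoreMap-class].
#' @param connectivity 6, 18 or 26 (default 26).
#' @param minSizeVoxels minimum cluster size (default 5, suppressing
#'   single-voxel noise).
#' @param negate extract z < -threshold instead of z > threshold.
#' @return List of [Cluster-class] (possibly empty).
#' @export
thresholdClusters <- function(zmap, connectivity = 26L, minSizeVoxels = 5L,
                              negate = FALSE) {
  stopifnot(is(zmap, "ZScoreMap"))
  z <- zmap@z@data
  if (negate) z <- -z
  supra <- (z > zmap@zThreshold) & zmap@mask@mask
  lab <- labelComponents(supra, connectivity = as.integer(connectivity))
  n <- max(lab)
  if (n == 0L) return(list())
  voxVolMl <- prod(zmap@z@spacing) / 1000
  clusters <- list()
  for (ci in seq_len(n)) {
    lin <- which(lab == ci)
    if (length(lin) < minSizeVoxels) next
    ijk <- arrayInd(lin, dim(z))          # 1-based
    zv <- z[lin]
    zmax <- max(zv)
    peaks <- ijk[zv == zmax, , drop = FALSE]
    # lexicographically smallest (i, j, k) among tied maxima
    pk <- peaks[order(peaks[, 1], peaks[, 2], peaks[, 3])[1], ]
    pk0 <- as.integer(pk - 1L)
    world <- as.numeric(voxelToWorld(zmap@z@affine, pk0))
    clusters[[length(clusters) + 1L]] <- new("Cluster",
      voxelIndices = ijk - 1L, peakZ = zmax, peakVoxel = pk0,
      peakWorld = world, sizeVoxels = length(lin),
      sizeMl = length(lin) * voxVolMl,
      side = sideFromWorldX(world[1]))
  }
  if (!length(clusters)) return(list())
  pz <- vapply(clusters, function(cl) cl@peakZ, numeric(1))
  sz <- vapply(clusters, function(cl) cl@sizeVoxels, integer(1))
  pv <- t(vapply(clusters, function(cl) cl@peakVoxel, integer(3)))
  ord <- order(-pz, -sz, pv[, 1], pv[, 2], pv[, 3])
  clusters[ord]
}

sideFromWorldX <- function(x) {
  if (x > 0) "right" else if (x < 0) "left" else "midline"
}

#' Attribute a cluster to an atlas region
#'
#' The region of the voxel with the highest z-score defines the cluster's
#' label (even when the cluster spans several lobes); the side comes from the
#' sign of the peak voxel's world x-coordinate (RAS+: positive x is right).
#'
#' @param cluster a [Cluster-class].
#' @param atlas a [LobeAtlas-class] on the same grid as the z map the cluster
#'   came from.
#' @return The cluster with `regionLabel` (and `side`) filled in; a peak on
#'   an unlabeled atlas voxel yields `"unlabeled"` with a warning.
#' @export
labelClusterRegion <- function(cluster, atlas) {
  stopifnot(is(cluster, "Cluster"), is(atlas, "LobeAtlas"))
  pk <- cluster@peakVoxel + 1L
  code <- as.character(as.integer(atlas@volume@data[pk[1], pk[2], pk[3]]))
  if (!code %in% names(atlas@labels) || code == "0") {
    warning("cluster peak voxel falls outside atlas labels; region 'unlabeled'")
    cluster@regionLabel <- "unlabeled"
  } else {
    cluster@regionLabel <- unname(atlas@labels[code])
  }
  cluster@side <- sideFromWorldX(cluster@peakWorld[1])
  cluster
}

#' Call the epileptogenic-zone candidate from extracted clusters
#'
#' The first cluster under the [thresholdClusters()] ordering (highest peak
#' z) is the EZ candidate; all others are propagation areas. With more than
#' one cluster the call carries a review flag: clinically, multiplicity is
#' adjudicated with the radiotracer injection time and clinical findings,
#' which this package deliberately does not automate. An empty cluster list
#' yields a valid "no significant hyperperfusion" call (the discordant
#' category when no hyperperfused area is observed), not an error.
#'
#' @param clusters list of [Cluster-class] as returned by
#'   [thresholdClusters()].
#' @return An [EZCall-class].
#' @export
callEZ <- function(clusters) {
  if (!length(clusters))
    return(new("EZCall", primary = NULL, propagation = list(),
               nClusters = 0L, reviewFlag = FALSE,
               status = "no_hyperperfusion"))
  new("EZCall", primary = clusters[[1]],
      propagation = clusters[-1],
      nClusters = length(clusters),
      reviewFlag = length(clusters) > 1L,
      status = "ok")
}

#' Run the full subtraction analysis on an ictal/interictal pair
#'
#' Composes the pipeline: brain mask on the ictal volume; symmetrized rigid
#' registration of the interictal to the ictal volume (both volumes serve as
#' source and target, and the two estimates are averaged in parameter space);
#' resampling onto the ictal grid; whole-brain normalization of both volumes;
#' voxel-wise subtraction; z-score standardization; threshold/cluster
#' extraction; optional atlas labeling; and the EZ call. The provenance
#' record captures every parameter and the registration result.
#'
#' @param ictal,interictal [BrainVolume-class]s.
#' @param config a [siscomConfig()] list (thresholds, connectivity, mask
#'   fraction, target mean, registration settings, `doRegister`).
#' @param atlas optional [LobeAtlas-class] on the ictal grid for lobe
#'   attribution.
#' @return A list with elements `zmap` ([ZScoreMap-class]), `clusters`,
#'   `ez` ([EZCall-class]), `hypoClusters` (when `config$reportHypo`),
#'   `registration` (a [RegistrationResult-class] or NULL) and `provenance`
#'   (named list of all parameters).
#' @examples
#' \donttest{
#' ph <- phantomSpec(seed = 11L)
#' sim <- simulateCase(ph)
#' res <- runSiscom(sim$ictal, sim$interictal,
#'                  config = siscomConfig(doRegister = FALSE))
#' res$ez
#' }
#' @export
runSiscom <- function(ictal, interictal, config = siscomConfig(),
                      atlas = NULL) {
  stopifnot(is(ictal, "BrainVolume"), is(interictal, "BrainVolume"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  maskIctal <- stage("mask", computeBrainMask(ictal, config$maskFraction))

  reg <- NULL
  if (isTRUE(config$doRegister)) {
    regcfg <- registrationConfig(nBins = config$nBins,
                                 schedule = config$schedule,
                                 maxit = config$maxit,
                                 reltol = config$reltol,
                                 maskFraction = config$maskFraction)
    reg <- stage("register",
                 registerRigidSymmetric(ictal, interictal, regcfg))
    t <- reg@transform
  } else {
    t <- rigidTransform()
  }

  interR <- stage("resample", applyTransform(interictal, t, ictal))
  support <- resampleSupport(interR)
  analysisMask <- brainMask(maskIctal@mask & support)
  if (analysisMask@nVoxels < 2L)
    stop("[resample] registered volumes share too few brain voxels")

  ictalN <- stage("normalize",
                  normalizeGlobal(ictal, analysisMask, config$targetMean))
  interN <- stage("normalize",
                  normalizeGlobal(interR, analysisMask, config$targetMean))
  diffV <- stage("subtract", subtractVolumes(ictalN, interN, analysisMask))
  zmap <- stage("zscore", zscoreMap(diffV, analysisMask, config$zThreshold))
  clusters <- stage("cluster",
                    thresholdClusters(zmap, config$connectivity,
                                      config$minClusterVoxels))
  if (!is.null(atlas))
    clusters <- lapply(clusters, labelClusterRegion, atlas = atlas)
  ez <- stage("call", callEZ(clusters))

  out <- list(zmap = zmap, clusters = clusters, ez = ez,
              registration = reg)
  if (isTRUE(config$reportHypo))
    out$hypoClusters <- thresholdClusters(zmap, config$connectivity,
                                          config$minClusterVoxels,
                                          negate = TRUE)
  out$provenance <- list(
    package = "siscom",
    version = as.character(utils::packageVersion("siscom")),
    config = unclass(config),
    maskVoxels = analysisMask@nVoxels,
    meanDiff = zmap@meanDiff,
    sdDiff = zmap@sdDiff,
    nClusters = length(clusters),
    registration = if (!is.null(reg)) list(
      rotations = reg@transform@rotations,
      translations = reg@transform@translations,
      center = reg@transform@center,
      finalMetric = reg@finalMetric,
      metricAtIdentity = reg@metricAtIdentity,
      nIterations = reg@nIterations,
      converged = reg@converged) else "skipped")
  out
}

#' Tabulate clusters
#'
#' @param clusters list of [Cluster-class] (ordered as returned by
#'   [thresholdClusters()]).
#' @return A data.frame with one row per cluster: id, role
#'   (primary/propagation), peak z, 0-based peak voxel indices, peak world mm,
#'   sizes, region and side.
#' @export
clusterTable <- function(clusters) {
  if (!length(clusters))
    return(data.frame(cluster = integer(), role = character(),
                      peak_z = numeric(), peak_i = integer(),
                      peak_j = integer(), peak_k = integer(),
                      peak_x_mm = numeric(), peak_y_mm = numeric(),
                      peak_z_mm = numeric(), size_voxels = integer(),
                      size_ml = numeric(), region = character(),
                      side = character()))
  data.frame(
    cluster = seq_along(clusters),
    role = c("primary", rep("propagation", length(clusters) - 1L)),
    peak_z = vapply(clusters, function(cl) cl@peakZ, numeric(1)),
    peak_i = vapply(clusters, function(cl) cl@peakVoxel[1], integer(1)),
    peak_j = vapply(clusters, function(cl) cl@peakVoxel[2], integer(1)),
    peak_k = vapply(clusters, function(cl) cl@peakVoxel[3], integer(1)),
    peak_x_mm = vapply(clusters, function(cl) cl@peakWorld[1], numeric(1)),
    peak_y_mm = vapply(clusters, function(cl) cl@peakWorld[2], numeric(1)),
    peak_z_mm = vapply(clusters, function(cl) cl@peakWorld[3], numeric(1)),
    size_voxels = vapply(clusters, function(cl) cl@sizeVoxels, integer(1)),
    size_ml = vapply(clusters, function(cl) cl@sizeMl, numeric(1)),
    region = vapply(clusters, function(cl) cl@regionLabel, character(1)),
    side = vapply(clusters, function(cl) cl@side, character(1)))
}
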