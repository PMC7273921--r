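#' Pipeline configuration
#'
#' Bundles every tunable of the subtraction pipeline. All values are
#' serializable: [saveConfig()]/[loadConfig()] round-trip a config through a
#' plain-text YAML file, and command-line flags override config values which
#' override these defaults.
#'
#' @param zThreshold significance threshold on the z map; voxels strictly
#'   exceeding it are significant (default 2).
#' @param minClusterVoxels minimum cluster size in voxels (default 5).
#' @param connectivity cluster connectivity: 6, 18 or 26 (default 26).
#' @param maskFraction brain-mask threshold as a fraction of the robust
#'   (99th percentile) maximum, in (0, 1) (default 0.3).
#' @param targetMean whole-brain normalization target mean (default 100; the
#'   z map is invariant to it).
#' @param nBins registration joint-histogram bins (default 32).
#' @param schedule registration multiresolution factors (default 4, 2, 1).
#' @param maxit registration iteration caps per level.
#' @param reltol registration convergence tolerance.
#' @param doRegister run rigid registration (default TRUE); set FALSE for
#'   pairs already sampled aligned on one grid.
#' @param reportHypo additionally extract hypoperfusion (z < -threshold)
#'   clusters for reporting (they never enter the EZ call).
#' @param seed integer seed recorded in provenance (the pipeline itself is
#'   deterministic; the seed matters for simulation).
#' @return A named list with class `"siscomConfig"`.
#' @examples
#' cfg <- siscomConfig(zThreshold = 2.5)
#' cfg$zThreshold
#' @export
siscomConfig <- function(zThreshold = 2, minClusterVoxels = 5L,
                         connectivity = 26L, maskFraction = 0.3,
                         targetMean = 100, nBins = 32L,
                         schedule = c(4L, 2L, 1L),
                         maxit = c(500L, 500L, 500L), reltol = 1e-10,
                         doRegister = TRUE, reportHypo = FALSE,
                         seed = 1L) {
  stopifnot(zThreshold > 0, minClusterVoxels >= 1,
            connectivity %in% c(6L, 18L, 26L),
            maskFraction > 0, maskFraction < 1,
            targetMean > 0, nBins >= 2, all(schedule >= 1), reltol > 0)
  structure(list(zThreshold = zThreshold,
                 minClusterVoxels = as.integer(minClusterVoxels),
                 connectivity = as.integer(connectivity),
                 maskFraction = maskFraction, targetMean = targetMean,
                 nBins = as.integer(nBins),
                 schedule = as.integer(schedule),
                 maxit = as.integer(rep_len(maxit, length(schedule))),
                 reltol = reltol, doRegister = isTRUE(doRegister),
                 reportHypo = isTRUE(reportHypo), seed = as.integer(seed)),
            class = "siscomConfig")
}

#' @rdname siscomConfig
#' @param config a `siscomConfig` list.
#' @param path YAML file path.
#' @export
saveConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname siscomConfig
#' @export
loadConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(siscomConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(siscomConfig, raw)
}
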