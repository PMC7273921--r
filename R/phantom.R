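# SPECT-like brain-perfusion phantom simulator with known ground truth.
#
# What it emulates: an ellipsoidal brain with a smooth (+-10% low-order
# polynomial) baseline perfusion pattern; focal ictal hyperperfusion as
# spheres of relative amplitude (1 + a); an effective spatial resolution
# imposed by a Gaussian PSF (default 7.65 mm FWHM, the reconstruction filter
# width typical of clinical perfusion SPECT); post-reconstruction noise
# (Gaussian, default SD 5% of baseline, or Poisson for raw-count flavor);
# and a small rigid patient repositioning between the two scans.

#' Specify a simulated ictal/interictal SPECT pair
#'
#' Defaults describe a clinically realistic study: ~4 mm sampling, 7.65 mm
#' FWHM effective resolution, Gaussian noise at 5\% of baseline, one
#' left-temporal focus of +40\% relative amplitude and 8 mm radius, and no
#' misalignment unless requested.
#'
#' @param shape grid dimensions (default 40 x 48 x 40).
#' @param spacing voxel size mm (default 4).
#' @param brainSemiaxes ellipsoid semiaxes mm (default 60, 75, 55).
#' @param baselineIntensity baseline counts (default 100).
#' @param foci list of `list(center, radius, amplitude)`; default one
#'   left-temporal focus at (-35, 5, -20) mm, radius 8 mm, amplitude 0.4.
#' @param psfFwhm Gaussian PSF FWHM mm (default 7.65).
#' @param noiseModel `list(type = "gaussian", sd_fraction = 0.05)` (default),
#'   `list(type = "poisson", scale = ...)` or `list(type = "none")`.
#' @param misalignment [RigidTransform-class] applied to the ictal volume, or
#'   NULL (default) for an aligned pair.
#' @param seed integer seed; the simulation is bit-reproducible from it.
#' @return A validated [PhantomSpec-class].
#' @export
phantomSpec <- function(shape = c(40L, 48L, 40L), spacing = c(4, 4, 4),
                        brainSemiaxes = c(60, 75, 55),
                        baselineIntensity = 100,
                        foci = list(list(center = c(-35, 5, -20),
                                         radius = 8, amplitude = 0.4)),
                        psfFwhm = 7.65,
                        noiseModel = list(type = "gaussian", sd_fraction = 0.05),
                        misalignment = NULL, seed = 1L) {
  new("PhantomSpec", shape = as.integer(rep_len(shape, 3L)),
      spacing = rep_len(as.numeric(spacing), 3L),
      brainSemiaxes = rep_len(as.numeric(brainSemiaxes), 3L),
      baselineIntensity = baselineIntensity, foci = foci,
      psfFwhm = psfFwhm, noiseModel = noiseModel,
      misalignment = misalignment, seed = as.integer(seed))
}

# world coordinates of every voxel center for a centered grid
phantomGridWorld <- function(spec) {
  aff <- diag(c(spec@spacing, 1))
  aff[1:3, 4] <- -(spec@shape - 1) / 2 * spec@spacing
  xs <- (seq_len(spec@shape[1]) - 1) * spec@spacing[1] + aff[1, 4]
  ys <- (seq_len(spec@shape[2]) - 1) * spec@spacing[2] + aff[2, 4]
  zs <- (seq_len(spec@shape[3]) - 1) * spec@spacing[3] + aff[3, 4]
  list(affine = aff, xs = xs, ys = ys, zs = zs)
}

# separable Gaussian blur with zero padding, kernel truncated at 4 sigma
gaussianBlur <- function(x, sigmaVox) {
  for (ax in 1:3) {
    s <- sigmaVox[ax]
    if (s <= 0) next
    n <- dim(x)[ax]
    half <- max(1L, ceiling(4 * s))
    k <- stats::dnorm(-half:half, sd = s)
    k <- k / sum(k)
    K <- matrix(0, n, n)
    for (o in -half:half) {
      idx <- seq_len(n)
      tgt <- idx + o
      keep <- tgt >= 1L & tgt <= n
      K[cbind(idx[keep], tgt[keep])] <- k[o + half + 1L]
    }
    x <- aperm(x, c(ax, setdiff(1:3, ax)))
    dd <- dim(x)
    x <- array(K %*% matrix(x, dd[1]), dd)
    x <- aperm(x, order(c(ax, setdiff(1:3, ax))))
  }
  x
}

#' Simulate an ictal/interictal SPECT-like pair with ground truth
#'
#' The interictal volume is an ellipsoidal brain at baseline intensity with a
#' fixed smooth polynomial modulation (+-10\%); the ictal volume is identical
#' except inside each focus sphere, where intensity is scaled by
#' (1 + amplitude). Both are blurred by the Gaussian PSF and then noised
#' independently (seeded); the ictal volume is finally resampled through the
#' requested misalignment, emulating patient repositioning. Bit-reproducible
#' from `spec@seed`; the caller's RNG state is left untouched.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with `ictal` and `interictal` [BrainVolume-class]s and
#'   `truth`, a [PhantomTruth-class] (focus centres in the canonical frame and
#'   mapped into the ictal frame, per-focus masks, the applied misalignment,
#'   and a synthetic lobe atlas).
#' @export
simulateCase <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  g <- phantomGridWorld(spec)
  a <- spec@brainSemiaxes
  # normalized coordinates over the full grid
  u <- array(rep(g$xs / a[1], times = spec@shape[2] * spec@shape[3]), spec@shape)
  v <- array(rep(rep(g$ys / a[2], each = spec@shape[1]), times = spec@shape[3]),
             spec@shape)
  w <- array(rep(g$zs / a[3], each = spec@shape[1] * spec@shape[2]), spec@shape)
  brain <- (u^2 + v^2 + w^2) <= 1

  # fixed low-order polynomial modulation, scaled to +-10%
  poly <- 0.5 * v + 0.3 * u * w - 0.4 * w^2 + 0.2 * u^2 - 0.25 * v * w
  poly <- poly / max(abs(poly[brain]))
  base <- spec@baselineIntensity * (1 + 0.1 * poly)
  inter <- array(0, spec@shape)
  inter[brain] <- base[brain]

  ictal <- inter
  focusMasks <- list()
  for (f in spec@foci) {
    dx <- (u * a[1] - f$center[1])
    dy <- (v * a[2] - f$center[2])
    dz <- (w * a[3] - f$center[3])
    fm <- (dx^2 + dy^2 + dz^2) <= f$radius^2 & brain
    focusMasks[[length(focusMasks) + 1L]] <- fm
    ictal[fm] <- ictal[fm] * (1 + f$amplitude)
  }
  if (length(focusMasks) > 1L) {
    tot <- Reduce(`+`, lapply(focusMasks, as.numeric))
    if (any(tot > 1)) stop("focus masks must be disjoint")
  }

  sigmaVox <- (spec@psfFwhm / (2 * sqrt(2 * log(2)))) / spec@spacing
  if (spec@psfFwhm > 0) {
    inter <- gaussianBlur(inter, sigmaVox)
    ictal <- gaussianBlur(ictal, sigmaVox)
  }

  # seeded noise, isolated from the caller's RNG
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(oldSeed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(spec@seed)
  nm <- spec@noiseModel
  if (nm$type == "gaussian" && nm$sd_fraction > 0) {
    sdn <- nm$sd_fraction * spec@baselineIntensity
    inter <- inter + array(stats::rnorm(length(inter), 0, sdn), spec@shape)
    ictal <- ictal + array(stats::rnorm(length(ictal), 0, sdn), spec@shape)
    inter[inter < 0] <- 0
    ictal[ictal < 0] <- 0
  } else if (nm$type == "poisson") {
    inter <- array(stats::rpois(length(inter), nm$scale * pmax(inter, 0)) / nm$scale,
                   spec@shape)
    ictal <- array(stats::rpois(length(ictal), nm$scale * pmax(ictal, 0)) / nm$scale,
                   spec@shape)
  }

  interVol <- new("BrainVolume", data = inter, spacing = spec@spacing,
                  affine = g$affine, modality = "interictal")
  ictalVol <- new("BrainVolume", data = ictal, spacing = spec@spacing,
                  affine = g$affine, modality = "ictal")

  mis <- spec@misalignment
  if (is.null(mis)) mis <- rigidTransform()
  centers <- lapply(spec@foci, function(f) as.numeric(f$center))
  if (any(mis@rotations != 0) || any(mis@translations != 0)) {
    ictalVol <- applyTransform(ictalVol, mis, interVol)
    ictalVol@modality <- "ictal"
    M <- rigidMatrix(mis)
    centersIctal <- lapply(centers, function(p)
      as.numeric((M %*% c(p, 1))[1:3]))
  } else {
    centersIctal <- centers
  }

  truth <- new("PhantomTruth", focusCenters = centers,
               focusCentersIctal = centersIctal, focusMasks = focusMasks,
               appliedMisalignment = mis,
               atlas = makeSyntheticAtlas(spec))
  list(ictal = ictalVol, interictal = interVol, truth = truth)
}

#' Partition the phantom brain into synthetic left/right pseudo-lobes
#'
#' Deterministic geometric rules on ellipsoid-normalized coordinates
#' (u, v, w) = (x, y, z) / semiaxes assign every brain voxel exactly one of
#' five lobes: frontal (anterior, v >= 0.30), occipital (posterior,
#' v <= -0.45), and in the middle band temporal (inferior, w <= -0.10),
#' insular (deep, |u| < 0.35 and w <= 0.35) or parietal (the superior/lateral
#' remainder). The rules use |u| only, so labels are mirror-symmetric under
#' an x-flip; laterality is derived downstream from the world x sign.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [LobeAtlas-class] with codes 1..5 (frontal, temporal, parietal,
#'   occipital, insular) and 0 outside the brain.
#' @export
makeSyntheticAtlas <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  g <- phantomGridWorld(spec)
  a <- spec@brainSemiaxes
  u <- array(rep(g$xs / a[1], times = spec@shape[2] * spec@shape[3]), spec@shape)
  v <- array(rep(rep(g$ys / a[2], each = spec@shape[1]), times = spec@shape[3]),
             spec@shape)
  w <- array(rep(g$zs / a[3], each = spec@shape[1] * spec@shape[2]), spec@shape)
  brain <- (u^2 + v^2 + w^2) <= 1
  lab <- array(0L, spec@shape)
  lab[brain & v >= 0.30] <- 1L                                   # frontal
  lab[brain & v <= -0.45] <- 4L                                  # occipital
  mid <- brain & v > -0.45 & v < 0.30
  lab[mid & w <= -0.10] <- 2L                                    # temporal
  lab[mid & w > -0.10 & abs(u) < 0.35 & w <= 0.35] <- 5L         # insular
  lab[mid & lab == 0L] <- 3L                                     # parietal
  vol <- new("BrainVolume", data = lab, spacing = spec@spacing,
             affine = g$affine, modality = "atlas")
  new("LobeAtlas", volume = vol,
      labels = c("1" = "frontal", "2" = "temporal", "3" = "parietal",
                 "4" = "occipital", "5" = "insular"))
}
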