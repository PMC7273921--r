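test_that("normalizeGlobal hits the target mean and is scale invariant", {
  sim <- simulateCase(phantomSpec(seed = 51L))
  vol <- sim$interictal
  mk <- computeBrainMask(vol)

  out <- normalizeGlobal(vol, mk, targetMean = 100)
  expect_equal(mean(volData(out)[maskArray(mk)]), 100, tolerance = 1e-6)

  # constant 50 inside mask -> constant 100
  const <- brainVolume(array(50, dim(vol)), volSpacing(vol), volAffine(vol))
  outc <- normalizeGlobal(const, mk, 100)
  expect_equal(unique(as.numeric(volData(outc)[maskArray(mk)])), 100)

  # multiplying the input by any positive c gives the identical output
  for (c in c(0.2, 3.7)) {
    scaled <- brainVolume(volData(vol) * c, volSpacing(vol), volAffine(vol))
    expect_equal(volData(normalizeGlobal(scaled, mk, 100)), volData(out),
                 tolerance = 1e-12)
  }

  neg <- brainVolume(array(-1, dim(vol)), volSpacing(vol), volAffine(vol))
  expect_error(normalizeGlobal(neg, mk), "non-positive")
})

test_that("subtraction is exact, masked and antisymmetric", {
  sim <- simulateCase(phantomSpec(seed = 52L))
  a <- sim$ictal; b <- sim$interictal
  mk <- computeBrainMask(b)

  d0 <- subtractVolumes(b, b, mk)
  expect_true(all(volData(d0) == 0))

  shifted <- brainVolume(volData(b) + 10, volSpacing(b), volAffine(b))
  d10 <- subtractVolumes(shifted, b, mk)
  expect_equal(volData(d10)[maskArray(mk)],
               rep(10, nMaskVoxels(mk)), tolerance = 1e-12)
  expect_true(all(volData(d10)[!maskArray(mk)] == 0))

  dab <- subtractVolumes(a, b, mk)
  dba <- subtractVolumes(b, a, mk)
  expect_equal(volData(dab), -volData(dba))
  expect_identical(volModality(dab), "diff")

  small <- brainVolume(array(0, c(4, 4, 4)))
  expect_error(subtractVolumes(a, small, mk), "grid mismatch")
})

test_that("zscoreMap standardizes exactly", {
  # 3-voxel mask with differences {1, 2, 3}: mean 2, sample SD 1
  x <- array(0, c(3, 3, 3))
  x[1, 1, 1] <- 1; x[2, 1, 1] <- 2; x[3, 1, 1] <- 3
  m <- array(FALSE, c(3, 3, 3)); m[1:3, 1, 1] <- TRUE
  zm <- zscoreMap(brainVolume(x), brainMask(m))
  expect_equal(zm@meanDiff, 2)
  expect_equal(zm@sdDiff, 1)
  expect_equal(volData(zm)[1:3, 1, 1], c(-1, 0, 1))
  expect_true(all(volData(zm)[!m] == 0))

  # identical inputs give an explicit degenerate-difference error
  zero <- brainVolume(array(0, c(3, 3, 3)))
  expect_error(zscoreMap(zero, brainMask(m)), "degenerate difference")

  # seeded Gaussian difference: within-mask moments exactly standardized
  set.seed(53)
  g <- array(rnorm(22^3, 5, 2.4), c(22, 22, 22))
  mk <- brainMask(array(TRUE, c(22, 22, 22)))
  zg <- zscoreMap(brainVolume(g), mk)
  zv <- volData(zg)[maskArray(mk)]
  expect_lt(abs(mean(zv)), 1e-6)
  expect_lt(abs(sd(zv) - 1), 1e-6)
  expect_equal(zg@meanDiff, mean(g))
  expect_equal(zg@sdDiff, sd(g))
})

test_that("threshold is strict and ordering/tie-breaking is total", {
  z <- array(0, c(10, 10, 10))
  z[5, 5, 5] <- 2.0
  expect_length(thresholdClusters(zmapFromArray(z), minSizeVoxels = 1L), 0)

  z[5, 5, 5] <- 2.5
  cl <- thresholdClusters(zmapFromArray(z), minSizeVoxels = 1L)
  expect_length(cl, 1)
  expect_equal(cl[[1]]@peakZ, 2.5)
  expect_identical(cl[[1]]@sizeVoxels, 1L)
  expect_identical(cl[[1]]@peakVoxel, c(4L, 4L, 4L))  # 0-based

  # min size filter
  expect_length(thresholdClusters(zmapFromArray(z), minSizeVoxels = 5L), 0)

  # equal peaks: larger cluster first, then smallest lexicographic peak index
  z2 <- array(0, c(12, 12, 12))
  z2[2:3, 2, 2] <- 3          # size 2
  z2[8, 8, 8] <- 3            # size 1
  cl2 <- thresholdClusters(zmapFromArray(z2), minSizeVoxels = 1L)
  expect_identical(vapply(cl2, function(c) c@sizeVoxels, integer(1)), c(2L, 1L))

  z3 <- array(0, c(12, 12, 12))
  z3[9, 9, 9] <- 3
  z3[2, 2, 2] <- 3
  cl3 <- thresholdClusters(zmapFromArray(z3), minSizeVoxels = 1L)
  expect_identical(cl3[[1]]@peakVoxel, c(1L, 1L, 1L))

  # size in mL uses the voxel volume
  cl4 <- thresholdClusters(zmapFromArray(z, spacing = 4), minSizeVoxels = 1L)
  expect_equal(cl4[[1]]@sizeMl, 64 / 1000)
})

test_that("two separated blobs give two clusters matching the oracle", {
  z <- array(0, c(16, 16, 16))
  z[2:4, 2:4, 2:4] <- 3
  z[10:12, 10:12, 10:12] <- 3
  cl <- thresholdClusters(zmapFromArray(z), minSizeVoxels = 1L)
  expect_length(cl, 2)
  lab <- oracleLabel(z > 2, 26L)
  expect_identical(max(lab), 2L)
})

test_that("cluster extraction agrees with the union-find oracle", {
  set.seed(54)
  for (trial in 1:15) {
    conn <- sample(c(6L, 26L), 1)
    z <- array(rnorm(16^3), c(16, 16, 16))
    supra <- z > 2
    ours <- relabelCanonical(labelComponents(supra, conn))
    theirs <- relabelCanonical(oracleLabel(supra, conn))
    expect_identical(ours, theirs)
  }
})

test_that("cluster region labeling follows the peak voxel", {
  spec <- phantomSpec(seed = 55L)
  atlas <- makeSyntheticAtlas(spec)
  av <- atlas@volume

  # a cluster whose peak sits at a known temporal-lobe voxel (left x)
  pk <- siscom:::worldToVoxel(volAffine(av), c(-35, 5, -20))
  pk <- as.integer(round(pk))
  z <- array(0, dim(av))
  z[pk[1] + 1, pk[2] + 1, pk[3] + 1] <- 4
  z[pk[1] + 2, pk[2] + 1, pk[3] + 1] <- 3  # member in possibly another lobe
  zm <- zmapFromArray(z, spacing = volSpacing(av)[1])
  zm@z@affine <- volAffine(av)
  cl <- thresholdClusters(zm, minSizeVoxels = 1L)[[1]]
  cl <- labelClusterRegion(cl, atlas)
  expect_identical(cl@regionLabel, "temporal")
  expect_identical(cl@side, "left")

  # peak on background label -> unlabeled with warning
  z0 <- array(0, dim(av))
  z0[1, 1, 1] <- 5
  zm0 <- zmapFromArray(z0, spacing = volSpacing(av)[1])
  zm0@z@affine <- volAffine(av)
  cl0 <- thresholdClusters(zm0, minSizeVoxels = 1L)[[1]]
  expect_warning(cl0 <- labelClusterRegion(cl0, atlas), "unlabeled")
  expect_identical(cl0@regionLabel, "unlabeled")
})

test_that("EZ call ranks clusters and flags multiplicity", {
  z <- array(0, c(16, 16, 16))
  z[2:3, 2:3, 2:3] <- 5.1
  z[8:9, 8:9, 8:9] <- 3.2
  z[13:14, 13:14, 13:14] <- 2.4
  cl <- thresholdClusters(zmapFromArray(z), minSizeVoxels = 1L)
  ez <- callEZ(cl)
  expect_identical(ez@status, "ok")
  expect_equal(ez@primary@peakZ, 5.1)
  expect_equal(vapply(ez@propagation, function(c) c@peakZ, numeric(1)),
               c(3.2, 2.4))
  expect_true(ez@reviewFlag)
  expect_identical(ez@nClusters, 3L)

  one <- callEZ(cl[1])
  expect_false(one@reviewFlag)
  expect_length(one@propagation, 0)

  none <- callEZ(list())
  expect_identical(none@status, "no_hyperperfusion")
  expect_identical(none@nClusters, 0L)
  expect_null(none@primary)
})

test_that("full pipeline localizes a focus and respects antisymmetry", {
  cfg <- siscomConfig(doRegister = FALSE)
  sim <- simulateCase(phantomSpec(seed = 56L))
  res <- runSiscom(sim$ictal, sim$interictal, cfg,
                   atlas = sim$truth@atlas)
  expect_identical(res$ez@status, "ok")
  d <- sqrt(sum((res$ez@primary@peakWorld -
                 sim$truth@focusCenters[[1]])^2))
  expect_lt(d, 8)
  expect_identical(res$ez@primary@regionLabel, "temporal")
  expect_identical(res$ez@primary@side, "left")

  # swapping the roles negates the z map (on the common mask)
  mk <- res$zmap@mask
  tm <- res$provenance$config$targetMean
  ni <- normalizeGlobal(sim$ictal, mk, tm)
  nj <- normalizeGlobal(sim$interictal, mk, tm)
  zab <- zscoreMap(subtractVolumes(ni, nj, mk), mk)
  zba <- zscoreMap(subtractVolumes(nj, ni, mk), mk)
  expect_equal(volData(zba), -volData(zab), tolerance = 1e-9)
  expect_equal(zba@meanDiff, -zab@meanDiff)

  # provenance carries the settings
  expect_identical(res$provenance$config$zThreshold, 2)
  expect_identical(res$provenance$registration, "skipped")
})

test_that("pipeline surfaces stage-named errors", {
  sim <- simulateCase(phantomSpec(seed = 57L, foci = list(),
                                  noiseModel = list(type = "none")))
  expect_error(runSiscom(sim$ictal, sim$interictal),
               "\\[zscore\\] degenerate difference")
})

test_that("hypoperfusion clusters are reported but never called", {
  cfg <- siscomConfig(doRegister = FALSE, reportHypo = TRUE)
  sim <- simulateCase(phantomSpec(seed = 58L))
  res <- runSiscom(sim$ictal, sim$interictal, cfg)
  expect_true(!is.null(res$hypoClusters))
  # the EZ call only ever sees hyperperfusion clusters
  expect_identical(res$ez@nClusters, length(res$clusters))
})

test_that("cluster table matches the cluster objects", {
  cfg <- siscomConfig(doRegister = FALSE)
  sim <- simulateCase(phantomSpec(seed = 59L))
  res <- runSiscom(sim$ictal, sim$interictal, cfg)
  tab <- clusterTable(res$clusters)
  expect_identical(nrow(tab), length(res$clusters))
  expect_identical(tab$role[1], "primary")
  expect_equal(tab$peak_z, vapply(res$clusters, function(c) c@peakZ, numeric(1)))
  expect_identical(clusterTable(list())$cluster, integer())
})
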