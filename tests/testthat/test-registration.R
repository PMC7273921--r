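test_that("rigid transforms compose with their inverse to identity", {
  set.seed(31)
  for (i in 1:20) {
    t <- rigidTransform(runif(3, -0.3, 0.3), runif(3, -15, 15),
                        center = runif(3, -20, 20))
    ti <- invertTransform(t)
    M <- rigidMatrix(t) %*% rigidMatrix(ti)
    expect_lt(max(abs(M - diag(4))), 1e-9)
    # round trip through the 6-parameter extraction
    t2 <- siscom:::rigidFromMatrix(rigidMatrix(t), center = t@center)
    expect_equal(t2@rotations, t@rotations, tolerance = 1e-6)
    expect_equal(t2@translations, t@translations, tolerance = 1e-6)
  }
})

test_that("transform sidecar serialization round-trips", {
  t <- rigidTransform(c(0.01, -0.02, 0.03), c(5.5, -3.25, 2), c(1, 2, 3))
  path <- tempfile(fileext = ".txt")
  saveTransform(t, path)
  t2 <- loadTransform(path)
  expect_equal(t2@rotations, t@rotations)
  expect_equal(t2@translations, t@translations)
  expect_equal(t2@center, t@center)
  unlink(path)
})

test_that("applyTransform: identity is exact, voxel shift is index shift", {
  sim <- simulateCase(phantomSpec(seed = 41L, noiseModel = list(type = "none")))
  vol <- sim$interictal

  out <- applyTransform(vol, rigidTransform(), vol)
  expect_identical(volData(out)[seq_along(volData(out))],
                   volData(vol)[seq_along(volData(vol))])

  # translation by exactly one voxel along x: interior voxels shift one index
  dx <- volSpacing(vol)[1]
  out1 <- applyTransform(vol, rigidTransform(translations = c(dx, 0, 0)), vol)
  d <- dim(vol)
  expect_equal(volData(out1)[2:d[1], , ], volData(vol)[1:(d[1] - 1), , ],
               tolerance = 1e-12)
})

test_that("applyTransform round trip stays within interpolation error", {
  # a smooth Gaussian blob: second derivatives small on the 4 mm grid, so
  # two trilinear resamplings stay within a 2%-of-range bound
  shape <- c(40L, 40L, 40L)
  vol0 <- brainVolume(array(0, shape), spacing = 4)
  co <- arrayInd(seq_len(prod(shape)), shape) - 1
  w <- cbind(co, 1) %*% t(volAffine(vol0))
  g <- 100 * exp(-rowSums(w[, 1:3]^2) / (2 * 30^2))
  vol <- brainVolume(array(g, shape), spacing = 4, affine = volAffine(vol0))

  t <- rigidTransform(c(0.04, -0.03, 0.06), c(3.3, -2.1, 4.7))
  fwd <- applyTransform(vol, t, vol)
  back <- applyTransform(fwd, invertTransform(t), vol)
  core <- attr(volData(back), "support") &
    array(rowSums(w[, 1:3]^2) < 60^2, shape)
  rng <- diff(range(volData(vol)))
  expect_lt(max(abs(volData(back)[core] - volData(vol)[core])), 0.02 * rng)
})

test_that("mutual information: entropy identity, symmetry, edge cases", {
  sim <- simulateCase(phantomSpec(seed = 43L))
  vol <- sim$interictal
  mk <- computeBrainMask(vol)

  # MI(X, X) equals the marginal entropy of the binned image
  x <- volData(vol)[maskArray(mk)]
  edges <- seq(min(x), max(x), length.out = 33)
  b <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  p <- tabulate(b, 32) / length(x)
  h <- -sum(p[p > 0] * log(p[p > 0]))
  expect_equal(mutualInformation(vol, vol, mk, 32L), h, tolerance = 1e-12)

  # symmetry
  other <- sim$ictal
  expect_equal(mutualInformation(vol, other, mk),
               mutualInformation(other, vol, mk), tolerance = 1e-12)

  # two independent noise fields: MI near 0 at ~1e5 voxels
  set.seed(7)
  a <- brainVolume(array(runif(48^3), c(48, 48, 48)))
  bvol <- brainVolume(array(runif(48^3), c(48, 48, 48)))
  full <- brainMask(array(TRUE, c(48, 48, 48)))
  expect_lt(mutualInformation(a, bvol, full), 0.05)
  expect_gte(mutualInformation(a, bvol, full), 0)

  # constant image inside mask: zero information, with warning
  const <- brainVolume(array(5, dim(vol)), volSpacing(vol), volAffine(vol))
  expect_warning(mi0 <- mutualInformation(vol, const, mk), "constant")
  expect_identical(mi0, 0)
})

test_that("registerRigid recovers a known translation on a smooth phantom", {
  sim <- simulateCase(phantomSpec(seed = 44L, noiseModel = list(type = "none"),
                                  foci = list()))
  v <- sim$interictal
  tt <- rigidTransform(translations = c(5, -3, 2))
  moved <- applyTransform(v, tt, v)
  reg <- registerRigid(moved, v)
  truth <- siscom:::rigidFromMatrix(rigidMatrix(tt),
                                    center = reg@transform@center)
  expect_true(all(abs(reg@transform@translations - truth@translations) < 0.5))
  expect_true(all(abs(reg@transform@rotations - truth@rotations) < 0.01))
  expect_gte(reg@finalMetric, reg@metricAtIdentity)
})

test_that("registerRigid on identical aligned volumes returns identity", {
  sim <- simulateCase(phantomSpec(seed = 45L, noiseModel = list(type = "none"),
                                  foci = list()))
  v <- sim$interictal
  reg <- registerRigid(v, v)
  expect_true(all(abs(reg@transform@rotations) < 1e-3))
  expect_true(all(abs(reg@transform@translations) < 0.1))
  expect_true(reg@converged)
})

test_that("registerRigid recovers a 5 degree rotation under 5% noise", {
  sim <- simulateCase(phantomSpec(seed = 46L))  # 5% Gaussian noise
  v <- sim$interictal
  tt <- rigidTransform(rotations = c(0, 0, 5 * pi / 180))
  moved <- applyTransform(v, tt, v)
  reg <- registerRigid(moved, v)
  truth <- siscom:::rigidFromMatrix(rigidMatrix(tt),
                                    center = reg@transform@center)
  expect_true(all(abs(reg@transform@rotations - truth@rotations) < pi / 180))
  expect_gte(reg@finalMetric, reg@metricAtIdentity)
})

test_that("registration errors on non-overlapping volumes", {
  sim <- simulateCase(phantomSpec(seed = 48L, foci = list()))
  v <- sim$interictal
  far <- brainVolume(volData(v), spacing = volSpacing(v))
  aff <- volAffine(far)
  aff[1:3, 4] <- aff[1:3, 4] + c(1000, 0, 0)  # 1 m away
  far <- brainVolume(volData(v), spacing = volSpacing(v), affine = aff)
  expect_error(registerRigid(v, far), "overlap")
})
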