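# Independent oracles and small fixtures used across the suite.

# Union-find connected-component labeling, independent of the package's
# BFS implementation. Labels ordered by first occurrence in column-major scan.
oracleLabel <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1L, , drop = FALSE]
  if (connectivity == 18L) offs <- offs[rowSums(abs(offs)) <= 2L, , drop = FALSE]
  idx <- which(mask)
  n <- length(mask)
  parent <- seq_len(n)
  find <- function(i) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    while (parent[i] != r) { nxt <- parent[i]; parent[i] <<- r; i <- nxt }
    r
  }
  co <- arrayInd(idx, d)
  d12 <- d[1] * d[2]
  for (r in seq_along(idx)) {
    for (o in seq_len(nrow(offs))) {
      nb <- co[r, ] + offs[o, ]
      if (any(nb < 1L) || any(nb > d)) next
      lin <- (nb[3] - 1L) * d12 + (nb[2] - 1L) * d[1] + nb[1]
      if (mask[lin]) {
        ra <- find(idx[r]); rb <- find(lin)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  lab <- array(0L, d)
  if (length(idx)) {
    roots <- vapply(idx, find, numeric(1))
    lab[idx] <- as.integer(factor(roots, levels = unique(roots)))
  }
  lab
}

# canonical relabeling (ids by first occurrence) so two labelings of the same
# partition compare equal
relabelCanonical <- function(lab) {
  idx <- which(lab > 0L)
  out <- array(0L, dim(lab))
  out[idx] <- as.integer(factor(lab[idx], levels = unique(lab[idx])))
  out
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
# (no ties assumed)
mwEnumerate <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vals <- c(x, y)
  ustat <- function(xi, yi) sum(outer(xi, yi, ">")) + 0.5 * sum(outer(xi, yi, "=="))
  uobs <- ustat(x, y)
  cmb <- utils::combn(nx + ny, nx)
  us <- apply(cmb, 2, function(ix) ustat(vals[ix], vals[-ix]))
  c(U = uobs,
    p = mean(abs(us - nx * ny / 2) >= abs(uobs - nx * ny / 2) - 1e-12))
}

# hard-edged ellipsoid test volume (intensity inner/outer) on a centered grid
ellipsoidVolume <- function(shape = c(24L, 24L, 24L), spacing = 4,
                            semiaxes = c(36, 40, 32), inner = 100, outer = 0) {
  vol <- brainVolume(array(outer, shape), spacing = spacing)
  aff <- volAffine(vol)
  co <- arrayInd(seq_len(prod(shape)), shape) - 1
  w <- cbind(co, 1) %*% t(aff)
  inside <- (w[, 1] / semiaxes[1])^2 + (w[, 2] / semiaxes[2])^2 +
    (w[, 3] / semiaxes[3])^2 <= 1
  d <- volData(vol)
  d[inside] <- inner
  brainVolume(d, spacing = spacing, affine = aff)
}

# membership array matching ellipsoidVolume's inside test
ellipsoidMembership <- function(shape = c(24L, 24L, 24L), spacing = 4,
                                semiaxes = c(36, 40, 32)) {
  vol <- brainVolume(array(0, shape), spacing = spacing)
  aff <- volAffine(vol)
  co <- arrayInd(seq_len(prod(shape)), shape) - 1
  w <- cbind(co, 1) %*% t(aff)
  array((w[, 1] / semiaxes[1])^2 + (w[, 2] / semiaxes[2])^2 +
          (w[, 3] / semiaxes[3])^2 <= 1, shape)
}

# a ZScoreMap wrapping an arbitrary z array (for cluster-extraction tests)
zmapFromArray <- function(z, threshold = 2, spacing = 1) {
  mask <- brainMask(array(TRUE, dim(z)))
  zvol <- brainVolume(z, spacing = spacing, modality = "z")
  new("ZScoreMap", z = zvol, mask = mask, meanDiff = 0, sdDiff = 1,
      zThreshold = threshold)
}
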