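# Connected-component labeling and geometry helpers shared by the brain-mask
# and cluster-extraction steps.

connOffsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  ord <- rowSums(abs(g))
  if (connectivity == 6L) g[ord == 1L, , drop = FALSE]
  else if (connectivity == 18L) g[ord <= 2L, , drop = FALSE]
  else if (connectivity == 26L) g
  else stop("connectivity must be 6, 18 or 26")
}

#' Label connected components of a 3-D logical array
#'
#' Breadth-first labeling under 6-, 18- or 26-connectivity. Labels are
#' assigned in column-major scan order of the component seeds, starting at 1;
#' background is 0.
#'
#' @param mask logical 3-D array.
#' @param connectivity 6, 18 or 26 (default).
#' @return integer array of component labels with the same dimensions.
#' @export
labelComponents <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  stopifnot(length(d) == 3L, is.logical(mask))
  offs <- connOffsets(as.integer(connectivity))
  noff <- nrow(offs)
  lab <- array(0L, d)
  seeds <- which(mask)
  if (!length(seeds)) return(lab)
  d12 <- d[1] * d[2]
  nextLab <- 0L
  for (s in seeds) {
    if (lab[s] != 0L) next
    nextLab <- nextLab + 1L
    lab[s] <- nextLab
    frontier <- s
    while (length(frontier)) {
      co <- arrayInd(frontier, d)
      nf <- nrow(co)
      cand <- co[rep(seq_len(nf), each = noff), , drop = FALSE] +
        offs[rep(seq_len(noff), times = nf), , drop = FALSE]
      ok <- cand[, 1] >= 1L & cand[, 1] <= d[1] &
            cand[, 2] >= 1L & cand[, 2] <= d[2] &
            cand[, 3] >= 1L & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      lin <- unique((cand[, 3] - 1L) * d12 + (cand[, 2] - 1L) * d[1] + cand[, 1])
      lin <- lin[mask[lin] & lab[lin] == 0L]
      lab[lin] <- nextLab
      frontier <- lin
    }
  }
  lab
}

# world coordinates (mm) of 0-based voxel indices, n x 3
voxelToWorld <- function(affine, ijk0) {
  ijk0 <- matrix(ijk0, ncol = 3)
  h <- cbind(ijk0, 1) %*% t(affine)
  h[, 1:3, drop = FALSE]
}

# continuous 0-based voxel indices of world points, n x 3
worldToVoxel <- function(affine, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  h <- cbind(xyz, 1) %*% t(solve(affine))
  h[, 1:3, drop = FALSE]
}
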