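# Shared fixtures and independent oracles, built in code at test time.

# default calibration used across tests (z, y, x), um
vsDefault <- c(0.34, 0.105, 0.105)

# spherical mask of radius r (um) centred at `center` (um) in an array of
# dims d, built analytically (independent of package rasterization)
sphereMask <- function(r, center, dims, vs = vsDefault) {
  gr <- as.matrix(expand.grid(z = seq_len(dims[1]), y = seq_len(dims[2]),
                              x = seq_len(dims[3])))
  P <- sweep(gr - 0.5, 2, vs, "*")
  d2 <- (P[, 1] - center[1])^2 + (P[, 2] - center[2])^2 +
    (P[, 3] - center[3])^2
  array(d2 <= r^2, dims)
}

# small noiseless / blurred simulated cell for fast unit tests
tinyCell <- function(fractionalRd = 0.5, direction = c(0, 0, 1),
                     nCopies = 1L, noiseless = TRUE, seed = 1L,
                     semiAxes = c(2.6, 2.3, 2.0), targetVolume = 1.2) {
  nuc <- nucleusSpec(center = rev(semiAxes) + 8 * vsDefault,
                     semiAxes = semiAxes)
  dirs <- list(c(0, 0, 1), c(0, 1, 0), c(0, -0.6, -0.8))
  terrs <- lapply(seq_len(nCopies), function(j)
    territorySpec("ct", fractionalRd,
                  if (nCopies == 1L) direction else dirs[[j]],
                  targetVolume, copyIndex = j))
  acq <- if (noiseless)
    acquisitionSpec(psfSigma = c(0, 0, 0), photonScale = 0, readNoiseSd = 0,
                    seed = seed)
  else acquisitionSpec(seed = seed)
  simulateCell(nuc, terrs, acq)
}

# brute-force flood-fill connected components (26- or 6-connectivity);
# returns component sizes sorted decreasingly. Independent oracle for
# labelObjects: plain breadth-first search, no graph library.
bruteComponents <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  seen <- array(FALSE, d)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, ]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, ]
  sizes <- integer(0)
  idx <- which(mask, arr.ind = TRUE)
  for (s in seq_len(nrow(idx))) {
    v0 <- idx[s, ]
    if (seen[v0[1], v0[2], v0[3]]) next
    queue <- matrix(v0, ncol = 3)
    seen[v0[1], v0[2], v0[3]] <- TRUE
    size <- 0L
    while (nrow(queue) > 0L) {
      v <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      size <- size + 1L
      nb <- sweep(offs, 2, v, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      for (r in seq_len(nrow(nb))) {
        if (mask[nb[r, 1], nb[r, 2], nb[r, 3]] &&
            !seen[nb[r, 1], nb[r, 2], nb[r, 3]]) {
          seen[nb[r, 1], nb[r, 2], nb[r, 3]] <- TRUE
          queue <- rbind(queue, nb[r, ])
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sort(sizes, decreasing = TRUE)
}

# exhaustive locus-to-surface distance oracle: nested definition of the
# surface (any anchor voxel with a 6-neighbour outside) and a full scan
bruteSurfaceDistance <- function(cm, mask, vs) {
  d <- dim(mask)
  best <- Inf
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    if (!mask[z, y, x]) next
    isSurf <- FALSE
    for (o in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                   c(0, 0, -1), c(0, 0, 1))) {
      n <- c(z, y, x) + o
      if (any(n < 1) || n[1] > d[1] || n[2] > d[2] || n[3] > d[3] ||
          !mask[n[1], n[2], n[3]]) { isSurf <- TRUE; break }
    }
    if (isSurf) {
      p <- (c(z, y, x) - 0.5) * vs
      best <- min(best, sqrt(sum((p - cm)^2)))
    }
  }
  best
}

# measure one simulated cell end to end; returns per-copy measured rd (%)
# and the filled nucleus mask for reuse
measureCell <- function(sim) {
  stacks <- sim$stacks
  nucImg <- stacks[["dapi"]]
  nuc <- nucleusObject(thresholdChannel(nucImg, "otsu"), img = nucImg)
  nucMask <- ctRadial:::.fillHoles3D(objectMask(nuc, dim(stacks)))
  ctImg <- stacks[[setdiff(channelNames(stacks), c("dapi", "lamina",
                                                   "locus"))[1]]]
  objs <- labelObjects(thresholdChannel(ctImg, "otsu"), img = ctImg)
  rd <- vapply(objs, function(o)
    rdPercent(radialDistance(nucMask, centroidUm(nuc), centroidUm(o),
                             voxelSize(stacks))), numeric(1))
  list(rd = rd, nucleus = nuc, nucMask = nucMask, objects = objs)
}
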