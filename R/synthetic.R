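# Synthetic 3D-FISH data with known ground truth. Nuclei are convex
# ellipsoids, territories are equal-volume balls placed at a planted
# fractional radial position, acquisition applies a Gaussian PSF, Poisson
# shot noise and Gaussian read noise, and every planted quantity is recorded
# in a ground-truth record so downstream recovery can be scored.

#' Specify a synthetic nucleus
#'
#' The nucleus is modelled as a convex triaxial ellipsoid (convexity keeps
#' the centre-to-periphery ray construction unambiguous).
#'
#' @param center numeric(3) centre in um, (z, y, x).
#' @param semiAxes numeric(3) ellipsoid semi-axes in um, (a, b, c) along the
#'   rotated (x, y, z) body axes; all > 0.
#' @param orientation numeric(3) Euler angles in radians (ZYX convention).
#' @return A `NucleusSpec` (validated list).
#' @examples
#' nucleusSpec(center = c(5, 6, 6), semiAxes = c(4.5, 4, 3.5))
#' @export
nucleusSpec <- function(center, semiAxes, orientation = c(0, 0, 0)) {
  stopifnot(length(center) == 3, length(semiAxes) == 3,
            length(orientation) == 3)
  if (any(!is.finite(semiAxes)) || any(semiAxes <= 0))
    stop("all semiAxes must be positive")
  structure(list(center = as.numeric(center),
                 semiAxes = as.numeric(semiAxes),
                 orientation = as.numeric(orientation)),
            class = "NucleusSpec")
}

#' Specify a synthetic chromosome territory
#'
#' @param chromosome territory channel label, e.g. "ct19". The number of
#'   `territorySpec` entries sharing a label defines the planted copy number
#'   of that chromosome.
#' @param fractionalRd planted ground-truth radial position in [0, 1]
#'   (0 = nuclear centre, 1 = periphery).
#' @param direction numeric(3) placement direction, (z, y, x); normalized
#'   internally.
#' @param targetVolume territory volume in um^3 (> 0).
#' @param copyIndex integer >= 1, which copy of the chromosome this is.
#' @return A `TerritorySpec` (validated list).
#' @export
territorySpec <- function(chromosome, fractionalRd, direction,
                          targetVolume, copyIndex = 1L) {
  if (fractionalRd < 0 || fractionalRd > 1)
    stop("fractionalRd must lie in [0, 1]")
  if (targetVolume <= 0) stop("targetVolume must be positive")
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be a nonzero vector")
  structure(list(chromosome = as.character(chromosome),
                 fractionalRd = fractionalRd,
                 direction = as.numeric(direction) / nrm,
                 targetVolume = targetVolume,
                 copyIndex = as.integer(copyIndex)),
            class = "TerritorySpec")
}

#' Specify acquisition physics for the synthetic microscope
#'
#' Defaults mirror a confocal acquisition at the calibration used throughout
#' the package: anisotropic voxels of 0.34 x 0.105 x 0.105 um (z, y, x) and
#' 8-bit pixel depth. Setting `psfSigma = c(0,0,0)`, `photonScale = 0` and
#' `readNoiseSd = 0` gives a noiseless, unblurred rendering.
#'
#' @param voxelSize numeric(3), um (z, y, x).
#' @param psfSigma numeric(3), Gaussian PSF sigma in um per axis (z, y, x);
#'   0 disables blur on that axis.
#' @param photonScale photons per unit normalized signal for Poisson shot
#'   noise; 0 disables shot noise.
#' @param readNoiseSd additive Gaussian read noise, in quantization units of
#'   the output bit depth; 0 disables.
#' @param bitDepth 8 or 16.
#' @param seed integer RNG seed applied at the start of each simulated cell.
#' @return An `AcquisitionSpec` (validated list).
#' @export
acquisitionSpec <- function(voxelSize = c(0.34, 0.105, 0.105),
                            psfSigma = c(0.30, 0.13, 0.13),
                            photonScale = 80,
                            readNoiseSd = 1,
                            bitDepth = 8L,
                            seed = 1L) {
  if (any(voxelSize <= 0)) stop("voxel sizes must be positive")
  if (any(psfSigma < 0)) stop("psfSigma must be >= 0")
  if (photonScale < 0) stop("photonScale must be >= 0")
  if (!bitDepth %in% c(8L, 16L)) stop("bitDepth must be 8 or 16")
  structure(list(voxelSize = as.numeric(voxelSize),
                 psfSigma = as.numeric(psfSigma),
                 photonScale = photonScale,
                 readNoiseSd = readNoiseSd,
                 bitDepth = as.integer(bitDepth),
                 seed = as.integer(seed)),
            class = "AcquisitionSpec")
}

# normalized ellipsoid radius rho for um points P (n x 3, z/y/x order);
# rho <= 1 inside. Returns rho vector.
.ellipsoidRho <- function(P, nucleus) {
  Pxyz <- P[, c(3, 2, 1), drop = FALSE]
  cxyz <- nucleus$center[c(3, 2, 1)]
  R <- .eulerRotation(nucleus$orientation)
  Q <- sweep(Pxyz, 2, cxyz) %*% R        # rotate into body frame
  Q <- sweep(Q, 2, nucleus$semiAxes, "/")
  sqrt(rowSums(Q^2))
}

# distance from nucleus centre to ellipsoid surface along unit direction u
# (z/y/x order)
.surfaceDistance <- function(u, nucleus) {
  uxyz <- u[c(3, 2, 1)]
  R <- .eulerRotation(nucleus$orientation)
  q <- as.numeric(uxyz %*% R) / nucleus$semiAxes
  1 / sqrt(sum(q^2))
}

#' Render one synthetic multi-channel 3D-FISH cell
#'
#' Rasterizes the nucleus, each chromosome-territory copy, an optional
#' lamina rim and optional gene-locus spots into a calibrated multi-channel
#' stack, then applies PSF blur, shot noise, read noise and quantization per
#' the acquisition spec. Placement is done in physical um before
#' rasterization, so the anisotropic z step is honoured exactly.
#'
#' Territories are rendered as equal-volume balls: the `n` voxels closest to
#' the planted centroid in physical distance, where
#' `n = round(targetVolume / voxelVolume)` — the rendered volume therefore
#' matches the target to within one voxel.
#'
#' @param nucleus a [nucleusSpec()].
#' @param territories list of [territorySpec()] objects.
#' @param acq an [acquisitionSpec()].
#' @param laminaThickness if non-`NULL`, a lamina channel is rendered as a
#'   rim of this thickness (um) at the nuclear boundary.
#' @param loci optional list of gene-locus specs; each a list with fields
#'   `name`, and either `positionUm` (numeric(3), um) or `fractionalRd` +
#'   `direction` for radial placement; optional `sigmaUm` spot size
#'   (default `c(0.3, 0.15, 0.15)` um).
#' @param dims optional integer(3) image dimensions (Z, Y, X); derived from
#'   the nucleus extent plus margin when `NULL`.
#' @return list with elements `stacks` (a [StackSet-class]) and `truth`
#'   (ground-truth record: nucleus geometry and analytic volume, per-copy
#'   planted centroids, fractional radial positions, target volumes, overlap
#'   flags, locus positions, seed).
#' @examples
#' nuc <- nucleusSpec(c(4, 5, 5), c(4, 3.5, 3))
#' ct <- territorySpec("ct19", 0.5, c(0, 0, 1), 3)
#' sim <- simulateCell(nuc, list(ct),
#'                     acquisitionSpec(psfSigma = c(0, 0, 0), photonScale = 0,
#'                                     readNoiseSd = 0))
#' sim$truth$territories
#' @export
simulateCell <- function(nucleus, territories, acq = acquisitionSpec(),
                         laminaThickness = NULL, loci = NULL, dims = NULL) {
  stopifnot(inherits(nucleus, "NucleusSpec"),
            inherits(acq, "AcquisitionSpec"))
  set.seed(acq$seed)
  vs <- acq$voxelSize
  maxval <- 2^acq$bitDepth - 1
  # axis-aligned half-extents of the rotated ellipsoid, (z, y, x) order
  R <- .eulerRotation(nucleus$orientation)
  extXyz <- sqrt(rowSums(sweep(R, 2, nucleus$semiAxes, "*")^2))
  halfExt <- extXyz[c(3, 2, 1)]
  if (is.null(dims)) {
    reach <- halfExt + 3 * acq$psfSigma
    dims <- ceiling((nucleus$center + reach) / vs) + 3L
  }
  dims <- as.integer(dims)
  # nucleus must fit with >= 2-voxel margin
  lo <- nucleus$center - halfExt
  hi <- nucleus$center + halfExt
  if (any(lo < 2 * vs) || any(hi > (dims - 2) * vs))
    stop("nucleus does not fit inside the image bounds with a 2-voxel margin")

  # voxel-centre coordinate matrix (um), z fastest as in array layout
  grid <- as.matrix(expand.grid(z = seq_len(dims[1]), y = seq_len(dims[2]),
                                x = seq_len(dims[3])))
  P <- .voxelToUm(grid, vs)
  rho <- .ellipsoidRho(P, nucleus)
  nucMask <- array(rho <= 1, dims)

  sigLevel <- 0.8  # fluorophore signal as a fraction of full scale
  channels <- list()
  channels[["dapi"]] <- array(as.numeric(nucMask) * sigLevel, dims)

  # territories, grouped into one channel per chromosome label
  voxVol <- prod(vs)
  truthRows <- NULL
  ctNames <- unique(vapply(territories, `[[`, character(1), "chromosome"))
  ctMaskCount <- list()
  for (nm in ctNames) ctMaskCount[[nm]] <- array(0L, dims)
  for (ts in territories) {
    stopifnot(inherits(ts, "TerritorySpec"))
    smax <- .surfaceDistance(ts$direction, nucleus)
    centroid <- nucleus$center + ts$fractionalRd * smax * ts$direction
    if (.ellipsoidRho(matrix(centroid, ncol = 3), nucleus) > 1 + 1e-9)
      stop("territory placement outside nucleus: ", ts$chromosome,
           " copy ", ts$copyIndex)
    nVox <- max(1L, round(ts$targetVolume / voxVol))
    r0 <- (3 * ts$targetVolume / (4 * pi))^(1 / 3)
    # candidate voxels inside a bounding box around the centroid
    rBox <- r0 * 1.6 + max(vs)
    loI <- pmax(.umToVoxel(centroid - rBox, vs), 1L)
    hiI <- pmin(.umToVoxel(centroid + rBox, vs), dims)
    sub <- as.matrix(expand.grid(z = loI[1]:hiI[1], y = loI[2]:hiI[2],
                                 x = loI[3]:hiI[3]))
    d2 <- rowSums(sweep(.voxelToUm(sub, vs), 2, centroid)^2)
    pick <- sub[order(d2)[seq_len(min(nVox, nrow(sub)))], , drop = FALSE]
    ctMaskCount[[ts$chromosome]][pick] <- ctMaskCount[[ts$chromosome]][pick] + 1L
    truthRows <- rbind(truthRows, data.frame(
      chromosome = ts$chromosome, copy_index = ts$copyIndex,
      fractional_rd = ts$fractionalRd,
      centroid_z = centroid[1], centroid_y = centroid[2],
      centroid_x = centroid[3],
      surface_distance_um = smax,
      target_volume_um3 = ts$targetVolume,
      rendered_volume_um3 = nrow(pick) * voxVol))
  }
  overlapFlag <- character(0)
  for (nm in ctNames) {
    if (any(ctMaskCount[[nm]] > 1L)) overlapFlag <- c(overlapFlag, nm)
    channels[[nm]] <- array(as.numeric(ctMaskCount[[nm]] > 0L) * sigLevel, dims)
  }
  if (!is.null(truthRows))
    truthRows$overlaps <- truthRows$chromosome %in% overlapFlag

  if (!is.null(laminaThickness)) {
    rUm <- sqrt(rowSums(sweep(P, 2, nucleus$center)^2))
    depth <- ifelse(rho > 0, rUm * (1 / rho - 1), Inf)  # um to surface
    rim <- nucMask & array(depth <= laminaThickness, dims)
    channels[["lamina"]] <- array(as.numeric(rim) * sigLevel, dims)
  }

  lociTruth <- NULL
  if (!is.null(loci)) {
    spot <- array(0, dims)
    for (lc in loci) {
      if (!is.null(lc$positionUm)) {
        pos <- as.numeric(lc$positionUm)
      } else {
        u <- as.numeric(lc$direction); u <- u / sqrt(sum(u^2))
        pos <- nucleus$center + lc$fractionalRd * .surfaceDistance(u, nucleus) * u
      }
      sg <- if (is.null(lc$sigmaUm)) c(0.3, 0.15, 0.15) else lc$sigmaUm
      dz <- (P[, 1] - pos[1]) / sg[1]
      dy <- (P[, 2] - pos[2]) / sg[2]
      dx <- (P[, 3] - pos[3]) / sg[3]
      spot <- spot + array(sigLevel * exp(-(dz^2 + dy^2 + dx^2) / 2), dims)
      lociTruth <- rbind(lociTruth, data.frame(
        name = if (is.null(lc$name)) "locus" else lc$name,
        pos_z = pos[1], pos_y = pos[2], pos_x = pos[3]))
    }
    channels[["locus"]] <- pmin(spot, 1)
  }

  imgs <- lapply(names(channels), function(nm) {
    sig <- channels[[nm]]
    if (any(acq$psfSigma > 0)) sig <- .gaussianBlur3D(sig, acq$psfSigma, vs)
    if (acq$photonScale > 0)
      sig <- array(stats::rpois(length(sig), acq$photonScale * sig) /
                     acq$photonScale, dim(sig))
    out <- sig * maxval
    if (acq$readNoiseSd > 0)
      out <- out + stats::rnorm(length(out), sd = acq$readNoiseSd)
    VoxelImage(pmin(pmax(round(out), 0), maxval), vs, nm, acq$bitDepth)
  })
  stacks <- StackSet(imgs)

  truth <- list(
    seed = acq$seed, voxel_size = vs, dims = dims,
    nucleus = list(center = nucleus$center, semi_axes = nucleus$semiAxes,
                   orientation = nucleus$orientation,
                   volume_um3 = 4 / 3 * pi * prod(nucleus$semiAxes),
                   mask_voxels = sum(nucMask)),
    territories = truthRows,
    loci = lociTruth,
    lamina_thickness = laminaThickness)
  list(stacks = stacks, truth = truth)
}

#' Simulate a per-gene expression table with planted deregulation
#'
#' Emits one row per coding gene. On each chromosome, exactly
#' `round(fraction / 100 * coding_genes)` genes are planted as deregulated —
#' they pass the standard filter (|fold change| >= 2 and p < 0.05) — and all
#' other genes fail at least one criterion (too-small fold change, p >= 0.05,
#' or both), so the planted per-chromosome deregulation fraction is recovered
#' exactly up to the rounding of the planted count.
#'
#' @param annotation data.frame with columns `chromosome` and `coding_genes`
#'   (see [readAnnotation()]).
#' @param plantedFraction planted percent deregulation per chromosome; a
#'   single number recycled to all chromosomes, or a vector named by
#'   canonical chromosome label. Must lie in [0, 100].
#' @param seed integer RNG seed.
#' @param forceDeregIds optional character vector of gene ids (of the form
#'   `g<chromosome>_<i>`) forced into the deregulated set — the device used
#'   to plant a common deregulated set across two knockdown tables.
#' @param upProb probability that a deregulated gene is upregulated.
#' @return data.frame with columns `gene_id`, `chromosome`, `fold_change`
#'   (signed linear), `p_value`.
#' @examples
#' ann <- data.frame(chromosome = c("18", "19"), coding_genes = c(400, 1000))
#' tab <- simulateExpressionTable(ann, plantedFraction = 1, seed = 7)
#' nrow(tab)  # sum of coding genes
#' @export
simulateExpressionTable <- function(annotation, plantedFraction, seed = 1L,
                                    forceDeregIds = NULL, upProb = 0.5) {
  chroms <- normalizeChromosome(annotation$chromosome)
  n <- as.integer(annotation$coding_genes)
  if (any(n <= 0)) stop("coding_genes must be positive")
  if (is.null(names(plantedFraction))) {
    frac <- rep_len(plantedFraction, length(chroms))
  } else {
    frac <- plantedFraction[chroms]
    if (any(is.na(frac))) stop("plantedFraction missing for some chromosome")
  }
  if (any(frac < 0) || any(frac > 100))
    stop("plantedFraction must lie in [0, 100]")
  set.seed(seed)
  rows <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    ids <- sprintf("g%s_%04d", chroms[i], seq_len(n[i]))
    k <- round(frac[i] / 100 * n[i])
    forced <- intersect(forceDeregIds, ids)
    if (length(forced) > k)
      stop("more forced deregulated ids than the planted count on chromosome ",
           chroms[i])
    pool <- setdiff(ids, forced)
    dereg <- c(forced, sample(pool, k - length(forced)))
    isDereg <- ids %in% dereg
    fc <- numeric(n[i]); p <- numeric(n[i])
    nd <- sum(isDereg)
    if (nd > 0) {
      mag <- 2 + stats::rexp(nd, rate = 1.2)
      sgn <- ifelse(stats::runif(nd) < upProb, 1, -1)
      fc[isDereg] <- sgn * mag
      p[isDereg] <- stats::runif(nd, 0, 0.049)
    }
    nn <- sum(!isDereg)
    if (nn > 0) {
      mode <- sample(c("fc", "p", "both"), nn, replace = TRUE,
                     prob = c(0.4, 0.4, 0.2))
      magLow <- stats::runif(nn, 0.3, 1.99)
      magHigh <- 2 + stats::rexp(nn, rate = 1.2)
      mag <- ifelse(mode == "p", magHigh, magLow)
      sgn <- ifelse(stats::runif(nn) < 0.5, 1, -1)
      fc[!isDereg] <- sgn * mag
      p[!isDereg] <- ifelse(mode == "fc", stats::runif(nn, 0, 0.049),
                            stats::runif(nn, 0.05, 1))
    }
    rows[[i]] <- data.frame(gene_id = ids, chromosome = chroms[i],
                            fold_change = fc, p_value = p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a cohort of cells for positioning / ploidy analysis
#'
#' Convenience generator for population-level tests: renders `nCells`
#' single-nucleus stacks, a fraction of which carry a planted extra territory
#' copy (aneuploid gain), with per-copy fractional radial positions drawn
#' from a given sampler.
#'
#' @param nCells number of cells.
#' @param chromosome territory channel label.
#' @param copies baseline copy number per cell (default 2, the diploid
#'   state).
#' @param gainFraction fraction of cells planted with one extra copy
#'   (aneuploid gain); the rounded count `round(gainFraction * nCells)` is
#'   planted exactly, at seeded random cell positions.
#' @param rdSampler function(n) returning n fractional radial positions in
#'   [0, 1]; default uniform on [0.05, 0.95].
#' @param acq an [acquisitionSpec()]; its seed field seeds cell `i` with
#'   `seed + i`.
#' @param semiAxes nucleus semi-axes in um.
#' @param targetVolume per-copy territory volume, um^3.
#' @details Copy placements are rejection-sampled so that planted centroids
#'   of distinct copies are at least one ball diameter plus 0.4 um apart —
#'   distinct hybridization signals, as scored in copy counting.
#' @return list of `simulateCell` results (each with `stacks` and `truth`).
#' @export
simulateCohort <- function(nCells, chromosome = "ct19", copies = 2L,
                           gainFraction = 0,
                           rdSampler = function(n) stats::runif(n, 0.05, 0.95),
                           acq = acquisitionSpec(),
                           semiAxes = c(4.2, 3.8, 3.2),
                           targetVolume = 2.8) {
  set.seed(acq$seed)
  # the planted gain fraction is the study condition: plant it exactly
  gained <- rep(FALSE, nCells)
  gained[sample.int(nCells, round(gainFraction * nCells))] <- TRUE
  r0 <- (3 * targetVolume / (4 * pi))^(1 / 3)
  minSep <- 2 * r0 + 0.4
  out <- vector("list", nCells)
  for (i in seq_len(nCells)) {
    nCopies <- as.integer(copies) + as.integer(gained[i])
    center <- rev(semiAxes) + 6 * acq$voxelSize  # (z, y, x) margin
    nuc <- nucleusSpec(center = center, semiAxes = semiAxes)
    for (try in 1:200) {
      rds <- rdSampler(nCopies)
      base <- stats::runif(1, 0, 2 * pi)
      phis <- base + 2 * pi * (seq_len(nCopies) - 1) / nCopies
      us <- lapply(seq_len(nCopies), function(j) {
        u <- c(stats::runif(1, -0.25, 0.25), sin(phis[j]), cos(phis[j]))
        u / sqrt(sum(u^2))
      })
      cents <- t(vapply(seq_len(nCopies), function(j)
        center + rds[j] * .surfaceDistance(us[[j]], nuc) * us[[j]],
        numeric(3)))
      if (nCopies == 1L ||
          min(stats::dist(cents)) >= minSep) break
    }
    terrs <- lapply(seq_len(nCopies), function(j)
      territorySpec(chromosome, rds[j], us[[j]], targetVolume,
                    copyIndex = j))
    acqI <- acq; acqI$seed <- acq$seed + i
    out[[i]] <- simulateCell(nuc, terrs, acqI)
  }
  out
}
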