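# The synthetic-data generator: planted geometry, copy numbers,
# reproducibility, and the planted expression tables.

test_that("planted territory centroid follows the fractional radial position", {
  # rd = 0: centroid coincides with the nucleus centre
  sim0 <- tinyCell(fractionalRd = 0)
  tr <- sim0$truth$territories
  expect_equal(c(tr$centroid_z, tr$centroid_y, tr$centroid_x),
               sim0$truth$nucleus$center, tolerance = 1e-12)

  # sphere: rd = 0.5 along +x plants the centroid at half the radius
  nuc <- nucleusSpec(c(3.8, 3.4, 3.4), c(3, 3, 3))
  ct <- territorySpec("ct", 0.5, c(0, 0, 1), 1.2)
  sim <- simulateCell(nuc, list(ct),
                      acquisitionSpec(psfSigma = c(0, 0, 0), photonScale = 0,
                                      readNoiseSd = 0))
  expect_equal(sim$truth$territories$centroid_x, 3.4 + 1.5, tolerance = 1e-12)
  expect_equal(sim$truth$territories$surface_distance_um, 3, tolerance = 1e-12)
})

test_that("rendered territory volume matches the target to one voxel", {
  sim <- tinyCell(fractionalRd = 0.3, targetVolume = 1.5)
  tr <- sim$truth$territories
  expect_lt(abs(tr$rendered_volume_um3 - tr$target_volume_um3),
            prod(vsDefault) + 1e-12)
})

test_that("two planted copies yield two labeled components (flood-fill oracle)", {
  sim <- tinyCell(fractionalRd = 0.55, nCopies = 2L)
  mask <- intensities(sim$stacks[["ct"]]) > 0
  oracleSizes <- bruteComponents(mask, 26L)
  expect_length(oracleSizes, 2L)
  objs <- labelObjects(mask, voxelSize = vsDefault, minVoxels = 10L)
  expect_length(objs, 2L)
  expect_equal(vapply(objs, function(o) nrow(o@voxelIndices), integer(1)),
               oracleSizes)
})

test_that("invalid territory and nucleus specs are rejected", {
  expect_error(territorySpec("ct", 1.2, c(0, 0, 1), 1), "fractionalRd")
  expect_error(territorySpec("ct", 0.5, c(0, 0, 1), -1), "targetVolume")
  expect_error(territorySpec("ct", 0.5, c(0, 0, 0), 1), "nonzero")
  expect_error(nucleusSpec(c(1, 1, 1), c(0, 1, 1)), "positive")
  # nucleus too close to the image border
  nuc <- nucleusSpec(c(2, 2, 2), c(3, 3, 3))
  expect_error(simulateCell(nuc, list(), acquisitionSpec(),
                            dims = c(10, 30, 30)), "margin")
})

test_that("identical seeds give bit-identical stacks and tables", {
  s1 <- tinyCell(noiseless = FALSE, seed = 9L)
  s2 <- tinyCell(noiseless = FALSE, seed = 9L)
  for (nm in channelNames(s1$stacks))
    expect_identical(intensities(s1$stacks[[nm]]),
                     intensities(s2$stacks[[nm]]))
  expect_identical(s1$truth$territories, s2$truth$territories)
  ann <- data.frame(chromosome = "19", coding_genes = 200)
  expect_identical(simulateExpressionTable(ann, 2, seed = 5),
                   simulateExpressionTable(ann, 2, seed = 5))
})

test_that("noiseless rendering recovers planted centroids within half a voxel diagonal", {
  sim <- tinyCell(fractionalRd = 0.4, direction = c(0.2, 0.5, 0.8))
  res <- measureCell(sim)
  tr <- sim$truth$territories
  planted <- c(tr$centroid_z, tr$centroid_y, tr$centroid_x)
  measured <- centroidUm(res$objects[[1]])
  halfDiag <- sqrt(sum(vsDefault^2)) / 2
  expect_lt(sqrt(sum((measured - planted)^2)), halfDiag)
  # nucleus centre too
  expect_lt(sqrt(sum((centroidUm(res$nucleus) -
                        sim$truth$nucleus$center)^2)), halfDiag)
})

test_that("measured %RD increases strictly with the planted fractional position", {
  rds <- vapply(c(0.15, 0.35, 0.55, 0.75, 0.9), function(f)
    measureCell(tinyCell(fractionalRd = f))$rd, numeric(1))
  expect_true(all(diff(rds) > 0))
})

test_that("expression tables plant the deregulation fraction exactly", {
  ann <- data.frame(chromosome = c("18", "19"),
                    coding_genes = c(400, 1000))
  tab <- simulateExpressionTable(ann, c("18" = 0, "19" = 1.0), seed = 3)
  expect_equal(nrow(tab), 1400L)
  # brute-force application of the printed filter to the emitted table
  pass <- abs(tab$fold_change) >= 2 & tab$p_value < 0.05
  expect_equal(sum(pass & tab$chromosome == "18"), 0L)
  expect_equal(sum(pass & tab$chromosome == "19"), 10L)
  expect_error(simulateExpressionTable(ann, 101, seed = 1), "100")
})

test_that("a planted common set is recovered by set intersection", {
  ann <- data.frame(chromosome = c("17", "19"),
                    coding_genes = c(500, 800))
  common <- c(sprintf("g17_%04d", 1:10), sprintf("g19_%04d", 1:12))
  t1 <- simulateExpressionTable(ann, 5, seed = 11, forceDeregIds = common)
  t2 <- simulateExpressionTable(ann, 5, seed = 22, forceDeregIds = common)
  d1 <- do.call(rbind, filterDeregulated(t1))$gene_id
  d2 <- do.call(rbind, filterDeregulated(t2))$gene_id
  expect_equal(length(intersect(intersect(d1, d2), common)), 22L)
  expect_true(all(common %in% d1) && all(common %in% d2))
})
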