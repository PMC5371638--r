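# Thresholding, 3D labeling and nucleus extraction.

test_that("Otsu separates a two-level image exactly and rejects constants", {
  arr <- array(0, c(4, 6, 6))
  arr[2:3, 2:4, 2:4] <- 200
  img <- VoxelImage(arr, vsDefault, "x")
  mask <- thresholdChannel(img, "otsu")
  expect_identical(mask, arr == 200)
  expect_error(thresholdChannel(VoxelImage(array(7, c(3, 3, 3)),
                                           vsDefault, "x"), "otsu"),
               "fixed")
})

test_that("fixed threshold is inclusive at the boundary", {
  arr <- array(c(99, 100, 101), c(3, 2, 2))
  img <- VoxelImage(arr, vsDefault, "x")
  mask <- thresholdChannel(img, "fixed", value = 100)
  expect_identical(as.logical(mask), as.logical(arr >= 100))
  expect_false(mask[1, 1, 1])  # 99 is below
  expect_true(mask[2, 1, 1])   # 100 is foreground
})

test_that("labeling respects the minimum voxel count and size ordering", {
  mask <- array(FALSE, c(12, 12, 12))
  mask[2:5, 2:5, 2:5] <- TRUE      # 64 voxels
  mask[8:11, 8:11, 8:11] <- TRUE   # 64 voxels, disjoint
  expect_length(labelObjects(mask, vsDefault, minVoxels = 50L), 2L)
  expect_length(labelObjects(mask, vsDefault, minVoxels = 65L), 0L)
  # larger object first
  mask[8, 8, 8] <- FALSE  # second cube now 63 voxels
  objs <- labelObjects(mask, vsDefault, minVoxels = 1L)
  expect_equal(vapply(objs, function(o) nrow(o@voxelIndices), integer(1)),
               c(64L, 63L))
  expect_equal(objs[[1]]@label, 1L)
})

test_that("labeling agrees with a brute-force flood fill on random masks", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      mask <- array(runif(10 * 10 * 10) < 0.2, c(10, 10, 10))
      oracle <- bruteComponents(mask, 26L)
      objs <- labelObjects(mask, vsDefault, minVoxels = 1L)
      expect_equal(vapply(objs, function(o) nrow(o@voxelIndices), integer(1)),
                   oracle)
    }
  })
})

test_that("object volumes partition the mask volume", {
  withr::with_seed(7, {
    mask <- array(runif(8 * 12 * 12) < 0.3, c(8, 12, 12))
    objs <- labelObjects(mask, vsDefault, minVoxels = 1L)
    total <- sum(vapply(objs, volumeUm3, numeric(1)))
    expect_equal(total, sum(mask) * prod(vsDefault), tolerance = 1e-12)
    objs50 <- labelObjects(mask, vsDefault, minVoxels = 5L)
    expect_lte(sum(vapply(objs50, volumeUm3, numeric(1))), total)
  })
})

test_that("centroid and centre of mass coincide on uniform objects", {
  mask <- array(FALSE, c(8, 8, 8)); mask[2:5, 3:6, 2:7] <- TRUE
  img <- VoxelImage(array(200 * mask, dim(mask)), vsDefault, "x")
  obj <- labelObjects(mask, img = img, minVoxels = 1L)[[1]]
  expect_equal(centroidUm(obj), centerOfMassUm(obj), tolerance = 1e-12)
  # non-uniform intensities pull the centre of mass, not the centroid
  arr <- array(0, c(8, 8, 8)); arr[2:5, 3:6, 2:7] <- 10
  arr[2, 3, 2] <- 255
  obj2 <- labelObjects(mask, img = VoxelImage(arr, vsDefault, "x"),
                       minVoxels = 1L)[[1]]
  expect_equal(centroidUm(obj2), centroidUm(obj))
  expect_false(isTRUE(all.equal(centroidUm(obj2), centerOfMassUm(obj2))))
})

test_that("nucleus extraction picks the largest object and fills holes", {
  # ellipsoid with an interior cavity plus a small debris blob
  dims <- c(24, 70, 70)
  ctr <- c(4, 3.6, 3.6)
  mask <- sphereMask(3, ctr, dims)
  hole <- sphereMask(1, ctr, dims)
  debris <- array(FALSE, dims); debris[2:3, 2:4, 2:4] <- TRUE
  nuc <- nucleusObject((mask & !hole) | debris, vsDefault)
  analytic <- 4 / 3 * pi * 27
  expect_lt(abs(volumeUm3(nuc) - analytic) / analytic, 0.05)
  expect_lt(sqrt(sum((centroidUm(nuc) - ctr)^2)),
            sqrt(sum(vsDefault^2)) / 2)
  expect_error(nucleusObject(array(FALSE, c(3, 3, 3)), vsDefault), "empty")
})

test_that("recovered sphere volume is within 5% of analytic for r >= 10 max voxel dim", {
  r <- 3.4  # 10 x the 0.34 um z step
  dims <- c(26, 80, 80)
  mask <- sphereMask(r, c(4.2, 4, 4), dims)
  obj <- labelObjects(mask, vsDefault, minVoxels = 1L)[[1]]
  expect_lt(abs(volumeUm3(obj) - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3),
            0.05)
})
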