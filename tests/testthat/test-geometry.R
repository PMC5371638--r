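# The radial-distance construction, shell binning, lamina distances and
# volumes-by-shell grouping.

test_that("degenerate measurement (B = A) returns rd 0 with C undefined", {
  mask <- sphereMask(2, c(2.6, 2.4, 2.4), c(16, 48, 48))
  A <- c(2.6, 2.4, 2.4)
  m <- radialDistance(mask, A, A, vsDefault)
  expect_true(m@degenerate)
  expect_equal(rdPercent(m), 0)
  expect_true(all(is.na(m@C_um)))
})

test_that("analytic sphere: rd at half radius is 50 +/- 2, boundary is 100 +/- 2", {
  r <- 5
  ctr <- c(5.5, 5.3, 5.3)
  mask <- sphereMask(r, ctr, c(33, 101, 101))
  m50 <- radialDistance(mask, ctr, ctr + c(0, 0, r / 2), vsDefault)
  expect_lt(abs(rdPercent(m50) - 50), 2)
  expect_equal(m50@X_um, r / 2, tolerance = 1e-9)
  expect_lt(abs(m50@Y_um - r), 0.2)
  # B essentially on the boundary
  mB <- radialDistance(mask, ctr, ctr + c(0, 0.6, 0.8) / 1 * r * 0.999,
                       vsDefault)
  expect_lt(abs(rdPercent(mB) - 100), 2)
  # off-axis direction
  u <- c(0.4, 0.5, 0.77); u <- u / sqrt(sum(u^2))
  mOff <- radialDistance(mask, ctr, ctr + 0.3 * r * u, vsDefault)
  expect_lt(abs(rdPercent(mOff) - 30), 2)
})

test_that("rd errors are raised for bad geometry", {
  mask <- sphereMask(2, c(2.6, 2.4, 2.4), c(16, 48, 48))
  expect_error(radialDistance(mask, c(0.1, 0.1, 0.1), c(1, 1, 1), vsDefault),
               "outside")
  # mask touching the border: ray exits image while inside mask
  full <- array(TRUE, c(8, 8, 8))
  expect_error(radialDistance(full, c(1, 0.3, 0.3), c(1, 0.3, 0.5),
                              c(0.3, 0.1, 0.1)), "border")
})

test_that("rd increases monotonically as B moves outward along a fixed ray", {
  mask <- sphereMask(3, c(3.6, 3.4, 3.4), c(22, 66, 66))
  ctr <- c(3.6, 3.4, 3.4)
  u <- c(0.2, 0.6, 0.75); u <- u / sqrt(sum(u^2))
  rds <- vapply(seq(0.1, 0.9, by = 0.1), function(f)
    rdPercent(radialDistance(mask, ctr, ctr + f * 3 * u, vsDefault)),
    numeric(1))
  expect_true(all(diff(rds) > 0))
  expect_true(all(rds >= 0 & rds <= 100))
})

test_that("rd is rotation invariant up to voxelization", {
  # same ellipsoidal nucleus and relative placement, rotated in the xy plane
  f <- 0.6
  base <- NULL
  for (th in c(0, 0.5, 1.1)) {
    nuc <- nucleusSpec(c(3.4, 4.6, 4.6), c(3.4, 2.4, 2.6),
                       orientation = c(th, 0, 0))
    dir <- c(0, sin(th + 0.3), cos(th + 0.3))  # co-rotating direction
    sim <- simulateCell(nuc, list(territorySpec("ct", f, dir, 1)),
                        acquisitionSpec(psfSigma = c(0, 0, 0),
                                        photonScale = 0, readNoiseSd = 0))
    res <- measureCell(sim)
    if (is.null(base)) base <- res$rd else expect_lt(abs(res$rd - base), 1)
  }
})

test_that("shell binning follows the upper-inclusive 20% convention", {
  expect_equal(as.character(shellOf(c(80, 60, 0, 100))),
               c("IV", "III", "I", "V"))
  expect_equal(as.character(shellOf(c(20, 20.0001, 40, 60.5))),
               c("I", "II", "II", "IV"))
  expect_error(shellOf(-1), "0, 100")
  expect_error(shellOf(100.5), "0, 100")
})

test_that("lamina distance equals the exhaustive surface-search oracle", {
  withr::with_seed(31, {
    for (rep in 1:6) {
      mask <- array(runif(6 * 7 * 7) < 0.4, c(6, 7, 7))
      if (!any(mask)) next
      cm <- c(runif(1, 0, 6 * 0.34), runif(1, 0, 0.7), runif(1, 0, 0.7))
      got <- laminaDistance(cm, mask, vsDefault)$distance_um
      expect_equal(got, bruteSurfaceDistance(cm, mask, vsDefault),
                   tolerance = 1e-12)
    }
  })
})

test_that("lamina distance from the centre of a spherical rim is the radius", {
  r <- 3
  ctr <- c(3.6, 3.4, 3.4)
  dims <- c(22, 66, 66)
  rim <- sphereMask(r, ctr, dims) & !sphereMask(r - 0.5, ctr, dims)
  d <- laminaDistance(ctr, rim, vsDefault)$distance_um
  expect_lt(abs(d - (r - 0.5)), sqrt(sum(vsDefault^2)) / 2 + 0.05)
  # a point on a surface voxel centre measures zero
  surf <- ctRadial:::.surfaceVoxels(rim)
  p <- (surf[1, ] - 0.5) * vsDefault
  expect_equal(laminaDistance(p, rim, vsDefault)$distance_um, 0)
  expect_error(laminaDistance(ctr, array(FALSE, c(3, 3, 3)), vsDefault),
               "empty")
})

test_that("volumes-by-shell groups correctly and is null-calibrated", {
  g <- volumesByShell(rep(50, 6), 1:6)
  expect_identical(names(g), "III")
  expect_identical(g$III, 1:6)
  expect_identical(volumesByShell(numeric(0), numeric(0)), list())
  # equal volume distributions in every shell: KW should rarely reject
  withr::with_seed(99, {
    ps <- replicate(40, {
      rd <- runif(100, 0, 100)
      vol <- rlnorm(100, meanlog = 1, sdlog = 0.3)
      kruskalWallis(volumesByShell(rd, vol))$p
    })
    expect_gte(mean(ps > 0.05), 0.9)
  })
})
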