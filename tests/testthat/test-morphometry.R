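test_that("elongation and flatness follow the radius-ratio definitions", {
  expect_equal(elongation(20, 20), 1)
  expect_equal(elongation(40, 20), 2)
  expect_equal(elongation(30, 12), 2.5)
  expect_equal(flatness(20, 20), 1)
  expect_equal(flatness(20, 10), 2)
  expect_equal(flatness(12, 4), 3)
  expect_error(elongation(10, 0), "positive")
  expect_error(flatness(10, -1), "positive")
})

test_that("equivalent-ellipsoid radii recover digitized shapes", {
  # ball of radius 20 um at 2 um pitch: all radii within 1 um
  f <- fitEllipsoidRadii(ellipsoidCoords(c(20, 20, 20), 2), 2)
  expect_true(f$shapeValid)
  expect_true(all(abs(f$radiiUm - 20) < 1))
  # axis-aligned ellipsoid (40, 20, 10) um within 10 percent
  f <- fitEllipsoidRadii(ellipsoidCoords(c(40, 20, 10), 2), 2)
  expect_true(all(abs(f$radiiUm - c(40, 20, 10)) / c(40, 20, 10) < 0.1))
  expect_true(all(diff(f$radiiUm) <= 0))
  # single voxel: below the shape floor
  f <- fitEllipsoidRadii(matrix(c(3L, 4L, 5L), 1L), 2)
  expect_false(f$shapeValid)
})

test_that("shape metrics are scale invariant and rotation robust", {
  co <- ellipsoidCoords(c(30, 15, 15), 1)
  f1 <- fitEllipsoidRadii(co, 1)
  f2 <- fitEllipsoidRadii(co, 7) # same voxels, larger pitch
  e <- function(f) elongation(f$radiiUm[1], f$radiiUm[2])
  fl <- function(f) flatness(f$radiiUm[2], f$radiiUm[3])
  expect_equal(e(f1), e(f2), tolerance = 1e-12)
  expect_equal(fl(f1), fl(f2), tolerance = 1e-12)
  set.seed(51)
  es <- replicate(10, {
    rot <- qr.Q(qr(matrix(rnorm(9), 3)))
    f <- fitEllipsoidRadii(ellipsoidCoords(c(20, 10, 10), 1, rot), 1)
    e(f)
  })
  expect_lt((max(es) - min(es)) / min(es), 0.1)
})

test_that("digitized spheres approach elongation and flatness 1 with refinement", {
  dev <- vapply(c(5, 10, 20), function(r) {
    f <- fitEllipsoidRadii(ellipsoidCoords(rep(r, 3), 1,
                                           centerOffset = c(0.31, 0.12, 0.47)), 1)
    max(abs(elongation(f$radiiUm[1], f$radiiUm[2]) - 1),
        abs(flatness(f$radiiUm[2], f$radiiUm[3]) - 1))
  }, numeric(1))
  expect_true(all(diff(dev) <= 0))
  expect_lt(dev[3], 0.02)
})

test_that("density and fraction arithmetic match their definitions", {
  expect_equal(cellDensity(300, 0.001), 3e5)
  expect_equal(cellDensity(0, 0.5), 0)
  expect_error(cellDensity(10, 0), "positive")
  expect_identical(densityFraction(169007, 300000), 56L)
  expect_identical(densityFraction(307518, 500000), 62L)
  expect_identical(densityFraction(563262, 1000000), 56L)
  expect_identical(densityFraction(123456, 123456), 100L)
  expect_error(densityFraction(1, 0), "positive")
})

test_that("viability is the live fraction to one decimal", {
  expect_equal(viability(9, 5), 64.3)
  expect_equal(viability(10, 0), 100)
  expect_error(viability(0, 0), "at least one")
})

test_that("sample summaries match hand-computed shapes and are deterministic", {
  empty <- labelComponents(array(FALSE, dim = c(4L, 6L, 6L)), voxelPitchUm = 2)
  s <- summarizeSample(empty, 0.001)
  expect_identical(s$metrics$n_cells, 0L)
  expect_identical(nrow(s$cells), 0L)
  expect_true(is.na(s$metrics$elongation_median))

  # two constructed shapes: a ball and an elongated box
  arr <- array(FALSE, dim = c(30L, 60L, 60L))
  ball <- ellipsoidMask(c(8, 8, 8), 21L)
  arr[5:25, 5:25, 5:25][ball] <- TRUE
  arr[10:12, 40:55, 40:42] <- TRUE # 3 x 16 x 3 voxel box
  labs <- labelComponents(arr, voxelPitchUm = 2)
  expect_identical(nLabels(labs), 2L)
  s <- summarizeSample(labs, 0.0005)
  expect_identical(s$metrics$n_cells, 2L)
  expect_equal(s$metrics$density_cells_per_ml, 2 / 0.0005)
  ballRow <- s$cells[s$cells$voxel_count == sum(ball), ]
  expect_equal(ballRow$voxel_count, sum(ball))
  expect_equal(ballRow$volume_um3, sum(ball) * 8)
  expect_true(all(abs(ballRow[, c("R_largest_um", "R_medium_um", "R_smallest_um")] - 16) < 1))
  boxRow <- s$cells[s$cells$voxel_count == 144L, ]
  # box with side lengths (3, 16, 3) voxels at 2 um: uniform-moment radii
  # sqrt(5 * (L^2 - 1) / 12) * pitch per axis (discrete uniform variance)
  expLong <- sqrt(5 * (16^2 - 1) / 12) * 2
  expShort <- sqrt(5 * (3^2 - 1) / 12) * 2
  expect_equal(boxRow$R_largest_um, expLong, tolerance = 1e-9)
  expect_equal(boxRow$R_medium_um, expShort, tolerance = 1e-9)
  expect_equal(boxRow$elongation, expLong / expShort, tolerance = 1e-9)
  expect_equal(boxRow$flatness, 1, tolerance = 1e-9)

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(s$cells, f1, row.names = FALSE)
  write.csv(summarizeSample(labs, 0.0005)$cells, f2, row.names = FALSE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("quantified density tracks phantom truth on an ideal reconstruction", {
  ph <- smallPhantom()
  labs <- suppressMessages(segmentVolume(ph$recon))
  d <- cellDensity(nLabels(labs), ph$truth@analysisVolumeMl)
  expect_lt(abs(d - ph$truth@realizedDensityPerMl) / ph$truth@realizedDensityPerMl,
            0.05)
})
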