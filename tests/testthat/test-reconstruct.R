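test_that("sinogram rearrangement is lossless and shape-correct", {
  ph <- smallPhantom()
  sinos <- buildSinograms(ph$stack)
  d <- dim(projData(ph$stack))
  expect_length(sinos, d[2L])
  expect_identical(dim(sinos[[1L]]), c(d[1L], d[3L]))
  back <- stackFromSinograms(sinos, anglesDeg(ph$stack), pixelPitch(ph$stack))
  expect_identical(projData(back), projData(ph$stack))
  # single-angle stack keeps matrix shape
  one <- new("ProjectionStack",
             data = projData(ph$stack)[1L, , , drop = FALSE],
             anglesDeg = 0, pixelPitchUm = 5, modality = "bright_field")
  expect_identical(dim(buildSinograms(one)[[1L]]), c(1L, d[3L]))
})

test_that("center-of-rotation estimation recovers injected offsets within 0.5 px", {
  spec <- phantomSpec(tubeInnerDiameterUm = 480, volumeShapeVoxels = c(8L, 96L, 96L),
                      nCells = 6, rngSeed = 19)
  ph <- generatePhantom(spec)
  for (off in c(-5, 0, 5)) {
    st <- forwardProject(ph$volume, defaultAngles(200L, 1.8), corOffsetPx = off)
    sino <- buildSinograms(st)[[4L]]
    est <- estimateCOR(sino, anglesDeg(st))
    expect_lt(abs(est - off), 0.5)
  }
  # fixed point: correcting by the estimate and re-estimating gives ~0
  st <- forwardProject(ph$volume, defaultAngles(200L, 1.8), corOffsetPx = 3)
  sino <- buildSinograms(st)[[4L]]
  est <- estimateCOR(sino, anglesDeg(st))
  corrected <- t(apply(sino, 1L, function(row) {
    approx(seq_along(row), row, xout = seq_along(row) + est, rule = 2)$y
  }))
  expect_lt(abs(estimateCOR(corrected, anglesDeg(st))), 0.25)
  expect_error(estimateCOR(sino[1:10, ], anglesDeg(st)[1:10]), "opposed")
})

test_that("FBP reconstructs a phantom faithfully inside the field of view", {
  ph <- smallPhantom()
  # zero sinograms give a zero volume
  z <- fbpReconstruct(matrix(0, 200L, 96L), anglesDeg(ph$stack))
  expect_true(all(volData(z) == 0))
  recon <- reconstructStack(ph$stack, cor = 0, filterName = "ramp")
  idx <- fovIndex(dim(volData(recon)))
  expect_gt(cor(volData(ph$volume)[idx], volData(recon)[idx]), 0.95)
  expect_error(fbpReconstruct(buildSinograms(ph$stack), anglesDeg(ph$stack),
                              filterName = "butterworth"))
  expect_error(fbpReconstruct(matrix(0, 10L, 96L), anglesDeg(ph$stack)),
               "match the angle list")
})

test_that("FBP is linear in the sinogram and localizes an impulse", {
  set.seed(23)
  angles <- defaultAngles(60L, 6)
  s1 <- matrix(runif(60 * 32), 60L, 32L)
  s2 <- matrix(runif(60 * 32), 60L, 32L)
  r1 <- volData(fbpReconstruct(s1, angles))
  r2 <- volData(fbpReconstruct(s2, angles))
  r12 <- volData(fbpReconstruct(2 * s1 - 0.5 * s2, angles))
  expect_equal(r12, 2 * r1 - 0.5 * r2, tolerance = 1e-9)
  # impulse round trip peaks at the impulse voxel
  W <- 49L
  arr <- array(0, dim = c(1L, W, W))
  arr[1L, 30L, 21L] <- 1
  vol <- new("ReconVolume", data = arr, voxelPitchUm = 5)
  st <- forwardProject(vol, defaultAngles(180L, 2))
  rec <- volData(reconstructStack(st, cor = 0))
  expect_identical(which.max(rec), which.max(arr))
})

test_that("reconstruction is invariant to consistent angle relabeling", {
  ph <- smallPhantom()
  sino <- buildSinograms(ph$stack)[[10L]]
  angles <- anglesDeg(ph$stack)
  set.seed(31)
  ord <- sample.int(length(angles))
  a <- volData(fbpReconstruct(sino, angles))
  # permuting (angle, row) pairs together must not change the volume
  b <- volData(fbpReconstruct(sino[ord, ], angles[ord]))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("intensity inversion is an involution that brightens cells", {
  ph <- smallPhantom()
  const <- new("ReconVolume", data = array(7, dim = c(2L, 8L, 8L)), voxelPitchUm = 5)
  expect_true(all(volData(invertIntensity(const)) == 0))
  v <- reconstructStack(ph$stack, cor = 0)
  inv <- invertIntensity(v)
  twice <- invertIntensity(inv)
  expect_equal(cor(as.vector(volData(twice)), as.vector(volData(v))), 1)
  m <- truthMask(ph)
  expect_gt(mean(volData(ph$recon)[m]), mean(volData(ph$recon)[!m]))
})

test_that("automatic center-of-rotation feeds the reconstruction", {
  spec <- phantomSpec(tubeInnerDiameterUm = 480, volumeShapeVoxels = c(6L, 96L, 96L),
                      nCells = 5, rngSeed = 29)
  ph <- generatePhantom(spec)
  st <- forwardProject(ph$volume, defaultAngles(200L, 1.8), corOffsetPx = 4)
  rec <- reconstructStack(st, cor = "auto")
  expect_equal(rec@provenance$corOffsetPx, 4, tolerance = 0.5)
  idx <- fovIndex(dim(volData(rec)))
  expect_gt(cor(volData(ph$volume)[idx], volData(rec)[idx]), 0.9)
})
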