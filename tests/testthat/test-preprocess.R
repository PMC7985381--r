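test_that("all-pass homomorphic configuration returns the input", {
  st <- flatStack(2L, 64L, value = 2)
  set.seed(8)
  d <- projData(st)
  d[] <- d + runif(length(d))
  st <- initialize(st, data = d)
  out <- homomorphicFilter(st, lowGain = 1, highGain = 1)
  expect_equal(projData(out), projData(st), tolerance = 1e-10)
  expect_error(homomorphicFilter(st, lowGain = 0), "lowGain")
  expect_error(homomorphicFilter(st, highGain = 0.5), "highGain")
  expect_error(homomorphicFilter(st, cutoffFreq = 0.7), "cutoffFreq")
})

test_that("homomorphic filtering strongly reduces illumination-driven variation", {
  st <- flatStack(2L, 256L)
  biased <- applyIlluminationField(st, 0.5, rngSeed = 21)
  out <- homomorphicFilter(biased, lowGain = 0.1)
  cv <- function(x) sd(x) / mean(x)
  expect_lte(cv(projData(out)), cv(projData(biased)) / 5)
  expect_true(all(projData(out) > 0))
})

test_that("small-object contrast survives homomorphic bias removal", {
  W <- 256L
  frame <- matrix(1, W, W)
  frame[120:126, 120:126] <- 0.5 # small dark object, ~7 px
  g <- optmorph:::illuminationField(W, W, 1, 31)
  biased <- frame * (1 + 0.5 * g)
  st <- new("ProjectionStack", data = array(biased, dim = c(1L, W, W)),
            anglesDeg = 0, pixelPitchUm = 5, modality = "bright_field")
  out <- projData(homomorphicFilter(st, lowGain = 0.1))[1L, , ]
  localContrast <- function(img) {
    obj <- mean(img[121:125, 121:125])
    bg <- mean(img[c(105:112, 134:141), c(105:112, 134:141)])
    (bg - obj) / bg
  }
  expect_equal(localContrast(out), localContrast(frame * (1 + 0 * g)),
               tolerance = 0.1)
})

test_that("homomorphic filter commutes with global gain via the low-frequency exponent", {
  set.seed(14)
  W <- 64L
  d <- array(exp(rnorm(2 * W * W, sd = 0.1)) + 0.5, dim = c(2L, W, W))
  st <- new("ProjectionStack", data = d, anglesDeg = c(0, 1), pixelPitchUm = 5,
            modality = "bright_field")
  lg <- 0.3
  fScaled <- projData(homomorphicFilter(initialize(st, data = 4 * d), lowGain = lg))
  fBase <- projData(homomorphicFilter(st, lowGain = lg))
  # a global gain c passes through as c^lowGain (log-domain linearity)
  expect_equal(fScaled, 4^lg * fBase, tolerance = 1e-8)
})

test_that("median filter removes hot pixels and is the identity at window 1", {
  st <- flatStack(1L, 32L, value = 3)
  d <- projData(st)
  d[1L, 16L, 16L] <- 100
  st <- initialize(st, data = d)
  expect_identical(medianFilterStack(st, 1L), st)
  out <- medianFilterStack(st, 3L)
  expect_equal(projData(out)[1L, 16L, 16L], 3, tolerance = 1e-6)
  flat <- flatStack(1L, 32L, value = 3)
  expect_equal(projData(medianFilterStack(flat, 3L)), projData(flat),
               tolerance = 1e-9)
  expect_error(medianFilterStack(st, 2L), "odd")
  expect_error(medianFilterStack(st, -3L), "odd")
})

test_that("brightness adjustment maps the percentile range monotonically", {
  set.seed(2)
  d <- array(runif(4 * 32 * 32), dim = c(4L, 32L, 32L))
  d[1L] <- 0; d[2L] <- 1 # pin the extremes
  st <- new("ProjectionStack", data = d,
            anglesDeg = seq(0, by = 1, length.out = 4L),
            pixelPitchUm = 5, modality = "fluor_live")
  out <- brightnessAdjust(st, outRange = c(0, 255), percentiles = c(0, 100))
  expect_equal(min(projData(out)), 0)
  expect_equal(max(projData(out)), 255)
  expect_equal(cor(as.vector(projData(out)), as.vector(d), method = "spearman"), 1)
  expect_error(brightnessAdjust(flatStack(2L, 16L)), "constant")
})

test_that("live/dead composition recovers known channel shifts", {
  set.seed(6)
  W <- 48L
  live <- array(0, dim = c(4L, W, W))
  live[, 20:26, 12:18] <- 4
  live <- live + array(runif(length(live)), dim = dim(live)) * 0.05
  angles <- seq(0, by = 1, length.out = 4L)
  lst <- new("ProjectionStack", data = live, anglesDeg = angles,
             pixelPitchUm = 5, modality = "fluor_live")
  # identical channels: zero shift everywhere
  same <- composeLiveDead(lst, initialize(lst, modality = "fluor_dead"))
  expect_true(all(same$shifts$dy == 0 & same$shifts$dx == 0))
  # dead = live shifted by (+3, -2): recovered applied shift is (-3, +2)
  dead <- live
  for (a in seq_len(4L)) dead[a, , ] <- optmorph:::shiftFrame(live[a, , ], 3L, -2L)
  dst <- new("ProjectionStack", data = dead, anglesDeg = angles,
             pixelPitchUm = 5, modality = "fluor_dead")
  res <- composeLiveDead(lst, dst)
  expect_true(all(res$shifts$dy == -3L))
  expect_true(all(res$shifts$dx == 2L))
  expect_identical(dim(res$composite), c(4L, W, W, 2L))
  # aligned dead channel matches live away from zero-filled borders
  expect_equal(projData(res$dead)[, 5:(W - 5), 5:(W - 5)],
               live[, 5:(W - 5), 5:(W - 5)], tolerance = 1e-9)
  # degenerate dead channel: zero shift with a warning
  zero <- initialize(dst, data = array(0, dim = dim(dead)))
  expect_warning(z <- composeLiveDead(lst, zero), "all-zero")
  expect_true(all(z$shifts$dy == 0 & z$shifts$dx == 0))
  # contract violations
  expect_error(composeLiveDead(lst, initialize(dst, anglesDeg = angles + 1)),
               "angle list")
})
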