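#' Construct a phantom specification
#'
#' Builds a [PhantomSpec-class] describing a cell-laden hydrogel cylinder.
#' Defaults emulate the acquisition this package models: a 1.5 mm inner
#' diameter sample tube, 5 um isotropic voxels, cells of fibroblast scale
#' (7.5-15 um semi-axes), and a fraction of dead cells rendered at strongly
#' reduced optical contrast.
#'
#' Exactly one of `nCells` / `seededDensityPerMl` may be given, or both if
#' mutually consistent (`round(density * analysisVolumeMl) == nCells`). The
#' analysis cylinder is the tube lumen minus `wallMarginVoxels` of wall
#' margin; it is both the seeding support and the density denominator.
#'
#' @param tubeInnerDiameterUm tube inner diameter (um). Default 1500.
#' @param volumeShapeVoxels integer (z, y, x) volume shape.
#' @param voxelPitchUm isotropic voxel pitch (um). Default 5.
#' @param nCells number of cells (alternative to density).
#' @param seededDensityPerMl seeding density, cells/mL (alternative to count).
#' @param semiAxisRangeUm either `c(min, max)` shared by all three sorted
#'   semi-axes, or a 3 x 2 matrix of per-axis (min, max) rows ordered
#'   largest, medium, smallest.
#' @param cellContrast live-cell attenuation amplitude. Default 1.
#' @param deadFraction proportion of dead cells. Default 0.
#' @param deadContrastFactor contrast multiplier for dead cells. Default 0.1.
#' @param illuminationAmplitude relative amplitude of the multiplicative
#'   illumination bias field. Default 0.
#' @param noiseScale photon noise scale (0 = noiseless). Default 0.
#' @param corOffsetPx center-of-rotation offset in detector columns.
#' @param wallMarginVoxels wall margin excluded from the analysis cylinder.
#'   Default 2.
#' @param minClearanceUm minimum bounding-sphere clearance between cells.
#'   Default 10.
#' @param maxPlacementRetries rejection-sampling retry cap per cell.
#'   Default 1000.
#' @param rngSeed integer seed for reproducible phantoms.
#' @return a validated [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(volumeShapeVoxels = c(32, 64, 64), nCells = 5,
#'                     tubeInnerDiameterUm = 300, rngSeed = 1)
#' @export
phantomSpec <- function(tubeInnerDiameterUm = 1500,
                        volumeShapeVoxels = c(96L, 304L, 304L),
                        voxelPitchUm = 5,
                        nCells = NA_real_,
                        seededDensityPerMl = NA_real_,
                        semiAxisRangeUm = c(7.5, 15),
                        cellContrast = 1,
                        deadFraction = 0,
                        deadContrastFactor = 0.1,
                        illuminationAmplitude = 0,
                        noiseScale = 0,
                        corOffsetPx = 0,
                        wallMarginVoxels = 2,
                        minClearanceUm = 10,
                        maxPlacementRetries = 1000,
                        rngSeed = 1L) {
  if (is.matrix(semiAxisRangeUm)) {
    stopifnot(identical(dim(semiAxisRangeUm), c(3L, 2L)))
    rng <- semiAxisRangeUm
  } else {
    stopifnot(length(semiAxisRangeUm) == 2L)
    rng <- matrix(rep(as.numeric(semiAxisRangeUm), each = 3L), nrow = 3L)
  }
  spec <- new("PhantomSpec",
    tubeInnerDiameterUm = as.numeric(tubeInnerDiameterUm),
    volumeShapeVoxels = as.integer(volumeShapeVoxels),
    voxelPitchUm = as.numeric(voxelPitchUm),
    nCells = as.numeric(nCells),
    seededDensityPerMl = as.numeric(seededDensityPerMl),
    semiAxisRangeUm = rng,
    cellContrast = as.numeric(cellContrast),
    deadFraction = as.numeric(deadFraction),
    deadContrastFactor = as.numeric(deadContrastFactor),
    illuminationAmplitude = as.numeric(illuminationAmplitude),
    noiseScale = as.numeric(noiseScale),
    corOffsetPx = as.numeric(corOffsetPx),
    wallMarginVoxels = as.numeric(wallMarginVoxels),
    minClearanceUm = as.numeric(minClearanceUm),
    maxPlacementRetries = as.numeric(maxPlacementRetries),
    rngSeed = as.numeric(rngSeed)
  )
  resolveCellCount(spec) # errors early on inconsistent count/density
  spec
}

#' Analysis cylinder volume of a phantom specification
#'
#' The analysis cylinder is the tube lumen shrunk by the wall margin; its
#' radius is `min(tube radius, half the slice extent) - wallMarginVoxels *
#' pitch` and its height the volume z extent.
#'
#' @param spec a [PhantomSpec-class].
#' @return volume in mL.
#' @export
analysisVolumeMl <- function(spec) {
  rUm <- analysisRadiusUm(spec)
  hUm <- spec@volumeShapeVoxels[1L] * spec@voxelPitchUm
  pi * rUm^2 * hUm / 1e12 # um^3 -> mL
}

analysisRadiusUm <- function(spec) {
  fovR <- spec@volumeShapeVoxels[2L] * spec@voxelPitchUm / 2
  min(spec@tubeInnerDiameterUm / 2, fovR) - spec@wallMarginVoxels * spec@voxelPitchUm
}

#' Number of cells implied by a phantom specification
#'
#' Resolves `nCells` / `seededDensityPerMl` to a cell count; errors if both
#' are given and inconsistent (density times analysis volume must round to
#' the count).
#'
#' @param spec a [PhantomSpec-class].
#' @return integer cell count.
#' @export
resolveCellCount <- function(spec) {
  vMl <- analysisVolumeMl(spec)
  nFromDensity <- if (!is.na(spec@seededDensityPerMl)) {
    as.integer(round(spec@seededDensityPerMl * vMl))
  } else NA_integer_
  if (!is.na(spec@nCells) && !is.na(nFromDensity)) {
    if (as.integer(round(spec@nCells)) != nFromDensity) {
      stop(sprintf(
        "inconsistent spec: nCells = %d but seededDensityPerMl * volume rounds to %d",
        as.integer(round(spec@nCells)), nFromDensity
      ))
    }
  }
  n <- if (!is.na(spec@nCells)) as.integer(round(spec@nCells)) else nFromDensity
  if (n < 0L) stop("cell count must be nonnegative")
  n
}

# Haar-uniform random 3x3 rotation (QR of a Gaussian matrix, sign-corrected).
randomRotation <- function() {
  qrd <- qr(matrix(rnorm(9L), 3L))
  q <- qr.Q(qrd)
  q <- q %*% diag(sign(diag(qr.R(qrd))))
  if (det(q) < 0) q[, 3L] <- -q[, 3L]
  q
}

#' Generate a cell-laden hydrogel phantom
#'
#' Renders a scalar attenuation volume (hydrogel and surrounding water are
#' treated as transparent, value 0) containing non-overlapping ellipsoidal
#' cells of value `cellContrast` (times `deadContrastFactor` for dead
#' cells), together with a ground-truth registry. Cell centers are uniform
#' in the analysis cylinder, orientations Haar-uniform; placement uses
#' rejection sampling with a retry cap and errors if a cell cannot be
#' placed. A voxel belongs to a cell when its center lies inside the
#' ellipsoid.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with elements `volume` ([ReconVolume-class]) and `truth`
#'   ([PhantomTruth-class]).
#' @examples
#' ph <- generatePhantom(phantomSpec(volumeShapeVoxels = c(32, 64, 64),
#'                                   tubeInnerDiameterUm = 300, nCells = 4,
#'                                   rngSeed = 7))
#' ph$truth
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  n <- resolveCellCount(spec)
  dims <- spec@volumeShapeVoxels
  pitch <- spec@voxelPitchUm
  truth <- withSeed(spec@rngSeed, samplePhantomCells(spec, n))
  vol <- if (n > 0L) {
    vals <- spec@cellContrast * ifelse(truth$is_dead, spec@deadContrastFactor, 1)
    cpp_render_cells(
      dims,
      as.matrix(truth[, c("center_z_um", "center_y_um", "center_x_um")]) / pitch,
      as.matrix(truth[, c("a_um", "b_um", "c_um")]) / pitch,
      as.matrix(truth[, sprintf("R%d%d", rep(1:3, each = 3L), rep(1:3, 3L))]),
      vals
    )
  } else {
    array(0, dim = dims)
  }
  vMl <- analysisVolumeMl(spec)
  list(
    volume = new("ReconVolume", data = vol, voxelPitchUm = pitch,
                 provenance = list(kind = "phantom", rngSeed = spec@rngSeed)),
    truth = new("PhantomTruth", cells = truth, realizedDensityPerMl = n / vMl,
                analysisVolumeMl = vMl)
  )
}

# Draw semi-axes, orientations and non-overlapping centers for n cells.
samplePhantomCells <- function(spec, n) {
  pitch <- spec@voxelPitchUm
  dims <- spec@volumeShapeVoxels
  rAnalysis <- analysisRadiusUm(spec)
  hUm <- dims[1L] * pitch
  cyUm <- (dims[2L] - 1) / 2 * pitch
  cxUm <- (dims[3L] - 1) / 2 * pitch
  rngMat <- spec@semiAxisRangeUm
  cols <- c(
    "id", "center_z_um", "center_y_um", "center_x_um", "a_um", "b_um",
    "c_um", sprintf("R%d%d", rep(1:3, each = 3L), rep(1:3, 3L)), "is_dead"
  )
  if (n == 0L) {
    out <- as.data.frame(matrix(numeric(0), nrow = 0L, ncol = length(cols)))
    names(out) <- cols
    out$is_dead <- logical(0)
    return(out)
  }
  centers <- matrix(NA_real_, n, 3L)
  axes <- matrix(NA_real_, n, 3L)
  rots <- matrix(NA_real_, n, 9L)
  bound <- numeric(n)
  for (i in seq_len(n)) {
    ax <- sort(runif(3L, rngMat[, 1L], rngMat[, 2L]), decreasing = TRUE)
    a <- ax[1L]
    rot <- randomRotation()
    placed <- FALSE
    for (try in seq_len(spec@maxPlacementRetries)) {
      rMax <- rAnalysis - a
      if (rMax <= 0 || hUm < 2 * a) break
      rad <- rMax * sqrt(runif(1L))
      th <- runif(1L, 0, 2 * pi)
      z <- runif(1L, a, hUm - a)
      cand <- c(z, cyUm + rad * sin(th), cxUm + rad * cos(th))
      ok <- TRUE
      if (i > 1L) {
        dd <- sqrt(colSums((t(centers[seq_len(i - 1L), , drop = FALSE]) - cand)^2))
        ok <- all(dd >= bound[seq_len(i - 1L)] + a + spec@minClearanceUm)
      }
      if (ok) {
        centers[i, ] <- cand
        axes[i, ] <- ax
        rots[i, ] <- as.vector(t(rot)) # row-major R11..R33
        bound[i] <- a
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(
        "phantom placement failure: could not place cell %d of %d within %d retries",
        i, n, as.integer(spec@maxPlacementRetries)
      ))
    }
  }
  nDead <- as.integer(round(spec@deadFraction * n))
  isDead <- rep(FALSE, n)
  if (nDead > 0L) isDead[sample.int(n, nDead)] <- TRUE
  out <- data.frame(
    id = seq_len(n), center_z_um = centers[, 1L], center_y_um = centers[, 2L],
    center_x_um = centers[, 3L], a_um = axes[, 1L], b_um = axes[, 2L],
    c_um = axes[, 3L]
  )
  out <- cbind(out, as.data.frame(rots))
  names(out)[8:16] <- sprintf("R%d%d", rep(1:3, each = 3L), rep(1:3, 3L))
  out$is_dead <- isDead
  out
}

#' Render fluorescence channel volumes from a phantom truth
#'
#' Live/dead staining marks each compartment at full signal regardless of
#' the bright-field contrast loss of dead cells, so each channel volume
#' renders its subset of cells at intensity 1.
#'
#' @param truth a [PhantomTruth-class].
#' @param spec the [PhantomSpec-class] the truth was generated from.
#' @param channel `"live"` or `"dead"`.
#' @return a [ReconVolume-class] emission-density volume.
#' @export
renderChannelVolume <- function(truth, spec, channel = c("live", "dead")) {
  channel <- match.arg(channel)
  cl <- truth@cells
  keep <- if (channel == "live") !cl$is_dead else cl$is_dead
  cl <- cl[keep, , drop = FALSE]
  dims <- spec@volumeShapeVoxels
  pitch <- spec@voxelPitchUm
  vol <- if (nrow(cl)) {
    cpp_render_cells(
      dims,
      as.matrix(cl[, c("center_z_um", "center_y_um", "center_x_um")]) / pitch,
      as.matrix(cl[, c("a_um", "b_um", "c_um")]) / pitch,
      as.matrix(cl[, sprintf("R%d%d", rep(1:3, each = 3L), rep(1:3, 3L))]),
      rep(1, nrow(cl))
    )
  } else {
    array(0, dim = dims)
  }
  new("ReconVolume", data = vol, voxelPitchUm = pitch,
      provenance = list(kind = "phantom_channel", channel = channel))
}

#' Default OPT acquisition angles
#'
#' A full revolution sampled at fixed steps: 400 projections at 0.9 degree
#' intervals by default.
#'
#' @param n number of projections. Default 400.
#' @param stepDeg angular step in degrees. Default 0.9.
#' @return numeric vector of angles in degrees, in [0, 360).
#' @export
defaultAngles <- function(n = 400L, stepDeg = 0.9) {
  a <- seq(0, by = stepDeg, length.out = n)
  if (any(a >= 360)) stop("angle list exceeds [0, 360)")
  a
}

#' Simulate projection acquisition (parallel-beam Radon transform)
#'
#' Each projection row r is the line-integral (Radon) transform of volume
#' slice z = r at the given angle, computed by mass-conserving bilinear
#' splatting, so the sum over a projection equals the sum over its slice
#' exactly for every angle. `corOffsetPx` rigidly shifts all projections
#' along the detector column axis, emulating a misaligned rotation axis.
#' Output is in attenuation (post-logarithm) units; see [toTransmission()]
#' for the raw bright-field transmission layer.
#'
#' @param volume a [ReconVolume-class].
#' @param anglesDeg strictly increasing angles in [0, 360).
#' @param corOffsetPx signed center-of-rotation offset in detector columns.
#' @param modality stamped on the output stack.
#' @return a [ProjectionStack-class] of dimension
#'   `length(anglesDeg) x nz x nx`.
#' @export
forwardProject <- function(volume, anglesDeg = defaultAngles(),
                           corOffsetPx = 0, modality = "bright_field") {
  stopifnot(is(volume, "ReconVolume"))
  if (length(anglesDeg) == 0L) stop("empty angle list")
  if (any(diff(anglesDeg) <= 0) || any(anglesDeg < 0) || any(anglesDeg >= 360)) {
    stop("angles must be strictly increasing in [0, 360)")
  }
  v <- volume@data
  if (any(!is.finite(v))) stop("volume contains non-finite voxels")
  dims <- dim(v)
  rad <- anglesDeg * pi / 180
  out <- array(0, dim = c(length(anglesDeg), dims[1L], dims[3L]))
  for (z in seq_len(dims[1L])) {
    out[, z, ] <- cpp_project_slice(v[z, , ], rad, corOffsetPx)
  }
  new("ProjectionStack", data = out, anglesDeg = as.numeric(anglesDeg),
      pixelPitchUm = volume@voxelPitchUm, modality = modality)
}

#' Apply a multiplicative low-frequency illumination bias field
#'
#' Multiplies every projection by `1 + amplitude * g(row, col)` where g is a
#' smooth zero-mean field with `|g| <= 1`, built from a fixed set of three
#' first-order harmonics (at most `spatialScale` cycles per image axis,
#' well below the default homomorphic cutoff) with seeded random
#' coefficients. `amplitude = 0`
#' returns the input unchanged. This emulates the illumination
#' inhomogeneity that homomorphic filtering is meant to remove.
#'
#' @param stack a [ProjectionStack-class].
#' @param amplitude bias amplitude (>= 0); the field stays within
#'   `[1 - amplitude, 1 + amplitude]`.
#' @param spatialScale approximate number of bias cycles across the image
#'   extent. Default 1.
#' @param rngSeed seed for the harmonic coefficients.
#' @return a biased [ProjectionStack-class].
#' @export
applyIlluminationField <- function(stack, amplitude, spatialScale = 1,
                                   rngSeed = 1L) {
  stopifnot(is(stack, "ProjectionStack"))
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (amplitude == 0) return(stack)
  g <- illuminationField(dim(stack@data)[2L], dim(stack@data)[3L],
                         spatialScale, rngSeed)
  d <- stack@data
  for (a in seq_len(dim(d)[1L])) d[a, , ] <- d[a, , ] * (1 + amplitude * g)
  initialize(stack, data = d)
}

# Smooth zero-mean field with |g| <= 1 on an nrow x ncol grid.
illuminationField <- function(nrow, ncol, spatialScale = 1, rngSeed = 1L) {
  orders <- cbind(p = c(0, 1, 1), q = c(1, 0, 1))
  withSeed(rngSeed, {
    amp <- rnorm(nrow(orders))
    phase <- runif(nrow(orders), 0, 2 * pi)
    y <- matrix(seq_len(nrow) - 1, nrow, ncol) / nrow
    x <- matrix(seq_len(ncol) - 1, nrow, ncol, byrow = TRUE) / ncol
    g <- 0
    for (k in seq_len(nrow(orders))) {
      g <- g + amp[k] *
        cos(2 * pi * spatialScale * (orders[k, 1L] * y + orders[k, 2L] * x) + phase[k])
    }
    g <- g - mean(g)
    g / max(abs(g))
  })
}

#' Add signal-dependent (Poisson-like) noise to a projection stack
#'
#' Each pixel value v is replaced by `noiseScale * Poisson(v / noiseScale)`,
#' so the mean is preserved and the variance is `noiseScale * v` (photon
#' shot-noise scaling). `noiseScale = 0` returns the input unchanged; output
#' is nonnegative by construction.
#'
#' @param stack a [ProjectionStack-class].
#' @param noiseScale noise intensity parameter (>= 0).
#' @param rngSeed seed.
#' @return a noisy [ProjectionStack-class].
#' @export
addNoise <- function(stack, noiseScale, rngSeed = 1L) {
  stopifnot(is(stack, "ProjectionStack"))
  if (noiseScale < 0) stop("noiseScale must be >= 0")
  if (noiseScale == 0) return(stack)
  d <- stack@data
  d[] <- withSeed(rngSeed, rpois(length(d), d / noiseScale)) * noiseScale
  initialize(stack, data = d)
}

#' Convert between attenuation and transmission bright-field images
#'
#' The forward projector works in attenuation (post-logarithm) units, the
#' standard filtered back-projection contract. `toTransmission` produces raw
#' bright-field transmission images `I = I0 * exp(-p)`; `fromTransmission`
#' is its inverse `p = -log(I / I0)` (intensities clamped to a tiny positive
#' floor before the log; attenuation clamped at 0, so noise-induced
#' transmission above I0 maps to zero attenuation).
#'
#' @param stack a [ProjectionStack-class].
#' @param I0 incident intensity. Default 1.
#' @return a [ProjectionStack-class] in the other domain.
#' @export
toTransmission <- function(stack, I0 = 1) {
  stopifnot(is(stack, "ProjectionStack"), I0 > 0)
  initialize(stack, data = I0 * exp(-stack@data))
}

#' @rdname toTransmission
#' @export
fromTransmission <- function(stack, I0 = 1) {
  stopifnot(is(stack, "ProjectionStack"), I0 > 0)
  initialize(stack, data = pmax(-log(pmax(stack@data, 1e-12) / I0), 0))
}
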