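# Shared fixture builders and independent oracles.

# Voxel-index matrix (z, y, x) of a digitized ellipsoid with semi-axes `ax`
# (um), optional body-to-world rotation (columns = body axes) and fractional
# center offset (voxels).
ellipsoidCoords <- function(ax, pitchUm = 1, rot = diag(3), centerOffset = c(0, 0, 0)) {
  R <- max(ax) / pitchUm + 2
  n <- as.integer(2 * R + 3)
  g <- expand.grid(z = seq_len(n), y = seq_len(n), x = seq_len(n))
  c0 <- (n + 1) / 2 + centerOffset
  d <- cbind(g$z - c0[1], g$y - c0[2], g$x - c0[3]) * pitchUm
  u <- d %*% rot
  inside <- (u[, 1] / ax[1])^2 + (u[, 2] / ax[2])^2 + (u[, 3] / ax[3])^2 <= 1
  as.matrix(g[inside, , drop = FALSE])
}

# Logical 3D mask of the same ellipsoid inside an n^3 box.
ellipsoidMask <- function(ax, n, center = rep((n + 1) / 2, 3), rot = diag(3)) {
  g <- expand.grid(z = seq_len(n), y = seq_len(n), x = seq_len(n))
  d <- cbind(g$z - center[1], g$y - center[2], g$x - center[3])
  u <- d %*% rot
  inside <- (u[, 1] / ax[1])^2 + (u[, 2] / ax[2])^2 + (u[, 3] / ax[3])^2 <= 1
  array(inside, dim = c(n, n, n))
}

# Independent per-angle rotate-and-sum Radon oracle: for each detector
# position t, sample the slice along the ray with bilinear interpolation and
# sum. Deliberately distinct from the splat-based projector in the package.
rotateSumProjection <- function(slice, angleDeg, step = 0.25) {
  ny <- nrow(slice); nx <- ncol(slice)
  cy <- (ny - 1) / 2; cx <- (nx - 1) / 2
  th <- angleDeg * pi / 180
  ct <- cos(th); st <- sin(th)
  W <- nx
  cdet <- (W - 1) / 2
  out <- numeric(W)
  sGrid <- seq(-cdet, cdet, by = step)
  for (ti in seq_len(W)) {
    t <- ti - 1 - cdet
    acc <- 0
    for (s in sGrid) {
      x <- t * ct - s * st + cx
      y <- t * st + s * ct + cy
      x0 <- floor(x); y0 <- floor(y)
      if (x0 < 0 || x0 + 1 > nx - 1 || y0 < 0 || y0 + 1 > ny - 1) next
      fx <- x - x0; fy <- y - y0
      acc <- acc +
        slice[y0 + 1, x0 + 1] * (1 - fy) * (1 - fx) +
        slice[y0 + 2, x0 + 1] * fy * (1 - fx) +
        slice[y0 + 1, x0 + 2] * (1 - fy) * fx +
        slice[y0 + 2, x0 + 2] * fy * fx
    }
    out[ti] <- acc * step
  }
  out
}

# Small phantom + derived objects, built once per session and reused.
.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, builder) {
  if (is.null(.fixtureCache[[name]])) .fixtureCache[[name]] <- builder()
  .fixtureCache[[name]]
}

smallPhantom <- function() {
  cachedFixture("smallPhantom", function() {
    spec <- phantomSpec(
      tubeInnerDiameterUm = 480, volumeShapeVoxels = c(32L, 96L, 96L),
      voxelPitchUm = 5, nCells = 10, rngSeed = 101
    )
    ph <- generatePhantom(spec)
    ph$spec <- spec
    ph$stack <- forwardProject(ph$volume, defaultAngles(200L, 1.8))
    # bright-field route: reconstruct transmission contrast, then invert so
    # cells are bright
    ph$recon <- invertIntensity(
      reconstructStack(toTransmission(ph$stack), cor = 0)
    )
    ph
  })
}

truthMask <- function(ph) {
  vol <- volData(ph$volume)
  vol != 0
}

fovIndex <- function(dims) {
  W <- dims[2L]
  c0 <- (W + 1) / 2
  inside <- outer(seq_len(W) - c0, seq_len(W) - c0,
                  function(a, b) a^2 + b^2) <= (W / 2 - 1)^2
  which(array(rep(as.vector(inside), each = dims[1L]), dim = dims))
}

flatStack <- function(nAngles, W, value = 1, pitch = 5) {
  new("ProjectionStack",
      data = array(value, dim = c(nAngles, W, W)),
      anglesDeg = seq(0, by = 0.9, length.out = nAngles),
      pixelPitchUm = pitch, modality = "bright_field")
}
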