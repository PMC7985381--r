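#' Rearrange a projection stack into per-slice sinograms
#'
#' `sinograms[[z]][i, ]` equals projection i, row z — a lossless axis
#' permutation preparing slice-wise filtered back-projection.
#'
#' @param stack a [ProjectionStack-class].
#' @return list of `n_angles x width` matrices, one per projection row.
#' @export
buildSinograms <- function(stack) {
  stopifnot(is(stack, "ProjectionStack"))
  d <- stack@data
  if (dim(d)[1L] == 0L) stop("empty projection stack")
  lapply(seq_len(dim(d)[2L]), function(z) {
    matrix(d[, z, ], nrow = dim(d)[1L])
  })
}

#' Reassemble a projection stack from sinograms (inverse of buildSinograms)
#'
#' @param sinograms list of `n_angles x width` matrices.
#' @param anglesDeg angle list.
#' @param pixelPitchUm pixel pitch (um).
#' @param modality stack modality.
#' @return a [ProjectionStack-class].
#' @export
stackFromSinograms <- function(sinograms, anglesDeg, pixelPitchUm,
                               modality = "bright_field") {
  nA <- nrow(sinograms[[1L]])
  W <- ncol(sinograms[[1L]])
  d <- array(0, dim = c(nA, length(sinograms), W))
  for (z in seq_along(sinograms)) d[, z, ] <- sinograms[[z]]
  new("ProjectionStack", data = d, anglesDeg = anglesDeg,
      pixelPitchUm = pixelPitchUm, modality = modality)
}

#' Estimate the center-of-rotation offset from an over-360-degrees sinogram
#'
#' In parallel-beam geometry a projection at angle theta is the mirror image
#' of the projection at theta + 180 degrees about the rotation-axis column.
#' For every opposed pair the estimator cross-correlates one projection
#' against the mirrored other (subpixel peak via parabolic interpolation);
#' the recovered lag is twice the axis offset. The median over all pairs is
#' returned. This automatic estimator complements the manual scalar offset
#' accepted everywhere else.
#'
#' @param sinogram `n_angles x width` matrix covering [0, 360).
#' @param anglesDeg the matching angle list.
#' @param pairToleranceDeg angular tolerance when matching opposed pairs.
#'   Default half the median step.
#' @return signed offset in detector columns.
#' @export
estimateCOR <- function(sinogram, anglesDeg, pairToleranceDeg = NULL) {
  stopifnot(is.matrix(sinogram), nrow(sinogram) == length(anglesDeg))
  if (is.null(pairToleranceDeg)) {
    pairToleranceDeg <- if (length(anglesDeg) > 1L) median(diff(anglesDeg)) / 2 else 0.5
  }
  opposed <- (anglesDeg + 180) %% 360
  j <- vapply(opposed, function(a) {
    dev <- abs(anglesDeg - a)
    k <- which.min(dev)
    if (dev[k] <= pairToleranceDeg) k else NA_integer_
  }, integer(1L))
  pairs <- which(!is.na(j) & seq_along(j) < j)
  if (!length(pairs)) stop("no 180-degree opposed projection pairs available")
  offs <- vapply(pairs, function(i) {
    subpixelLag(sinogram[i, ], rev(sinogram[j[i], ])) / 2
  }, numeric(1L))
  median(offs, na.rm = TRUE)
}

# Subpixel lag of b relative to a via FFT cross-correlation + parabolic fit.
subpixelLag <- function(a, b) {
  a0 <- a - mean(a)
  b0 <- b - mean(b)
  if (all(a0 == 0) || all(b0 == 0)) return(NA_real_)
  n <- length(a0)
  cc <- Re(fft(fft(a0) * Conj(fft(b0)), inverse = TRUE)) / n
  lags <- fftLags(n)
  k <- which.max(cc)
  l0 <- lags[k]
  km <- if (k == 1L) n else k - 1L
  kp <- if (k == n) 1L else k + 1L
  denom <- cc[km] - 2 * cc[k] + cc[kp]
  frac <- if (denom < 0) 0.5 * (cc[km] - cc[kp]) / denom else 0
  l0 + frac
}

#' Filtered back-projection reconstruction
#'
#' Per slice: the sinogram rows are ramp-filtered in the frequency domain
#' (optionally Hann-apodized; `"none"` back-projects unfiltered), then
#' back-projected over all angles with linear detector interpolation,
#' accumulating with weight pi / n_angles. The center-of-rotation offset is
#' honored during back-projection (a subpixel detector shift). Voxels
#' outside the inscribed field-of-view circle, where parallel-beam data are
#' undefined, are set to 0.
#'
#' @param sinograms list of `n_angles x width` matrices (see
#'   [buildSinograms()]), or a single matrix for one slice.
#' @param anglesDeg the acquisition angles (degrees, covering [0, 360)).
#' @param corOffsetPx signed center-of-rotation offset in detector columns.
#'   Default 0.
#' @param filterName `"ramp"`, `"hann"` or `"none"`. Default `"ramp"`.
#' @param pixelPitchUm voxel pitch stamped on the output volume. Default 1.
#' @return a [ReconVolume-class] with one z slice per sinogram.
#' @export
fbpReconstruct <- function(sinograms, anglesDeg, corOffsetPx = 0,
                           filterName = c("ramp", "hann", "none"),
                           pixelPitchUm = 1) {
  filterName <- match.arg(filterName)
  if (is.matrix(sinograms)) sinograms <- list(sinograms)
  nA <- length(anglesDeg)
  if (!all(vapply(sinograms, nrow, integer(1L)) == nA)) {
    stop("sinogram row count must match the angle list")
  }
  W <- ncol(sinograms[[1L]])
  rad <- anglesDeg * pi / 180
  flt <- rampResponse(W, filterName)
  vol <- array(0, dim = c(length(sinograms), W, W))
  for (z in seq_along(sinograms)) {
    fs <- filterSinogram(sinograms[[z]], flt)
    vol[z, , ] <- cpp_backproject_slice(fs, rad, corOffsetPx)
  }
  new("ReconVolume", data = vol, voxelPitchUm = pixelPitchUm,
      provenance = list(filter = filterName, corOffsetPx = corOffsetPx,
                        nAngles = nA))
}

# Frequency response of the reconstruction filter on a zero-padded grid.
rampResponse <- function(W, filterName) {
  n <- 2^ceiling(log2(max(2 * W, 64)))
  f <- fftFreq(n)
  resp <- switch(filterName,
    ramp = 2 * abs(f),
    hann = 2 * abs(f) * 0.5 * (1 + cos(pi * f / 0.5)),
    none = rep(1, n)
  )
  list(n = n, resp = resp)
}

# Row-wise frequency-domain filtering of an n_angles x W sinogram.
filterSinogram <- function(sino, flt) {
  if (all(flt$resp == 1)) return(sino)
  W <- ncol(sino)
  pad <- matrix(0, flt$n, nrow(sino))
  pad[seq_len(W), ] <- t(sino)
  ft <- mvfft(pad) * flt$resp
  out <- Re(mvfft(ft, inverse = TRUE)) / flt$n
  t(out[seq_len(W), , drop = FALSE])
}

#' Invert volume intensities
#'
#' `v' = max(v) - v`: attenuating cells, which reconstruct dark in
#' transmission contrast, become bright for segmentation and display.
#' Applying it twice restores the original up to a constant offset (ranks
#' are preserved exactly).
#'
#' @param volume a [ReconVolume-class] with finite voxels.
#' @return the inverted [ReconVolume-class].
#' @export
invertIntensity <- function(volume) {
  stopifnot(is(volume, "ReconVolume"))
  if (any(!is.finite(volume@data))) stop("volume contains non-finite voxels")
  initialize(volume, data = max(volume@data) - volume@data)
}

#' Reconstruct a full projection stack into a volume
#'
#' Convenience wrapper: builds per-slice sinograms, optionally estimates the
#' center of rotation automatically, and runs [fbpReconstruct()].
#'
#' @param stack a [ProjectionStack-class] (attenuation or emission domain).
#' @param cor `"auto"` to estimate via [estimateCOR()] on the middle slice,
#'   or a numeric manual offset. Default 0.
#' @param filterName passed to [fbpReconstruct()].
#' @return a [ReconVolume-class]; the offset used is recorded in
#'   `provenance`.
#' @export
reconstructStack <- function(stack, cor = 0,
                             filterName = c("ramp", "hann", "none")) {
  filterName <- match.arg(filterName)
  sinos <- buildSinograms(stack)
  corUsed <- if (identical(cor, "auto")) {
    mid <- sinos[[max(1L, length(sinos) %/% 2L)]]
    estimateCOR(mid, stack@anglesDeg)
  } else {
    as.numeric(cor)
  }
  vol <- fbpReconstruct(sinos, stack@anglesDeg, corUsed, filterName,
                        pixelPitchUm = stack@pixelPitchUm)
  vol@provenance$corMode <- if (identical(cor, "auto")) "auto" else "manual"
  vol
}
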