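#' Band threshold a volume into a binary mask
#'
#' `mask = (tMin <= v) & (v <= tMax)`. When `tMin` is omitted it defaults to
#' the Otsu threshold of the volume's intensity distribution; `tMax`
#' defaults to the volume maximum. Chosen values are reported via
#' `message()`, mirroring an interactive min/max adjustment.
#'
#' @param volume a [ReconVolume-class] (cells bright, i.e. inverted
#'   transmission or fluorescence contrast).
#' @param tMin lower threshold; default Otsu.
#' @param tMax upper threshold; default `max(volume)`.
#' @return logical array of the volume's shape.
#' @export
thresholdVolume <- function(volume, tMin = NULL, tMax = NULL) {
  stopifnot(is(volume, "ReconVolume"))
  v <- volume@data
  chosen <- FALSE
  if (is.null(tMin)) {
    tMin <- otsuThreshold(v)
    chosen <- TRUE
  }
  if (is.null(tMax)) {
    tMax <- max(v)
    chosen <- TRUE
  }
  if (tMin >= tMax) stop("tMin must be strictly less than tMax")
  if (chosen) message(sprintf("thresholdVolume: tMin = %.6g, tMax = %.6g", tMin, tMax))
  m <- v >= tMin & v <= tMax
  storage.mode(m) <- "logical"
  m
}

# Otsu threshold of arbitrary-range data via EBImage on the normalized
# intensity distribution.
otsuThreshold <- function(v) {
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("cannot compute Otsu threshold of a constant volume")
  vn <- (as.vector(v) - lo) / (hi - lo)
  t01 <- EBImage::otsu(EBImage::Image(matrix(vn, nrow = 1L)), range = c(0, 1))
  lo + t01 * (hi - lo)
}

# Integer offsets (dz, dy, dx) of a digital ball of given radius.
ballOffsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  g <- g[g$dz^2 + g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

#' Morphological closing with a 3D ball structuring element
#'
#' Dilation followed by erosion with the same digital ball, bridging small
#' gaps and filling interior holes up to the ball scale. `radius = 0` is the
#' identity. Voxels outside the volume are treated as background.
#'
#' @param mask logical 3D array.
#' @param radiusVoxels integer ball radius (>= 0). Default 1.
#' @return closed logical array.
#' @export
morphClose <- function(mask, radiusVoxels = 1L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (radiusVoxels < 0) stop("radius must be >= 0")
  if (radiusVoxels == 0) return(mask)
  off <- ballOffsets(radiusVoxels)
  dims <- dim(mask)
  d <- cpp_morph3d(mask, dims, off, TRUE)
  e <- cpp_morph3d(d, dims, off, FALSE)
  out <- array(e, dim = dims)
  storage.mode(out) <- "logical"
  out
}

#' Remove small connected components from a mask
#'
#' Deletes 26-connected components with fewer than `minVoxels` voxels —
#' the small-particle filter that removes hydrogel-texture and
#' reconstruction artifacts. Other components are untouched.
#'
#' @param mask logical 3D array.
#' @param minVoxels minimum surviving component size (>= 0).
#' @param connectivity 6, 18 or 26. Default 26.
#' @return filtered logical array.
#' @export
removeSmallParticles <- function(mask, minVoxels, connectivity = 26L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, minVoxels >= 0)
  if (minVoxels == 0) return(mask)
  lab <- cpp_label3d(mask, dim(mask), as.integer(connectivity))
  n <- attr(lab, "n_labels")
  if (n == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(sizes >= minVoxels)
  out <- array(lab %in% keep & lab > 0L, dim = dim(mask))
  storage.mode(out) <- "logical"
  out
}

#' Default minimum particle size
#'
#' The voxel count of a sphere of the given diameter at the given pitch —
#' by default 10 um, the smallest plausible cell-scale object, so anything
#' smaller is treated as debris.
#'
#' @param voxelPitchUm voxel pitch (um).
#' @param diameterUm sphere diameter (um). Default 10.
#' @return integer voxel count (>= 1).
#' @export
defaultMinVoxels <- function(voxelPitchUm, diameterUm = 10) {
  r <- diameterUm / 2 / voxelPitchUm
  max(1L, as.integer(round(4 / 3 * pi * r^3)))
}

#' Label connected components of a binary mask
#'
#' Deterministic 3D connected-component labeling: components are numbered
#' 1..n in order of first encounter in the array's linear scan, so identical
#' masks always yield identical labelings.
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26. Default 26.
#' @param voxelPitchUm voxel pitch stamped on the result. Default 1.
#' @return a [LabelVolume-class].
#' @export
labelComponents <- function(mask, connectivity = 26L, voxelPitchUm = 1) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  lab <- cpp_label3d(mask, dim(mask), as.integer(connectivity))
  n <- attr(lab, "n_labels")
  labels <- array(as.integer(lab), dim = dim(mask))
  new("LabelVolume", labels = labels, nLabels = as.integer(n),
      connectivity = as.integer(connectivity),
      voxelPitchUm = as.numeric(voxelPitchUm))
}

#' End-to-end segmentation of a reconstructed volume
#'
#' The paper-order pipeline on a cells-bright volume: band threshold
#' (Otsu default), 3D morphological closing, small-particle removal, and
#' connected-component labeling.
#'
#' @param volume a [ReconVolume-class], cells bright.
#' @param tMin,tMax thresholds; see [thresholdVolume()].
#' @param closeRadius ball radius for [morphClose()]. Default 1.
#' @param minVoxels small-particle cutoff; default
#'   `defaultMinVoxels(voxelPitch(volume))`.
#' @param connectivity labeling connectivity. Default 26.
#' @return a [LabelVolume-class].
#' @export
segmentVolume <- function(volume, tMin = NULL, tMax = NULL, closeRadius = 1L,
                          minVoxels = NULL, connectivity = 26L) {
  if (is.null(minVoxels)) minVoxels <- defaultMinVoxels(volume@voxelPitchUm)
  m <- thresholdVolume(volume, tMin, tMax)
  m <- morphClose(m, closeRadius)
  m <- removeSmallParticles(m, minVoxels, connectivity)
  labelComponents(m, connectivity, volume@voxelPitchUm)
}
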