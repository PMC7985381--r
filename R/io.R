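#' Write / read a projection stack as multi-page TIFF + JSON descriptor
#'
#' Pages are stored as 32-bit float TIFF normalized to [0, 1]; the sidecar
#' descriptor (`<path>.json`) records the intensity range, angle list, pixel
#' pitch, modality and any center-of-rotation offset, so reading restores
#' the original values.
#'
#' @param stack a [ProjectionStack-class].
#' @param path output TIFF path (the descriptor goes to `<path>.json`).
#' @param corOffsetPx optional offset recorded in the descriptor.
#' @return `path`, invisibly.
#' @export
writeProjectionStack <- function(stack, path, corOffsetPx = NULL) {
  stopifnot(is(stack, "ProjectionStack"))
  rng <- range(stack@data)
  pages <- lapply(seq_len(dim(stack@data)[1L]), function(a) {
    normalizeRange(stack@data[a, , ], rng)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  desc <- list(
    type = "ProjectionStack", angles_deg = stack@anglesDeg,
    pixel_pitch_um = stack@pixelPitchUm, modality = stack@modality,
    intensity_range = rng
  )
  if (!is.null(corOffsetPx)) desc$cor_offset_px <- corOffsetPx
  jsonlite::write_json(desc, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeProjectionStack
#' @export
readProjectionStack <- function(path) {
  desc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- array(0, dim = c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]])))
  for (a in seq_along(pages)) {
    d[a, , ] <- denormalizeRange(pages[[a]], desc$intensity_range)
  }
  new("ProjectionStack", data = d, anglesDeg = as.numeric(desc$angles_deg),
      pixelPitchUm = as.numeric(desc$pixel_pitch_um), modality = desc$modality)
}

#' Write / read a volume as multi-page TIFF + JSON descriptor
#'
#' One page per z slice, 32-bit float normalized to [0, 1] with the range
#' recorded in `<path>.json` along with voxel pitch and provenance.
#'
#' @param volume a [ReconVolume-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeReconVolume <- function(volume, path) {
  stopifnot(is(volume, "ReconVolume"))
  rng <- range(volume@data)
  pages <- lapply(seq_len(dim(volume@data)[1L]), function(z) {
    normalizeRange(volume@data[z, , ], rng)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(type = "ReconVolume", voxel_pitch_um = volume@voxelPitchUm,
         intensity_range = rng, provenance = volume@provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname writeReconVolume
#' @export
readReconVolume <- function(path) {
  desc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- array(0, dim = c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]])))
  for (z in seq_along(pages)) {
    d[z, , ] <- denormalizeRange(pages[[z]], desc$intensity_range)
  }
  new("ReconVolume", data = d, voxelPitchUm = as.numeric(desc$voxel_pitch_um),
      provenance = as.list(desc$provenance))
}

#' Write / read a label volume as 16-bit multi-page TIFF + JSON descriptor
#'
#' Labels are stored as 16-bit grayscale (label / 65535), so at most 65535
#' components can be represented.
#'
#' @param labelVolume a [LabelVolume-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeLabelVolume <- function(labelVolume, path) {
  stopifnot(is(labelVolume, "LabelVolume"))
  if (labelVolume@nLabels > 65535L) stop("more than 65535 labels")
  pages <- lapply(seq_len(dim(labelVolume@labels)[1L]), function(z) {
    labelVolume@labels[z, , ] / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(type = "LabelVolume", n_labels = labelVolume@nLabels,
         connectivity = labelVolume@connectivity,
         voxel_pitch_um = labelVolume@voxelPitchUm),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname writeLabelVolume
#' @export
readLabelVolume <- function(path) {
  desc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- array(0L, dim = c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]])))
  for (z in seq_along(pages)) {
    d[z, , ] <- as.integer(round(pages[[z]] * 65535))
  }
  new("LabelVolume", labels = d, nLabels = as.integer(desc$n_labels),
      connectivity = as.integer(desc$connectivity),
      voxelPitchUm = as.numeric(desc$voxel_pitch_um))
}

#' Write / read a phantom ground-truth registry (CSV + JSON scalars)
#'
#' @param truth a [PhantomTruth-class].
#' @param pathPrefix files are written to `<pathPrefix>.csv` (one row per
#'   cell) and `<pathPrefix>.json` (scalars).
#' @return `pathPrefix`, invisibly.
#' @export
writePhantomTruth <- function(truth, pathPrefix) {
  stopifnot(is(truth, "PhantomTruth"))
  write.csv(truth@cells, paste0(pathPrefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(type = "PhantomTruth",
         realized_density_cells_per_ml = truth@realizedDensityPerMl,
         analysis_cylinder_volume_ml = truth@analysisVolumeMl),
    paste0(pathPrefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(pathPrefix)
}

#' @rdname writePhantomTruth
#' @export
readPhantomTruth <- function(pathPrefix) {
  cells <- read.csv(paste0(pathPrefix, ".csv"))
  sc <- jsonlite::read_json(paste0(pathPrefix, ".json"), simplifyVector = TRUE)
  new("PhantomTruth", cells = cells,
      realizedDensityPerMl = sc$realized_density_cells_per_ml,
      analysisVolumeMl = sc$analysis_cylinder_volume_ml)
}

normalizeRange <- function(m, rng) {
  if (rng[2L] > rng[1L]) (m - rng[1L]) / (rng[2L] - rng[1L]) else m * 0
}

denormalizeRange <- function(m, rng) {
  if (rng[2L] > rng[1L]) m * (rng[2L] - rng[1L]) + rng[1L] else m + rng[1L]
}
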