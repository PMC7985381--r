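#' Accessors for optmorph containers
#'
#' `projData`, `anglesDeg`, `modality` access projection stacks; `volData`
#' and `voxelPitch` access volumes; `labelData` and `nLabels` access label
#' volumes. `pixelPitch` applies to both stacks and volumes.
#'
#' @param x an optmorph object.
#' @return the slot contents.
#' @name accessors
#' @aliases projData anglesDeg modality volData voxelPitch pixelPitch
#'   labelData nLabels
NULL

#' @rdname accessors
#' @export
setGeneric("projData", function(x) standardGeneric("projData"))
#' @rdname accessors
#' @export
setGeneric("anglesDeg", function(x) standardGeneric("anglesDeg"))
#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname accessors
#' @export
setGeneric("pixelPitch", function(x) standardGeneric("pixelPitch"))
#' @rdname accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname accessors
#' @export
setGeneric("voxelPitch", function(x) standardGeneric("voxelPitch"))
#' @rdname accessors
#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))
#' @rdname accessors
#' @export
setGeneric("nLabels", function(x) standardGeneric("nLabels"))
#' @rdname accessors
#' @export
setGeneric("truthCells", function(x) standardGeneric("truthCells"))

#' @rdname accessors
setMethod("projData", "ProjectionStack", function(x) x@data)
#' @rdname accessors
setMethod("anglesDeg", "ProjectionStack", function(x) x@anglesDeg)
#' @rdname accessors
setMethod("modality", "ProjectionStack", function(x) x@modality)
#' @rdname accessors
setMethod("pixelPitch", "ProjectionStack", function(x) x@pixelPitchUm)
#' @rdname accessors
setMethod("volData", "ReconVolume", function(x) x@data)
#' @rdname accessors
setMethod("voxelPitch", "ReconVolume", function(x) x@voxelPitchUm)
#' @rdname accessors
setMethod("pixelPitch", "ReconVolume", function(x) x@voxelPitchUm)
#' @rdname accessors
setMethod("labelData", "LabelVolume", function(x) x@labels)
#' @rdname accessors
setMethod("nLabels", "LabelVolume", function(x) x@nLabels)
#' @rdname accessors
setMethod("voxelPitch", "LabelVolume", function(x) x@voxelPitchUm)
#' @rdname accessors
setMethod("truthCells", "PhantomTruth", function(x) x@cells)

setMethod("show", "ProjectionStack", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "ProjectionStack: %d projections (%d x %d px), %s, pitch %.3g um\n",
    d[1L], d[2L], d[3L], object@modality, object@pixelPitchUm
  ))
  if (d[1L]) {
    cat(sprintf(
      "  angles: %.4g .. %.4g deg (step ~%.4g)\n", object@anglesDeg[1L],
      object@anglesDeg[d[1L]],
      if (d[1L] > 1L) mean(diff(object@anglesDeg)) else NA_real_
    ))
  }
})

setMethod("show", "ReconVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "ReconVolume: %d x %d x %d voxels (z,y,x), pitch %.3g um, range [%.4g, %.4g]\n",
    d[1L], d[2L], d[3L], object@voxelPitchUm, min(object@data), max(object@data)
  ))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@labels)
  cat(sprintf(
    "LabelVolume: %d x %d x %d voxels, %d components (connectivity %d)\n",
    d[1L], d[2L], d[3L], object@nLabels, object@connectivity
  ))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf(
    "PhantomTruth: %d cells (%d dead), realized density %.4g cells/mL over %.4g uL\n",
    nrow(object@cells), sum(object@cells$is_dead),
    object@realizedDensityPerMl, object@analysisVolumeMl * 1e3
  ))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf(
    "GroupComparison [%s]: statistic %.4g, global p %.3g (alpha %.3g)\n",
    object@testName, object@globalStatistic, object@globalP, object@alpha
  ))
  if (nrow(object@pairwise)) {
    cat(sprintf("  %d pairwise comparisons, %d significant\n",
                nrow(object@pairwise), sum(object@pairwise$significant)))
  }
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: tube %g um ID, %d x %d x %d voxels at %g um, %s, dead fraction %g\n",
    object@tubeInnerDiameterUm, object@volumeShapeVoxels[1L],
    object@volumeShapeVoxels[2L], object@volumeShapeVoxels[3L],
    object@voxelPitchUm,
    if (is.na(object@nCells)) sprintf("%g cells/mL", object@seededDensityPerMl)
    else sprintf("%d cells", as.integer(object@nCells)),
    object@deadFraction
  ))
})
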