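#' ProjectionStack: an ordered angular series of 2D projections
#'
#' Container for a tomographic projection series. `data` is a numeric array
#' indexed `angle x row x column`; rows correspond to axial (z) slices of the
#' sample, columns to detector positions. Angles are in degrees,
#' counterclockwise, strictly increasing in [0, 360); angle 0 aligns the
#' detector columns with the volume x axis.
#'
#' @slot data numeric array, `angle x row x column`, nonnegative.
#' @slot anglesDeg numeric vector of acquisition angles (degrees).
#' @slot pixelPitchUm detector pixel pitch in micrometers.
#' @slot modality one of `"bright_field"`, `"fluor_live"`, `"fluor_dead"`.
#' @exportClass ProjectionStack
setClass("ProjectionStack",
  representation(
    data = "array",
    anglesDeg = "numeric",
    pixelPitchUm = "numeric",
    modality = "character"
  )
)

setValidity("ProjectionStack", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3D array (angle x row x column)")
  a <- object@anglesDeg
  if (length(a) != dim(d)[1L]) return("length(anglesDeg) must equal dim(data)[1]")
  if (length(a) && (any(a < 0) || any(a >= 360))) return("angles must lie in [0, 360)")
  if (length(a) > 1L && any(diff(a) <= 0)) return("angles must be strictly increasing")
  if (any(!is.finite(d))) return("projection data must be finite")
  if (any(d < 0)) return("projection intensities must be nonnegative")
  if (length(object@pixelPitchUm) != 1L || object@pixelPitchUm <= 0)
    return("pixelPitchUm must be a single positive number")
  if (!object@modality %in% c("bright_field", "fluor_live", "fluor_dead"))
    return("modality must be bright_field, fluor_live or fluor_dead")
  TRUE
})

#' ReconVolume: a reconstructed (or phantom) 3D intensity volume
#'
#' `data` is a numeric array indexed `z x y x x` with isotropic voxel pitch
#' in micrometers; y and x extents are equal (square slices, the
#' parallel-beam detector width).
#'
#' @slot data numeric array, `z x y x x`.
#' @slot voxelPitchUm isotropic voxel pitch in micrometers.
#' @slot provenance list of free-form acquisition/reconstruction metadata.
#' @exportClass ReconVolume
setClass("ReconVolume",
  representation(
    data = "array",
    voxelPitchUm = "numeric",
    provenance = "list"
  ),
  prototype(provenance = list())
)

setValidity("ReconVolume", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3D array (z x y x x)")
  if (dim(d)[2L] != dim(d)[3L]) return("slices must be square (y extent == x extent)")
  if (length(object@voxelPitchUm) != 1L || object@voxelPitchUm <= 0)
    return("voxelPitchUm must be a single positive number")
  TRUE
})

#' LabelVolume: a 3D connected-component labeling
#'
#' Integer array of the same shape as the segmented volume; 0 is background
#' and labels run 1..nLabels with no gaps, each connected under the declared
#' connectivity.
#'
#' @slot labels integer array, `z x y x x`.
#' @slot nLabels number of labeled components.
#' @slot connectivity 6, 18 or 26.
#' @slot voxelPitchUm isotropic voxel pitch in micrometers.
#' @exportClass LabelVolume
setClass("LabelVolume",
  representation(
    labels = "array",
    nLabels = "integer",
    connectivity = "integer",
    voxelPitchUm = "numeric"
  )
)

setValidity("LabelVolume", function(object) {
  l <- object@labels
  if (length(dim(l)) != 3L) return("labels must be a 3D array")
  n <- object@nLabels
  if (length(n) != 1L || n < 0L) return("nLabels must be a single nonnegative integer")
  if (n > 0L) {
    tab <- tabulate(l[l > 0L], nbins = n)
    if (max(l) != n || any(tab == 0L))
      return("label values must be exactly {0, 1, ..., nLabels} with no gaps")
  } else if (any(l != 0L)) {
    return("nLabels is 0 but nonzero labels present")
  }
  if (!object@connectivity %in% c(6L, 18L, 26L)) return("connectivity must be 6, 18 or 26")
  TRUE
})

#' PhantomSpec: parameters of a cell-laden hydrogel digital phantom
#'
#' Describes the simulated sample: a transparent hydrogel cylinder (the FEP
#' tube lumen) seeded with ellipsoidal cells. Either `nCells` or
#' `seededDensityPerMl` fixes the cell count; if both are given they must be
#' mutually consistent. Dead cells are rendered at
#' `cellContrast * deadContrastFactor`, emulating the optical-contrast loss
#' of membrane-compromised cells.
#'
#' Use [phantomSpec()] to construct.
#'
#' @slot tubeInnerDiameterUm inner diameter of the sample tube (um).
#' @slot volumeShapeVoxels integer (z, y, x) volume shape.
#' @slot voxelPitchUm isotropic voxel pitch (um).
#' @slot nCells cell count (NA if given by density).
#' @slot seededDensityPerMl seeding density in cells/mL (NA if given by count).
#' @slot semiAxisRangeUm 3 x 2 matrix of (min, max) um per sorted semi-axis
#'   (rows: largest, medium, smallest).
#' @slot cellContrast attenuation amplitude of a live cell vs background.
#' @slot deadFraction proportion of dead cells in [0, 1].
#' @slot deadContrastFactor contrast multiplier for dead cells in [0, 1).
#' @slot illuminationAmplitude relative amplitude of the multiplicative
#'   low-frequency illumination bias.
#' @slot noiseScale photon-noise intensity parameter (0 = noiseless).
#' @slot corOffsetPx signed detector-column shift of the rotation axis.
#' @slot wallMarginVoxels wall margin excluded from the analysis cylinder.
#' @slot minClearanceUm minimum surface-to-surface clearance between cells
#'   (bounding-sphere approximation) enforced during placement.
#' @slot maxPlacementRetries rejection-sampling retry cap per cell.
#' @slot rngSeed integer seed.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    tubeInnerDiameterUm = "numeric",
    volumeShapeVoxels = "integer",
    voxelPitchUm = "numeric",
    nCells = "numeric",
    seededDensityPerMl = "numeric",
    semiAxisRangeUm = "matrix",
    cellContrast = "numeric",
    deadFraction = "numeric",
    deadContrastFactor = "numeric",
    illuminationAmplitude = "numeric",
    noiseScale = "numeric",
    corOffsetPx = "numeric",
    wallMarginVoxels = "numeric",
    minClearanceUm = "numeric",
    maxPlacementRetries = "numeric",
    rngSeed = "numeric"
  )
)

setValidity("PhantomSpec", function(object) {
  if (object@tubeInnerDiameterUm <= 0) return("tubeInnerDiameterUm must be positive")
  if (length(object@volumeShapeVoxels) != 3L || any(object@volumeShapeVoxels < 1L))
    return("volumeShapeVoxels must be three positive integers (z, y, x)")
  if (object@volumeShapeVoxels[2L] != object@volumeShapeVoxels[3L])
    return("volume slices must be square (y extent == x extent)")
  if (object@voxelPitchUm <= 0) return("voxelPitchUm must be positive")
  if (is.na(object@nCells) && is.na(object@seededDensityPerMl))
    return("one of nCells or seededDensityPerMl must be given")
  if (any(object@semiAxisRangeUm <= 0) || any(object@semiAxisRangeUm[, 2L] < object@semiAxisRangeUm[, 1L]))
    return("semiAxisRangeUm must be positive with max >= min per axis")
  if (object@deadFraction < 0 || object@deadFraction > 1)
    return("deadFraction must lie in [0, 1]")
  if (object@deadContrastFactor < 0 || object@deadContrastFactor >= 1)
    return("deadContrastFactor must lie in [0, 1)")
  if (object@illuminationAmplitude < 0) return("illuminationAmplitude must be >= 0")
  if (object@noiseScale < 0) return("noiseScale must be >= 0")
  fovUm <- object@volumeShapeVoxels[2L] * object@voxelPitchUm
  if (object@tubeInnerDiameterUm > fovUm)
    return("volume too small to contain the tube cylinder")
  TRUE
})

#' PhantomTruth: ground-truth registry of a simulated sample
#'
#' One row per rendered cell (center in um, sorted semi-axes, body-to-world
#' rotation, live/dead flag) plus the realized density over the analysis
#' cylinder. `realizedDensityPerMl * analysisVolumeMl` equals the cell count
#' exactly.
#'
#' @slot cells data.frame with columns id, center_z_um, center_y_um,
#'   center_x_um, a_um, b_um, c_um, R11..R33, is_dead.
#' @slot realizedDensityPerMl realized density (cells/mL).
#' @slot analysisVolumeMl analysis cylinder volume (mL).
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  representation(
    cells = "data.frame",
    realizedDensityPerMl = "numeric",
    analysisVolumeMl = "numeric"
  )
)

setValidity("PhantomTruth", function(object) {
  cl <- object@cells
  n <- nrow(cl)
  if (n > 0L) {
    if (any(cl$a_um < cl$b_um) || any(cl$b_um < cl$c_um))
      return("semi-axes must be sorted descending (a >= b >= c)")
    if (any(cl$c_um <= 0)) return("semi-axes must be positive")
  }
  if (object@analysisVolumeMl <= 0) return("analysisVolumeMl must be positive")
  if (abs(object@realizedDensityPerMl * object@analysisVolumeMl - n) > 1e-6)
    return("realizedDensityPerMl must equal nrow(cells) / analysisVolumeMl")
  TRUE
})

#' GroupComparison: result of a multi-group statistical comparison
#'
#' @slot testName e.g. "oneway_anova_bonferroni" or "kruskal_wallis_dunn".
#' @slot globalStatistic global F or H statistic.
#' @slot globalP global p-value.
#' @slot pairwise data.frame: group_a, group_b, statistic, p_raw, p_adjusted,
#'   significant.
#' @slot alpha significance level.
#' @slot normalityPs per-group Shapiro-Wilk p-values (may be empty).
#' @exportClass GroupComparison
setClass("GroupComparison",
  representation(
    testName = "character",
    globalStatistic = "numeric",
    globalP = "numeric",
    pairwise = "data.frame",
    alpha = "numeric",
    normalityPs = "numeric"
  )
)

setValidity("GroupComparison", function(object) {
  pw <- object@pairwise
  if (nrow(pw)) {
    if (any(pw$p_adjusted < 0 | pw$p_adjusted > 1)) return("adjusted p must lie in [0, 1]")
    if (!identical(pw$significant, pw$p_adjusted < object@alpha))
      return("significant flag must equal p_adjusted < alpha")
  }
  TRUE
})
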