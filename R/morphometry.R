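#' Equivalent-ellipsoid radii of a labeled voxel set
#'
#' The cell's "radii" are the semi-axes of the ellipsoid whose second
#' central moments match the voxel distribution: with eigenvalues
#' `lambda_1 >= lambda_2 >= lambda_3` of the voxel-coordinate covariance
#' matrix (population moments, voxel centers scaled to um), the radii are
#' `sqrt(5 * lambda)` — the continuous-ellipsoid calibration, under which a
#' digitized ball of radius r reports a radius of approximately r.
#'
#' Voxel sets below `shapeFloor` voxels, or with degenerate (coplanar /
#' collinear) covariance, are flagged `shape_valid = FALSE`; degenerate
#' radii are floored at half the voxel pitch with a warning.
#'
#' @param coords integer matrix of voxel indices (rows; columns z, y, x).
#' @param voxelPitchUm isotropic voxel pitch (um).
#' @param shapeFloor minimum voxel count for a trustworthy shape. Default 8.
#' @return list with `radiiUm` (descending: largest, medium, smallest) and
#'   `shapeValid`.
#' @export
fitEllipsoidRadii <- function(coords, voxelPitchUm, shapeFloor = 8L) {
  stopifnot(is.matrix(coords), ncol(coords) == 3L, voxelPitchUm > 0)
  n <- nrow(coords)
  if (n == 0L) stop("empty voxel set")
  xyz <- coords * voxelPitchUm
  ctr <- colMeans(xyz)
  dev <- sweep(xyz, 2L, ctr)
  covm <- crossprod(dev) / n # population second central moments
  ev <- sort(eigen(covm, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  valid <- n >= shapeFloor
  floorUm <- voxelPitchUm / 2
  if (any(ev <= 0) || sqrt(5 * max(ev[3L], 0)) < floorUm) {
    if (n >= shapeFloor) {
      warning("degenerate voxel covariance; smallest radius floored at pitch/2")
    }
    valid <- FALSE
  }
  radii <- pmax(sqrt(5 * pmax(ev, 0)), floorUm)
  list(radiiUm = radii, shapeValid = valid)
}

#' Cell elongation
#'
#' Ratio of the largest to the medium equivalent-ellipsoid radius; 1 for a
#' sphere, much greater than 1 for spindle-shaped (well-adhered) cells.
#'
#' @param rLargest,rMedium radii with `rLargest >= rMedium > 0`.
#' @return `rLargest / rMedium`.
#' @export
elongation <- function(rLargest, rMedium) {
  if (any(rMedium <= 0)) stop("rMedium must be positive")
  rLargest / rMedium
}

#' Cell flatness
#'
#' Ratio of the medium to the smallest equivalent-ellipsoid radius; 1 for a
#' sphere, much greater than 1 for disk-like cells.
#'
#' @param rMedium,rSmallest radii with `rMedium >= rSmallest > 0`.
#' @return `rMedium / rSmallest`.
#' @export
flatness <- function(rMedium, rSmallest) {
  if (any(rSmallest <= 0)) stop("rSmallest must be positive")
  rMedium / rSmallest
}

#' Cell density
#'
#' @param nCells cell count.
#' @param analysisVolumeMl counted volume in mL (> 0) — the cylindrical
#'   field-of-view mask minus the configured wall margin.
#' @return density in cells/mL (exact ratio).
#' @export
cellDensity <- function(nCells, analysisVolumeMl) {
  if (analysisVolumeMl <= 0) stop("analysisVolumeMl must be positive")
  nCells / analysisVolumeMl
}

#' Fraction of quantified vs initially seeded density
#'
#' @param quantifiedDensity quantified density (cells/mL).
#' @param initialDensity seeded density (cells/mL, > 0).
#' @return integer percent, `round(100 * quantified / initial)`.
#' @export
densityFraction <- function(quantifiedDensity, initialDensity) {
  if (any(initialDensity <= 0)) stop("initialDensity must be positive")
  as.integer(round(100 * quantifiedDensity / initialDensity))
}

#' Live/dead viability
#'
#' @param nLive,nDead cell counts from independently segmented live and
#'   dead fluorescence channels; their sum must be positive.
#' @return viability percent `100 * nLive / (nLive + nDead)`, rounded to
#'   one decimal.
#' @export
viability <- function(nLive, nDead) {
  if (nLive + nDead <= 0) stop("at least one cell required")
  round(100 * nLive / (nLive + nDead), 1)
}

#' Per-cell morphometric table of a label volume
#'
#' One row per label: centroid (um), voxel count, volume
#' (`voxel_count * pitch^3`), sorted equivalent-ellipsoid radii, elongation,
#' flatness, and the shape-validity flag. Deterministic: identical inputs
#' yield identical tables.
#'
#' @param labelVolume a [LabelVolume-class].
#' @param shapeFloor minimum voxel count for shape metrics. Default 8.
#' @return data.frame with columns label_id, centroid_z_um, centroid_y_um,
#'   centroid_x_um, voxel_count, volume_um3, R_largest_um, R_medium_um,
#'   R_smallest_um, elongation, flatness, shape_valid.
#' @export
cellTable <- function(labelVolume, shapeFloor = 8L) {
  stopifnot(is(labelVolume, "LabelVolume"))
  pitch <- labelVolume@voxelPitchUm
  n <- labelVolume@nLabels
  cols <- data.frame(
    label_id = integer(0), centroid_z_um = numeric(0),
    centroid_y_um = numeric(0), centroid_x_um = numeric(0),
    voxel_count = integer(0), volume_um3 = numeric(0),
    R_largest_um = numeric(0), R_medium_um = numeric(0),
    R_smallest_um = numeric(0), elongation = numeric(0),
    flatness = numeric(0), shape_valid = logical(0)
  )
  if (n == 0L) return(cols)
  idx <- which(labelVolume@labels > 0L)
  lab <- labelVolume@labels[idx]
  dims <- dim(labelVolume@labels)
  z <- (idx - 1L) %% dims[1L]
  rest <- (idx - 1L) %/% dims[1L]
  y <- rest %% dims[2L]
  x <- rest %/% dims[2L]
  rows <- lapply(seq_len(n), function(k) {
    sel <- lab == k
    coords <- cbind(z[sel], y[sel], x[sel])
    fit <- fitEllipsoidRadii(coords, pitch, shapeFloor)
    r <- fit$radiiUm
    data.frame(
      label_id = k,
      centroid_z_um = mean(coords[, 1L]) * pitch,
      centroid_y_um = mean(coords[, 2L]) * pitch,
      centroid_x_um = mean(coords[, 3L]) * pitch,
      voxel_count = nrow(coords),
      volume_um3 = nrow(coords) * pitch^3,
      R_largest_um = r[1L], R_medium_um = r[2L], R_smallest_um = r[3L],
      elongation = elongation(r[1L], r[2L]),
      flatness = flatness(r[2L], r[3L]),
      shape_valid = fit$shapeValid
    )
  })
  do.call(rbind, rows)
}

#' Summarize a segmented sample
#'
#' Emits the per-cell table plus sample-level metrics: cell count, density
#' over the analysis volume, and median/Q1/Q3 summaries of elongation and
#' flatness over shape-valid cells (linear-interpolation quantiles, R type
#' 7). Viability is attached when live/dead counts are supplied.
#'
#' @param labelVolume a [LabelVolume-class].
#' @param analysisVolumeMl counted volume in mL.
#' @param groupLabel free-text group tag. Default `""`.
#' @param viabilityPercent optional precomputed viability.
#' @param shapeFloor minimum voxel count for shape metrics. Default 8.
#' @return list with `metrics` (list: n_cells, analysis_volume_ml,
#'   density_cells_per_ml, elongation_median/q1/q3, flatness_median/q1/q3,
#'   viability_percent, group_label) and `cells` (the per-cell data.frame).
#' @export
summarizeSample <- function(labelVolume, analysisVolumeMl, groupLabel = "",
                            viabilityPercent = NA_real_, shapeFloor = 8L) {
  cells <- cellTable(labelVolume, shapeFloor)
  valid <- cells[cells$shape_valid, , drop = FALSE]
  q3 <- function(x) {
    if (!length(x)) return(c(NA_real_, NA_real_, NA_real_))
    quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  }
  eq <- q3(valid$elongation)
  fq <- q3(valid$flatness)
  if (!is.na(viabilityPercent) &&
      (viabilityPercent < 0 || viabilityPercent > 100)) {
    stop("viabilityPercent must lie in [0, 100]")
  }
  metrics <- list(
    n_cells = nrow(cells),
    analysis_volume_ml = analysisVolumeMl,
    density_cells_per_ml = cellDensity(nrow(cells), analysisVolumeMl),
    elongation_median = eq[1L], elongation_q1 = eq[2L], elongation_q3 = eq[3L],
    flatness_median = fq[1L], flatness_q1 = fq[2L], flatness_q3 = fq[3L],
    viability_percent = viabilityPercent,
    group_label = groupLabel
  )
  list(metrics = metrics, cells = cells)
}
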