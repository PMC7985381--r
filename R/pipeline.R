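#' Run the full OPT quantification pipeline
#'
#' Ties the stages into one reproducible run. Bright-field route: simulate
#' (or read) projections, convert to transmission, apply illumination bias
#' and photon noise as configured, homomorphic brightness normalization,
#' back to attenuation, filtered back-projection with center-of-rotation
#' correction, intensity inversion, segmentation, morphometry. Fluorescence
#' route: live and dead channel stacks are median-filtered,
#' brightness-adjusted and aligned (no homomorphic step), reconstructed and
#' segmented independently, and viability is computed from the two counts.
#'
#' Every artifact is written under `outDir`; `manifest.json` captures the
#' package version, the full effective configuration, seeds and md5 hashes
#' of all outputs, so a run is re-derivable from the manifest alone.
#'
#' @param config a nested list, or the path of a YAML/JSON file holding
#'   one. Sections: `seed`; `modality` ("bright_field" or "fluorescence");
#'   `simulate` (arguments of [phantomSpec()]); `preprocess`
#'   (`cutoff_freq`, `low_gain`, `high_gain`, `median_window`); `reconstruct`
#'   (`cor` = "auto" or a number, `filter`); `segment` (`t_min`, `t_max`,
#'   `close_radius`, `min_voxels`, `connectivity`); `group_label`.
#' @param outDir output directory (created if missing).
#' @return invisibly, a list with `metrics`, `cells`, `manifest`, and the
#'   key objects (`volume`, `labels`, `truth`).
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  config <- validateConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  sim <- config$simulate
  sim$rngSeed <- seed # the run seed governs every stochastic stage
  spec <- do.call(phantomSpec, sim)
  ph <- generatePhantom(spec)
  writePhantomTruth(ph$truth, file.path(outDir, "truth"))

  if (config$modality == "bright_field") {
    res <- runBrightField(config, spec, ph, outDir, seed)
  } else {
    res <- runFluorescence(config, spec, ph, outDir, seed)
  }

  summ <- summarizeSample(res$labels, ph$truth@analysisVolumeMl,
                          groupLabel = config$group_label,
                          viabilityPercent = res$viability)
  summ$metrics$seeded_density_cells_per_ml <- ph$truth@realizedDensityPerMl
  summ$metrics$density_fraction_percent <- densityFraction(
    summ$metrics$density_cells_per_ml, ph$truth@realizedDensityPerMl
  )
  write.csv(summ$cells, file.path(outDir, "cells.csv"), row.names = FALSE)
  jsonlite::write_json(summ$metrics, file.path(outDir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)

  files <- sort(list.files(outDir, recursive = TRUE))
  files <- setdiff(files, "manifest.json")
  hashes <- md5sum(file.path(outDir, files))
  names(hashes) <- files
  manifest <- list(
    package = "optmorph",
    version = as.character(utils::packageVersion("optmorph")),
    config = config, seed = seed, stage_params = res$params,
    outputs = as.list(hashes)
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(metrics = summ$metrics, cells = summ$cells,
                 manifest = manifest, volume = res$volume,
                 labels = res$labels, truth = ph$truth))
}

validateConfig <- function(config) {
  stopifnot(is.list(config))
  config$seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  config$modality <- if (is.null(config$modality)) "bright_field" else config$modality
  if (!config$modality %in% c("bright_field", "fluorescence")) {
    stop("config: modality must be bright_field or fluorescence")
  }
  if (is.null(config$simulate)) stop("config: a simulate section is required")
  known <- names(formals(phantomSpec))
  bad <- setdiff(names(config$simulate), known)
  if (length(bad)) stop("config: unknown simulate keys: ", paste(bad, collapse = ", "))
  dflt <- function(x, d) if (is.null(x)) d else x
  pp <- config$preprocess
  config$preprocess <- list(
    cutoff_freq = dflt(pp$cutoff_freq, 0.02),
    low_gain = dflt(pp$low_gain, 0.3),
    high_gain = dflt(pp$high_gain, 1),
    median_window = dflt(pp$median_window, 3L)
  )
  rc <- config$reconstruct
  config$reconstruct <- list(cor = dflt(rc$cor, 0), filter = dflt(rc$filter, "ramp"))
  aq <- config$acquisition
  config$acquisition <- list(n_angles = dflt(aq$n_angles, 400L),
                             step_deg = dflt(aq$step_deg, 0.9))
  sg <- config$segment
  config$segment <- list(
    t_min = sg$t_min, t_max = sg$t_max,
    close_radius = dflt(sg$close_radius, 1L),
    min_voxels = sg$min_voxels, connectivity = dflt(sg$connectivity, 26L)
  )
  config$group_label <- if (is.null(config$group_label)) "" else config$group_label
  config
}

runBrightField <- function(config, spec, ph, outDir, seed) {
  angles <- defaultAngles(config$acquisition$n_angles, config$acquisition$step_deg)
  stack <- forwardProject(ph$volume, angles, spec@corOffsetPx)
  trans <- toTransmission(stack)
  if (spec@illuminationAmplitude > 0) {
    trans <- applyIlluminationField(trans, spec@illuminationAmplitude,
                                    rngSeed = seed + 1L)
  }
  if (spec@noiseScale > 0) trans <- addNoise(trans, spec@noiseScale, seed + 2L)
  writeProjectionStack(trans, file.path(outDir, "projections_raw.tif"),
                       corOffsetPx = spec@corOffsetPx)
  pp <- config$preprocess
  filt <- homomorphicFilter(trans, pp$cutoff_freq, pp$low_gain, pp$high_gain)
  # reconstruct the transmission-contrast images directly (cells are dark
  # dips), then invert so cells are bright for segmentation
  vol <- reconstructStack(filt, cor = config$reconstruct$cor,
                          filterName = config$reconstruct$filter)
  vol <- invertIntensity(vol)
  writeReconVolume(vol, file.path(outDir, "recon.tif"))
  labels <- suppressMessages(segmentVolume(
    vol, config$segment$t_min, config$segment$t_max,
    config$segment$close_radius, config$segment$min_voxels,
    config$segment$connectivity
  ))
  writeLabelVolume(labels, file.path(outDir, "labels.tif"))
  list(volume = vol, labels = labels, viability = NA_real_,
       params = list(preprocess = pp, reconstruct = config$reconstruct,
                     segment = config$segment,
                     cor_used = vol@provenance$corOffsetPx))
}

runFluorescence <- function(config, spec, ph, outDir, seed) {
  channels <- list(
    live = renderChannelVolume(ph$truth, spec, "live"),
    dead = renderChannelVolume(ph$truth, spec, "dead")
  )
  pp <- config$preprocess
  angles <- defaultAngles(config$acquisition$n_angles, config$acquisition$step_deg)
  stacks <- list()
  for (ch in names(channels)) {
    st <- forwardProject(channels[[ch]], angles, spec@corOffsetPx,
                         modality = paste0("fluor_", ch))
    if (spec@noiseScale > 0) {
      st <- addNoise(st, spec@noiseScale,
                     seed + 2L + match(ch, names(channels)))
    }
    st <- medianFilterStack(st, pp$median_window)
    if (max(st@data) > min(st@data)) st <- brightnessAdjust(st)
    stacks[[ch]] <- st
  }
  comp <- tryCatch(composeLiveDead(stacks$live, stacks$dead),
                   warning = function(w) {
                     suppressWarnings(composeLiveDead(stacks$live, stacks$dead))
                   })
  counts <- integer(0)
  labelsByCh <- list()
  for (ch in names(stacks)) {
    writeProjectionStack(stacks[[ch]],
                         file.path(outDir, sprintf("projections_%s.tif", ch)),
                         corOffsetPx = spec@corOffsetPx)
    vol <- reconstructStack(stacks[[ch]], cor = config$reconstruct$cor,
                            filterName = config$reconstruct$filter)
    writeReconVolume(vol, file.path(outDir, sprintf("recon_%s.tif", ch)))
    labs <- if (max(vol@data) > min(vol@data)) {
      suppressMessages(segmentVolume(
        vol, config$segment$t_min, config$segment$t_max,
        config$segment$close_radius, config$segment$min_voxels,
        config$segment$connectivity
      ))
    } else {
      labelComponents(array(FALSE, dim(vol@data)), config$segment$connectivity,
                      vol@voxelPitchUm)
    }
    writeLabelVolume(labs, file.path(outDir, sprintf("labels_%s.tif", ch)))
    labelsByCh[[ch]] <- labs
    counts[ch] <- labs@nLabels
  }
  write.csv(comp$shifts, file.path(outDir, "align_shifts.csv"),
            row.names = FALSE)
  viab <- if (sum(counts) > 0) viability(counts[["live"]], counts[["dead"]]) else NA_real_
  list(volume = NULL, labels = labelsByCh$live, viability = viab,
       params = list(preprocess = pp, reconstruct = config$reconstruct,
                     segment = config$segment, counts = as.list(counts)))
}

#' Built-in fixture presets
#'
#' Scenario presets covering the conditions the package models:
#' `gg_like` (small near-spherical cells at 300k cells/mL),
#' `gelatin_gg_like` (elongated cells at 500k cells/mL), `geltrex_like`
#' (elongated and flat cells), `density_sweep` (300k / 500k / 1M cells/mL),
#' `cor_offset` (one phantom projected at rotation-axis offsets
#' -5, -2, 0, +2, +5 px) and `dead_fraction_sweep` (dead fractions 0 / 0.2
#' / 0.4 at sub-threshold dead contrast). Fixtures use a desk-scale grid
#' (96 x 96 x 48 voxels at 5 um) with the tube matched to the field of
#' view.
#'
#' @param preset one of the names above.
#' @param seed integer seed.
#' @param dir optional directory; when given, phantom truth (and stacks for
#'   `cor_offset`) are written there.
#' @return a list of named fixtures; each has `spec`, `volume`, `truth`,
#'   plus `stacks` for `cor_offset`.
#' @export
makeFixtures <- function(preset = c("gg_like", "gelatin_gg_like",
                                    "geltrex_like", "density_sweep",
                                    "cor_offset", "dead_fraction_sweep"),
                         seed = 1L, dir = NULL) {
  preset <- match.arg(preset)
  base <- list(
    tubeInnerDiameterUm = 480, volumeShapeVoxels = c(48L, 96L, 96L),
    voxelPitchUm = 5, cellContrast = 1
  )
  mkSpec <- function(extra, s = seed) {
    do.call(phantomSpec, c(base, extra, list(rngSeed = s)))
  }
  roundAxes <- c(6, 10)
  elongAxes <- rbind(c(20, 32), c(7, 10), c(6, 9))
  flatAxes <- rbind(c(18, 28), c(14, 22), c(5, 8))
  specs <- switch(preset,
    gg_like = list(gg_like = mkSpec(list(
      seededDensityPerMl = 3e5, semiAxisRangeUm = roundAxes))),
    gelatin_gg_like = list(gelatin_gg_like = mkSpec(list(
      seededDensityPerMl = 5e5, semiAxisRangeUm = elongAxes))),
    geltrex_like = list(geltrex_like = mkSpec(list(
      seededDensityPerMl = 3e5, semiAxisRangeUm = flatAxes))),
    density_sweep = list(
      d300k = mkSpec(list(seededDensityPerMl = 3e5,
                          semiAxisRangeUm = roundAxes), seed),
      d500k = mkSpec(list(seededDensityPerMl = 5e5,
                          semiAxisRangeUm = roundAxes), seed + 1L),
      d1M = mkSpec(list(seededDensityPerMl = 1e6,
                        semiAxisRangeUm = roundAxes), seed + 2L)
    ),
    cor_offset = list(cor_offset = mkSpec(list(
      nCells = 20, semiAxisRangeUm = roundAxes))),
    dead_fraction_sweep = list(
      dead0 = mkSpec(list(seededDensityPerMl = 5e5,
                          semiAxisRangeUm = roundAxes, deadFraction = 0,
                          deadContrastFactor = 0.05), seed),
      dead20 = mkSpec(list(seededDensityPerMl = 5e5,
                           semiAxisRangeUm = roundAxes, deadFraction = 0.2,
                           deadContrastFactor = 0.05), seed + 1L),
      dead40 = mkSpec(list(seededDensityPerMl = 5e5,
                           semiAxisRangeUm = roundAxes, deadFraction = 0.4,
                           deadContrastFactor = 0.05), seed + 2L)
    )
  )
  out <- lapply(names(specs), function(nm) {
    ph <- generatePhantom(specs[[nm]])
    fx <- list(spec = specs[[nm]], volume = ph$volume, truth = ph$truth)
    if (preset == "cor_offset") {
      offsets <- c(-5, -2, 0, 2, 5)
      fx$stacks <- lapply(offsets, function(o) {
        forwardProject(ph$volume, defaultAngles(), corOffsetPx = o)
      })
      names(fx$stacks) <- sprintf("offset_%+d", offsets)
    }
    fx
  })
  names(out) <- names(specs)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      writePhantomTruth(out[[nm]]$truth, file.path(dir, paste0(nm, "_truth")))
      writeReconVolume(out[[nm]]$volume,
                       file.path(dir, paste0(nm, "_phantom.tif")))
      if (!is.null(out[[nm]]$stacks)) {
        for (sn in names(out[[nm]]$stacks)) {
          writeProjectionStack(out[[nm]]$stacks[[sn]],
                               file.path(dir, sprintf("%s_%s.tif", nm, sn)))
        }
      }
    }
  }
  out
}
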