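# End-to-end pipeline: contour -> fit -> asymmetry -> ONH offset -> cohort
# statistics, with a single configuration object embedded in every output
# for provenance.

#' Pipeline configuration
#'
#' All tunable thresholds of the analysis chain with their defaults.
#'
#' @param posteriorFraction axial fraction kept for the fit (default 2/3).
#' @param cannySigma Gaussian blur in voxels (default 1).
#' @param cannyLow,cannyHigh hysteresis thresholds as fractions of the
#'   maximum gradient magnitude (defaults 0.1, 0.3).
#' @param magnitudeFloor residual threshold in multiples of the fit RMSE
#'   (default 1).
#' @param poleCapDeg posterior-pole cap half-angle, degrees (default 35).
#' @param minRegionPoints smallest component kept as a region (default 5).
#' @param dominanceFraction dominant-protrusion share of the outward area
#'   (default 0.7).
#' @param pairAreaThreshold posterior-pole area the pair must exceed
#'   (default 0.5).
#' @param areaRule "pair" or "depression" (see [classifyAsymmetry()]).
#' @param adjacencyK neighbors in the surface graph (default 8).
#' @param adjacencyHops hops defining "immediately adjacent" (default 3).
#' @param fitReltol,fitMaxRestarts optimizer controls.
#' @param welch use Welch t-tests (default FALSE).
#' @param minPoints minimum posterior points for a fit (default 500).
#' @param maxPoints posterior points are evenly subsampled down to this
#'   count before fitting (default 2500; keeps dense contours tractable).
#' @param seed default seed for stochastic steps.
#' @return a list of class "pipelineConfig".
#' @export
pipelineConfig <- function(posteriorFraction = 2 / 3, cannySigma = 1.0,
                           cannyLow = 0.1, cannyHigh = 0.3,
                           magnitudeFloor = 1.0, poleCapDeg = 35,
                           minRegionPoints = 5L, dominanceFraction = 0.7,
                           pairAreaThreshold = 0.5, areaRule = "pair",
                           adjacencyK = 8L, adjacencyHops = 3L,
                           fitReltol = 1e-8, fitMaxRestarts = 5L,
                           welch = FALSE, minPoints = 500L,
                           maxPoints = 2500L, seed = 20240430L) {
  stopifnot(posteriorFraction > 0, posteriorFraction <= 1,
            cannyLow > 0, cannyHigh > cannyLow, cannyHigh < 1,
            magnitudeFloor >= 0, dominanceFraction > 0.5,
            dominanceFraction <= 1, pairAreaThreshold >= 0,
            pairAreaThreshold < 1, areaRule %in% c("pair", "depression"))
  cfg <- list(posteriorFraction = posteriorFraction, cannySigma = cannySigma,
              cannyLow = cannyLow, cannyHigh = cannyHigh,
              magnitudeFloor = magnitudeFloor,
              poleCapDeg = poleCapDeg,
              minRegionPoints = as.integer(minRegionPoints),
              dominanceFraction = dominanceFraction,
              pairAreaThreshold = pairAreaThreshold, areaRule = areaRule,
              adjacencyK = as.integer(adjacencyK),
              adjacencyHops = as.integer(adjacencyHops),
              fitReltol = fitReltol, fitMaxRestarts = as.integer(fitMaxRestarts),
              welch = welch, minPoints = as.integer(minPoints),
              maxPoints = as.integer(maxPoints), seed = as.integer(seed))
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Stable hash of a configuration
#'
#' @param config a [pipelineConfig()].
#' @return md5 hex string of the canonical JSON serialization.
#' @export
configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(unclass(config), digits = NA,
                                           auto_unbox = TRUE)), tmp)
  unname(tools::md5sum(tmp))
}

#' Analyze one eye from a voxel volume
#'
#' Contour extraction, frame standardization, posterior selection, ellipsoid
#' fit and asymmetry classification.
#'
#' @param volume a [VoxelVolume-class].
#' @param landmarks named list with lens/onh/fovea/bmo (mm, volume frame).
#' @param laterality "right" or "left".
#' @param config a [pipelineConfig()].
#' @return list with `cloud`, `fit`, `field`, `result`.
#' @export
analyzeEyeVolume <- function(volume, landmarks, laterality = "right",
                             config = pipelineConfig()) {
  vol <- rescaleIntensities(volume)
  pts <- extractContour(vol, lowThresh = config$cannyLow,
                        highThresh = config$cannyHigh,
                        sigma = config$cannySigma)
  cloud <- standardizeFrame(pts, landmarks, laterality)
  cloud <- selectPosterior(cloud, fraction = config$posteriorFraction,
                           minPoints = config$minPoints)
  if (nrow(cloud@points) > config$maxPoints) {
    keep <- round(seq(1L, nrow(cloud@points), length.out = config$maxPoints))
    cloud@points <- cloud@points[keep, , drop = FALSE]
  }
  fit <- fitEllipsoid(cloud@points, maxRestarts = config$fitMaxRestarts,
                      seed = config$seed, reltol = config$fitReltol)
  field <- residualField(cloud, fit, k = config$adjacencyK)
  res <- classifyAsymmetry(segmentRegions(field, config$magnitudeFloor,
                                          config$poleCapDeg,
                                          config$minRegionPoints),
                           field, dominanceFraction = config$dominanceFraction,
                           pairAreaThreshold = config$pairAreaThreshold,
                           adjacencyHops = config$adjacencyHops,
                           areaRule = config$areaRule)
  list(cloud = cloud, fit = fit, field = field, result = res)
}

#' Run the full pipeline over a synthetic or assembled cohort
#'
#' Per-eye volumes and scenes are analyzed, metrics merged into the manifest
#' (overriding any pre-filled metric columns for analyzed eyes), and the
#' statistics stage is run on the exclusion-filtered set.  Eyes whose
#' analysis fails are flagged in the `analysis_error` column, not dropped
#' silently.
#'
#' @param manifest per-eye cohort data.frame (subject_id, eye, flags, ...).
#' @param volumes optional named list `subject:eye` -> list(volume,
#'   landmarks, laterality).
#' @param scenes optional named list `subject:eye` -> [BMOScene-class].
#' @param config a [pipelineConfig()].
#' @return list of class "pipelineResult": `metrics` (per-eye data.frame),
#'   `stats` (see [cohortStats()]), `configHash`, `config`.
#' @export
runPipeline <- function(manifest, volumes = list(), scenes = list(),
                        config = pipelineConfig()) {
  if (!nrow(manifest)) stop("empty manifest")
  need <- c("subject_id", "eye")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  manifest$analysis_error <- NA_character_
  for (col in c("rmse", "group", "opp_angle", "protrusion_depth",
                "dominant_area_fraction", "offset_angle", "offset_index",
                "bmo_area", "ppa_angle"))
    if (!col %in% names(manifest)) manifest[[col]] <- NA_real_
  keys <- paste(manifest$subject_id, manifest$eye, sep = ":")
  for (k in names(volumes)) {
    row <- match(k, keys)
    if (is.na(row)) stop("volume key not in manifest: ", k)
    v <- volumes[[k]]
    res <- tryCatch(
      analyzeEyeVolume(v$volume, v$landmarks, v$laterality %||% "right",
                       config),
      error = function(e) e)
    if (inherits(res, "error")) {
      manifest$analysis_error[row] <- conditionMessage(res)
      next
    }
    manifest$rmse[row] <- res$fit@rmse
    manifest$group[row] <- if (res$result@isAsymmetric) 2L else 1L
    manifest$opp_angle[row] <- res$result@oppAngle
    manifest$protrusion_depth[row] <- res$result@protrusionDepth
    manifest$dominant_area_fraction[row] <- if (res$result@isAsymmetric)
      res$result@outwardRegion@areaFraction + res$result@inwardRegion@areaFraction
    else NA_real_
  }
  for (k in names(scenes)) {
    row <- match(k, keys)
    if (is.na(row)) stop("scene key not in manifest: ", k)
    off <- tryCatch(computeOffset(scenes[[k]]), error = function(e) e)
    if (inherits(off, "error")) {
      manifest$analysis_error[row] <- conditionMessage(off)
      next
    }
    manifest$offset_angle[row] <- off@offsetAngle
    manifest$offset_index[row] <- off@offsetIndex
    manifest$bmo_area[row] <- off@bmoArea
    manifest$ppa_angle[row] <- off@ppaAngle
  }
  stats <- cohortStats(manifest, welch = config$welch)
  out <- list(metrics = manifest, stats = stats,
              configHash = configHash(config), config = config)
  class(out) <- "pipelineResult"
  out
}

#' Write per-eye metrics to CSV
#'
#' @param result a "pipelineResult" (or a metrics data.frame).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeMetricsCSV <- function(result, path) {
  d <- if (inherits(result, "pipelineResult")) result$metrics else result
  cols <- intersect(c("subject_id", "eye", "group", "rmse", "opp_angle",
                      "protrusion_depth", "dominant_area_fraction",
                      "offset_angle", "offset_index", "bmo_area",
                      "ppa_angle", "analysis_error"), names(d))
  utils::write.csv(d[, cols], path, row.names = FALSE)
  invisible(path)
}
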