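#' Load a run configuration
#'
#' Reads a YAML run configuration and validates the basic contract: exactly
#' one of \code{inputs} (GSF/ASCII paths) or \code{scene} (a SceneSpec, see
#' \code{\link{genScene}}) must be present; an explicit threshold must be
#' positive.
#'
#' @param path YAML file path, or a list to validate directly.
#' @return the validated configuration list, with a \code{configHash}
#'   fingerprint attached.
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  hasInputs <- !is.null(cfg$inputs) && length(cfg$inputs) > 0
  hasScene <- !is.null(cfg$scene)
  if (hasInputs == hasScene)
    stopf("config must contain exactly one of 'inputs' or 'scene'")
  if (!is.null(cfg$threshold) && cfg$threshold <= 0)
    stopf("explicit threshold must be positive")
  cfg$configHash <- fnv1a32(jsonlite::toJSON(cfg, auto_unbox = TRUE))
  cfg
}

loadInputField <- function(path) {
  if (grepl("\\.gsf$", path, ignore.case = TRUE)) readGSF(path)
  else readASCIIGrid(path, pixelSize = 1)
}

#' Characterize surfaces: roughness, HDCF ripple metrics, anisotropy peaks
#'
#' For each input image: plane + median-line levelling, RMS roughness, the
#' HDCF along both axes with ripple metrics on the better axis, and 2D FFT
#' anisotropy peaks. Writes a JSON report and per-image HDCF CSVs when
#' \code{outDir} is given.
#'
#' @param fields list of \linkS4class{HeightField}s, or character paths.
#' @param outDir optional output directory.
#' @return list of per-image reports (sq, rippleMetrics, peaks).
#' @export
runCharacterize <- function(fields, outDir = NULL) {
  if (length(fields) == 0L) stopf("no input images")
  if (is.character(fields)) fields <- lapply(fields, loadInputField)
  if (!is.null(outDir)) dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  reports <- lapply(seq_along(fields), function(i) {
    f <- levelField(fields[[i]])
    r <- rmsRoughness(f)
    rm_ <- rippleMetrics(f)
    peaks <- detectAnisotropyPeaks(fftPower2D(f))
    if (!is.null(outDir))
      writeHdcfCSV(hdcf1D(f, rm_@axis),
                   file.path(outDir, sprintf("hdcf_%03d.csv", i)))
    list(image = i, sq = r@sq, meanHeight = r@meanHeight,
         ripple = list(detected = rm_@detected,
                       periodicity = rm_@periodicity,
                       amplitudePp = rm_@amplitudePp, axis = rm_@axis),
         nPeaks = nrow(peaks),
         peaks = if (nrow(peaks)) peaks else NULL)
  })
  if (!is.null(outDir))
    jsonlite::write_json(reports, file.path(outDir, "characterize.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  reports
}

#' Run the full analysis chain on one image
#'
#' level -> anisotropy-peak detection -> (if anisotropic) Fourier notch
#' subtraction -> height threshold -> grain labelling -> per-grain
#' morphometrics -> artefact rules. Flat images (no detected peaks) bypass
#' the filter. The threshold is either explicit
#' (\code{threshold}) or the reproducible auto rule
#' (\code{autoThresholdK}, see \code{\link{autoThreshold}}).
#'
#' @param field a \linkS4class{HeightField} (raw; levelling is applied).
#' @param threshold explicit height threshold in nm, or NULL.
#' @param autoThresholdK multiple of Sq for the auto threshold rule, or NULL.
#' @param radiusFactor notch radius factor (see
#'   \code{\link{notchesFromPeaks}}).
#' @param rules artefact exclusion rules (see
#'   \code{\link{excludeArtefacts}}).
#' @param connectivity,minAreaPx passed to \code{\link{markByThreshold}}.
#' @return list with the levelled/filtered field, the threshold used, the
#'   peak table, the \linkS4class{GrainLabelMap} and the morphometrics
#'   data.frame (with kept flags).
#' @export
analyzeField <- function(field, threshold = NULL, autoThresholdK = 5,
                         radiusFactor = 0.25, rules = list(),
                         connectivity = 8L, minAreaPx = 4L) {
  f <- levelField(field)
  peaks <- detectAnisotropyPeaks(fftPower2D(f))
  filtered <- if (nrow(peaks) > 0L)
    fourierSubtract(f, notchesFromPeaks(peaks, radiusFactor))
  else f
  filtered <- polishRowOffsets(filtered)
  thr <- threshold %||%
    (if (!is.null(autoThresholdK)) autoThreshold(filtered, autoThresholdK)
     else stopf("no threshold: give an explicit value or an auto rule"))
  lm <- markByThreshold(filtered, thr, connectivity, minAreaPx)
  morph <- excludeArtefacts(grainSummary(filtered, lm), rules)
  list(field = filtered, threshold = thr, peaks = peaks, labelMap = lm,
       morphometrics = morph)
}

#' Orchestrate a configured analysis run
#'
#' Runs \code{\link{analyzeField}} over every image of a run configuration
#' (file inputs or a generated scene), writes the per-grain CSV, the
#' condition summary CSV when condition metadata is present, and a JSON run
#' report carrying the package version and config fingerprint. Deterministic
#' given config + seed.
#'
#' @param config list from \code{\link{readRunConfig}} (or a path).
#' @param outDir output directory.
#' @return the run report list, invisibly.
#' @export
runAnalyze <- function(config, outDir) {
  cfg <- readRunConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  fields <- if (!is.null(cfg$scene)) list(genScene(cfg$scene)$field)
            else lapply(cfg$inputs, loadInputField)
  allMorph <- list()
  for (i in seq_along(fields)) {
    res <- analyzeField(fields[[i]], threshold = cfg$threshold,
                        autoThresholdK = cfg$autoThresholdK %||% 5,
                        radiusFactor = cfg$radiusFactor %||% 0.25,
                        rules = cfg$rules %||% list())
    m <- res$morphometrics
    if (nrow(m) > 0L) {
      m$image <- i
      m$thresholdNm <- res$threshold
      if (!is.null(cfg$surface)) m$surface <- cfg$surface
      if (!is.null(cfg$timeMin)) m$timeMin <- cfg$timeMin
      allMorph[[length(allMorph) + 1L]] <- m
    }
  }
  morph <- if (length(allMorph)) do.call(rbind, allMorph) else
    data.frame()
  grainCsv <- file.path(outDir, "grains.csv")
  utils::write.csv(morph, grainCsv, row.names = FALSE, quote = FALSE)
  summaryCsv <- NULL
  if (nrow(morph) > 0L && all(c("surface", "timeMin") %in% names(morph))) {
    summaryCsv <- file.path(outDir, "condition_summary.csv")
    utils::write.csv(summarizeConditions(morph[morph$keptFlag, , drop = FALSE]),
                     summaryCsv, row.names = FALSE, quote = FALSE)
  }
  report <- list(version = as.character(utils::packageVersion("afmorph")),
                 configHash = cfg$configHash, nImages = length(fields),
                 nGrains = nrow(morph), grainCsv = grainCsv,
                 summaryCsv = summaryCsv)
  jsonlite::write_json(report, file.path(outDir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}

#' Generate and write a synthetic scene
#'
#' Writes the composed field as GSF, the ground truth summary (spec, true
#' volumes, surface parameters) as a JSON sidecar, and the aggregate masks
#' as 16-bit TIFF when the tiff package is available.
#'
#' @param spec a SceneSpec list (e.g. from \code{\link{scenePreset}}).
#' @param outDir output directory.
#' @param basename file stem (default \code{"scene"}).
#' @return paths of the written files, invisibly.
#' @export
runSimulate <- function(spec, outDir, basename = "scene") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  scene <- genScene(spec)
  gsf <- file.path(outDir, paste0(basename, ".gsf"))
  writeGSF(scene$field, gsf)
  sidecar <- file.path(outDir, paste0(basename, ".json"))
  jsonlite::write_json(
    list(spec = scene$truth@spec,
         trueVolumes = scene$truth@trueVolumes,
         trueSurfaceParams = scene$truth@surfaceParams),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  maskPath <- NULL
  if (requireNamespace("tiff", quietly = TRUE)) {
    maskPath <- file.path(outDir, paste0(basename, "_masks.tif"))
    tiff::writeTIFF(matrix(as.integer(scene$truth@masks) / 65535,
                           nrow(scene$truth@masks)),
                    maskPath, bits.per.sample = 16L)
  }
  invisible(list(gsf = gsf, sidecar = sidecar, masks = maskPath))
}
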