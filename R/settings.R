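.settingsKeyMap <- c(
  threshold_method = "thresholdMethod",
  gauss_sigma = "gaussSigma",
  repeat_gauss_after_binarization = "repeatGaussAfterBinarization",
  blur_only_inside_roi = "blurOnlyInsideRoi",
  upscaling_fold = "upscalingFold",
  add_head_com_first_point = "addHeadComFirstPoint",
  unify_start_points = "unifyStartPoints",
  filter_points_by_fits = "filterPointsByFits",
  max_vector_length_points = "maxVectorLengthPoints",
  normal_radius_um = "normalRadiusUm",
  exclude_head_from_correction = "excludeHeadFromCorrection",
  smooth_normal_profile = "smoothNormalProfile",
  save_intermediates = "saveIntermediates",
  z_smoothing_arc_distance_um = "zSmoothingArcDistanceUm",
  smoothing_neighbor_count = "smoothingNeighborCount",
  reference_vector_arc_length_um = "referenceVectorArcLengthUm",
  curvature_reference_distance_um = "curvatureReferenceDistanceUm",
  fft_window_frames = "fftWindowFrames",
  fft_skip_initial_um = "fftSkipInitialUm",
  head_rotation_matrix_radius_px = "headRotationRadiusPx"
)

#' Create a settings profile
#'
#' All arguments default to the tethered-mouse reference profile; override
#' any subset. See [mouseSettings()] and [humanSettings()] for the two
#' published reference profiles.
#'
#' @param thresholdMethod,gaussSigma,repeatGaussAfterBinarization,blurOnlyInsideRoi,upscalingFold,addHeadComFirstPoint,unifyStartPoints,filterPointsByFits,maxVectorLengthPoints,normalRadiusUm,excludeHeadFromCorrection,smoothNormalProfile,saveIntermediates,zSmoothingArcDistanceUm,smoothingNeighborCount,referenceVectorArcLengthUm,curvatureReferenceDistanceUm,fftWindowFrames,fftSkipInitialUm,headRotationRadiusPx
#'   see [TraceSettings-class] for the meaning and units of each parameter.
#' @return a [TraceSettings-class] object.
#' @export
traceSettings <- function(thresholdMethod = "Li",
                          gaussSigma = 3.0,
                          repeatGaussAfterBinarization = FALSE,
                          blurOnlyInsideRoi = TRUE,
                          upscalingFold = 3,
                          addHeadComFirstPoint = FALSE,
                          unifyStartPoints = FALSE,
                          filterPointsByFits = FALSE,
                          maxVectorLengthPoints = 14,
                          normalRadiusUm = 5.0,
                          excludeHeadFromCorrection = TRUE,
                          smoothNormalProfile = TRUE,
                          saveIntermediates = FALSE,
                          zSmoothingArcDistanceUm = 9.6,
                          smoothingNeighborCount = 15,
                          referenceVectorArcLengthUm = 10.0,
                          curvatureReferenceDistanceUm = 10.0,
                          fftWindowFrames = 200,
                          fftSkipInitialUm = 0.0,
                          headRotationRadiusPx = 10) {
  new("TraceSettings",
      thresholdMethod = thresholdMethod,
      gaussSigma = gaussSigma,
      repeatGaussAfterBinarization = repeatGaussAfterBinarization,
      blurOnlyInsideRoi = blurOnlyInsideRoi,
      upscalingFold = upscalingFold,
      addHeadComFirstPoint = addHeadComFirstPoint,
      unifyStartPoints = unifyStartPoints,
      filterPointsByFits = filterPointsByFits,
      maxVectorLengthPoints = maxVectorLengthPoints,
      normalRadiusUm = normalRadiusUm,
      excludeHeadFromCorrection = excludeHeadFromCorrection,
      smoothNormalProfile = smoothNormalProfile,
      saveIntermediates = saveIntermediates,
      zSmoothingArcDistanceUm = zSmoothingArcDistanceUm,
      smoothingNeighborCount = smoothingNeighborCount,
      referenceVectorArcLengthUm = referenceVectorArcLengthUm,
      curvatureReferenceDistanceUm = curvatureReferenceDistanceUm,
      fftWindowFrames = fftWindowFrames,
      fftSkipInitialUm = fftSkipInitialUm,
      headRotationRadiusPx = headRotationRadiusPx)
}

#' Reference settings profiles
#'
#' `mouseSettings()` is the profile for tethered mouse sperm recorded at
#' 200 fps behind 16x magnification; `humanSettings()` the profile for
#' freely swimming human sperm at 500 fps behind 20x magnification.
#'
#' @param ... overrides passed on to [traceSettings()].
#' @return a [TraceSettings-class] object.
#' @export
mouseSettings <- function(...) {
  args <- list(...)
  do.call(traceSettings, args)
}

#' @rdname mouseSettings
#' @export
humanSettings <- function(...) {
  defaults <- list(
    thresholdMethod = "Triangle", gaussSigma = 2.0,
    repeatGaussAfterBinarization = TRUE, blurOnlyInsideRoi = FALSE,
    maxVectorLengthPoints = 20, normalRadiusUm = 6.0,
    excludeHeadFromCorrection = FALSE, referenceVectorArcLengthUm = 6.4,
    fftWindowFrames = 500)
  args <- utils::modifyList(defaults, list(...))
  do.call(traceSettings, args)
}

#' Read or write a settings profile
#'
#' Settings files are YAML or JSON (chosen by file extension) with
#' snake_case keys (`threshold_method`, `gauss_sigma`, ...); camelCase slot
#' names are also accepted on input. Unknown keys raise an error.
#'
#' @param path settings file (`.yaml`/`.yml` or `.json`).
#' @return for `readSettings`, a [TraceSettings-class] object.
#' @export
readSettings <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path),
    stop("unsupported settings format: .", ext))
  args <- list()
  for (key in names(vals)) {
    slot <- if (key %in% names(.settingsKeyMap)) .settingsKeyMap[[key]]
            else if (key %in% .settingsKeyMap) key
            else stop("unknown settings key: ", key)
    args[[slot]] <- vals[[key]]
  }
  do.call(traceSettings, args)
}

#' @param settings a [TraceSettings-class] object.
#' @rdname readSettings
#' @export
writeSettings <- function(settings, path) {
  vals <- lapply(.settingsKeyMap, function(sl) slot(settings, sl))
  names(vals) <- names(.settingsKeyMap)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(vals, path),
    json = jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    stop("unsupported settings format: .", ext))
  invisible(path)
}
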