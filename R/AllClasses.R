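#' @import methods
NULL

#' Calibrated grayscale image stack
#'
#' Container for a time-ordered grayscale movie with physical calibration.
#' Frames are stored as a numeric array indexed `[row, column, frame]`;
#' intensities are kept as real numbers on the original scale of the source
#' file (no rescaling), and are clipped at zero by every correction.
#'
#' Coordinate convention used throughout the package: 0-based, pixel centers
#' at integer positions, `x` = column, `y` = row.
#'
#' @slot frames numeric array `[row, column, frame]`, non-negative.
#' @slot fps frames per second (Hz), positive scalar.
#' @slot pixelSize micrometres per pixel, positive scalar.
#' @slot bitDepth bit depth of the source data (informational).
#'
#' @exportClass ImageStack
setClass("ImageStack",
  representation(
    frames = "array",
    fps = "numeric",
    pixelSize = "numeric",
    bitDepth = "numeric"
  )
)

setValidity("ImageStack", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L) msg <- c(msg, "frames must be a [row, col, frame] array")
  if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
    msg <- c(msg, "fps must be a positive scalar")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a positive scalar")
  if (any(!is.finite(object@frames)) || any(object@frames < 0))
    msg <- c(msg, "frame intensities must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' Analysis settings profile
#'
#' The parameter block governing every stage of the tracing pipeline.
#' Defaults follow the published profile for tethered mouse sperm; see
#' [mouseSettings()] and [humanSettings()] for the two reference profiles.
#'
#' @slot thresholdMethod one of `"Li"`, `"Triangle"`, `"Otsu"`.
#' @slot gaussSigma Gaussian blur sigma in pixels (> 0).
#' @slot repeatGaussAfterBinarization blur the binary mask again (same sigma)
#'   and re-binarize at 0.5 before skeletonization.
#' @slot blurOnlyInsideRoi restrict the blur to the user ROI.
#' @slot upscalingFold point-list upscaling factor (>= 1); `fold - 1`
#'   interpolated points are inserted between consecutive points.
#' @slot addHeadComFirstPoint prepend the intensity-weighted center of mass of
#'   the radius-8 head disk as the first point.
#' @slot unifyStartPoints replace each frame's first point by the across-frame
#'   mean start position (second pass over the movie).
#' @slot filterPointsByFits remove points whose Gaussian fit fails the
#'   acceptance criteria (second pass).
#' @slot maxVectorLengthPoints support length (in points) of the secant used
#'   for tangent vectors (>= 2).
#' @slot normalRadiusUm half-length of the normal profile line, micrometres.
#' @slot excludeHeadFromCorrection exempt head points (within 8 px of the
#'   first point) from center correction and fit-based deletion.
#' @slot smoothNormalProfile 3-tap moving-average smoothing of each normal
#'   profile before fitting.
#' @slot saveIntermediates write per-frame skeleton masks and rough traces.
#' @slot zSmoothingArcDistanceUm arc-distance cutoff for z-width smoothing.
#' @slot smoothingNeighborCount number of neighbours on each side used by the
#'   median-projection smoother.
#' @slot referenceVectorArcLengthUm arc length of the point defining the
#'   head-midpiece vector.
#' @slot curvatureReferenceDistanceUm tangent separation used for curvature
#'   and curvature angle.
#' @slot fftWindowFrames FFT window length in frames (>= 2).
#' @slot fftSkipInitialUm skip flagellar frequency analysis for arc lengths
#'   at or below this value.
#' @slot headRotationRadiusPx half-length (px) of the head cross-line used
#'   for the rolling signal.
#'
#' @exportClass TraceSettings
setClass("TraceSettings",
  representation(
    thresholdMethod = "character",
    gaussSigma = "numeric",
    repeatGaussAfterBinarization = "logical",
    blurOnlyInsideRoi = "logical",
    upscalingFold = "numeric",
    addHeadComFirstPoint = "logical",
    unifyStartPoints = "logical",
    filterPointsByFits = "logical",
    maxVectorLengthPoints = "numeric",
    normalRadiusUm = "numeric",
    excludeHeadFromCorrection = "logical",
    smoothNormalProfile = "logical",
    saveIntermediates = "logical",
    zSmoothingArcDistanceUm = "numeric",
    smoothingNeighborCount = "numeric",
    referenceVectorArcLengthUm = "numeric",
    curvatureReferenceDistanceUm = "numeric",
    fftWindowFrames = "numeric",
    fftSkipInitialUm = "numeric",
    headRotationRadiusPx = "numeric"
  )
)

setValidity("TraceSettings", function(object) {
  msg <- character()
  if (!object@thresholdMethod %in% c("Li", "Triangle", "Otsu"))
    msg <- c(msg, "thresholdMethod must be one of 'Li', 'Triangle', 'Otsu'")
  if (object@gaussSigma <= 0) msg <- c(msg, "gaussSigma must be > 0")
  if (object@upscalingFold < 1) msg <- c(msg, "upscalingFold must be >= 1")
  if (object@maxVectorLengthPoints < 2)
    msg <- c(msg, "maxVectorLengthPoints must be >= 2")
  if (object@normalRadiusUm <= 0) msg <- c(msg, "normalRadiusUm must be > 0")
  if (object@fftWindowFrames < 2) msg <- c(msg, "fftWindowFrames must be >= 2")
  dists <- c(object@zSmoothingArcDistanceUm, object@referenceVectorArcLengthUm,
             object@curvatureReferenceDistanceUm, object@fftSkipInitialUm)
  if (any(dists < 0)) msg <- c(msg, "distances must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Per-frame flagellar trace
#'
#' An ordered, head-first list of flagellar points for one movie frame,
#' with per-point geometry (position, tangent, normal, arc length), Gaussian
#' fit descriptors (height, center, width, r-squared, acceptance flag) and
#' derived values (smoothed z-width, intensity). Point coordinates are
#' 0-based pixel units; arc lengths are micrometres.
#'
#' @slot points data.frame with one row per trace point.
#' @slot frame 1-based frame index within the source movie.
#' @slot pixelSize micrometres per pixel.
#'
#' @exportClass FlagellarTrace
setClass("FlagellarTrace",
  representation(
    points = "data.frame",
    frame = "numeric",
    pixelSize = "numeric"
  )
)

setValidity("FlagellarTrace", function(object) {
  msg <- character()
  need <- c("x", "y")
  if (!all(need %in% names(object@points)))
    msg <- c(msg, "points must contain at least columns x, y")
  if ("arcLengthUm" %in% names(object@points)) {
    l <- object@points$arcLengthUm
    if (length(l) && (is.unsorted(l) || abs(l[1]) > 1e-9))
      msg <- c(msg, "arcLengthUm must start at 0 and be non-decreasing")
  }
  if (length(msg)) msg else TRUE
})

#' Arc-length-by-time kymograph
#'
#' Matrix of one flagellar parameter binned by arc length (rows) over
#' movie frames (columns), with a mask for bins not covered in a frame.
#'
#' @slot parameter name of the encoded parameter.
#' @slot values numeric matrix, bins x frames.
#' @slot mask logical matrix, `TRUE` where no data fell into the bin.
#' @slot binEdges arc-length bin edges (micrometres), uniform width.
#' @slot times frame times in seconds.
#'
#' @exportClass Kymograph
setClass("Kymograph",
  representation(
    parameter = "character",
    values = "matrix",
    mask = "matrix",
    binEdges = "numeric",
    times = "numeric"
  )
)

setValidity("Kymograph", function(object) {
  msg <- character()
  if (!identical(dim(object@values), dim(object@mask)))
    msg <- c(msg, "values and mask must have identical dimensions")
  if (nrow(object@values) != length(object@binEdges) - 1L)
    msg <- c(msg, "rows must match binEdges")
  if (ncol(object@values) != length(object@times))
    msg <- c(msg, "columns must match times")
  w <- diff(object@binEdges)
  if (length(w) > 1 && diff(range(w)) > 1e-9 * max(w))
    msg <- c(msg, "bins must have uniform width")
  if (length(msg)) msg else TRUE
})

#' One-sided amplitude spectrum
#'
#' Discrete-Fourier amplitude spectrum of a mean-subtracted signal; the DC
#' bin is excluded. Frequencies are `k * fps / W` for `k = 1..floor(W/2)`.
#'
#' @slot frequencies bin frequencies in Hz.
#' @slot amplitudes non-negative amplitudes (one-sided, `2/W` normalization).
#' @slot windowLength window length `W` in frames.
#' @slot windowStart 1-based index of the first frame of the window.
#' @slot fps sampling rate in Hz.
#'
#' @exportClass Spectrum
setClass("Spectrum",
  representation(
    frequencies = "numeric",
    amplitudes = "numeric",
    windowLength = "numeric",
    windowStart = "numeric",
    fps = "numeric"
  )
)

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@frequencies) != length(object@amplitudes))
    msg <- c(msg, "frequencies and amplitudes must have equal length")
  if (any(object@amplitudes < 0)) msg <- c(msg, "amplitudes must be >= 0")
  if (length(object@frequencies) &&
      max(object@frequencies) > object@fps / 2 + 1e-9)
    msg <- c(msg, "frequencies must not exceed the Nyquist bound fps/2")
  if (length(msg)) msg else TRUE
})

#' Complete single-cell analysis result
#'
#' Bundles the refined per-frame traces, the head parameter table, the
#' kymographs of the flagellar parameters and the settings used.
#'
#' @slot traces list of [FlagellarTrace-class] objects (possibly with `NULL`
#'   entries for failed frames).
#' @slot head data.frame of per-frame head parameters.
#' @slot kymographs named list of [Kymograph-class] objects.
#' @slot settings the [TraceSettings-class] profile used.
#' @slot fps frames per second of the source movie.
#' @slot pixelSize micrometres per pixel of the source movie.
#'
#' @exportClass BeatAnalysis
setClass("BeatAnalysis",
  representation(
    traces = "list",
    head = "data.frame",
    kymographs = "list",
    settings = "TraceSettings",
    fps = "numeric",
    pixelSize = "numeric"
  )
)
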