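#' Accessors for flagellaR classes
#'
#' Small accessor generics following Bioconductor conventions; use these
#' instead of direct slot access.
#'
#' @param object an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("fps", function(object) standardGeneric("fps"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("tracePoints", function(object) standardGeneric("tracePoints"))

#' @rdname accessors
#' @export
setGeneric("kymographValues", function(object) standardGeneric("kymographValues"))

#' @rdname accessors
#' @export
setGeneric("kymographMask", function(object) standardGeneric("kymographMask"))

#' @rdname accessors
#' @export
setGeneric("arcBinCenters", function(object) standardGeneric("arcBinCenters"))

#' @rdname accessors
#' @export
setGeneric("spectrumFrequencies",
           function(object) standardGeneric("spectrumFrequencies"))

#' @rdname accessors
#' @export
setGeneric("spectrumAmplitudes",
           function(object) standardGeneric("spectrumAmplitudes"))

#' @rdname accessors
setMethod("frames", "ImageStack", function(object) object@frames)

#' @rdname accessors
setMethod("fps", "ImageStack", function(object) object@fps)

#' @rdname accessors
setMethod("pixelSize", "ImageStack", function(object) object@pixelSize)

#' @rdname accessors
setMethod("nFrames", "ImageStack", function(object) dim(object@frames)[3L])

#' @rdname accessors
setMethod("tracePoints", "FlagellarTrace", function(object) object@points)

#' @rdname accessors
setMethod("pixelSize", "FlagellarTrace", function(object) object@pixelSize)

#' @rdname accessors
setMethod("kymographValues", "Kymograph", function(object) object@values)

#' @rdname accessors
setMethod("kymographMask", "Kymograph", function(object) object@mask)

#' @rdname accessors
setMethod("arcBinCenters", "Kymograph", function(object) {
  e <- object@binEdges
  (e[-1] + e[-length(e)]) / 2
})

#' @rdname accessors
setMethod("spectrumFrequencies", "Spectrum", function(object) object@frequencies)

#' @rdname accessors
setMethod("spectrumAmplitudes", "Spectrum", function(object) object@amplitudes)

#' @rdname accessors
setMethod("fps", "Spectrum", function(object) object@fps)

#' @rdname accessors
setMethod("fps", "BeatAnalysis", function(object) object@fps)

#' @rdname accessors
setMethod("pixelSize", "BeatAnalysis", function(object) object@pixelSize)

#' @rdname accessors
setMethod("nFrames", "BeatAnalysis", function(object) length(object@traces))

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "ImageStack: %d frames of %d x %d px, %.4g fps, %.4g um/px (%d-bit)\n",
    d[3], d[1], d[2], object@fps, object@pixelSize, object@bitDepth))
})

setMethod("show", "TraceSettings", function(object) {
  cat("TraceSettings profile\n")
  for (sl in slotNames(object))
    cat(sprintf("  %-30s %s\n", sl, format(slot(object, sl))))
})

setMethod("show", "FlagellarTrace", function(object) {
  n <- nrow(object@points)
  l <- if ("arcLengthUm" %in% names(object@points) && n)
    max(object@points$arcLengthUm) else NA_real_
  cat(sprintf("FlagellarTrace: frame %d, %d points, arc length %.2f um\n",
              object@frame, n, l))
})

setMethod("show", "Kymograph", function(object) {
  cat(sprintf(
    "Kymograph '%s': %d arc-length bins x %d frames (%.3g um bins)\n",
    object@parameter, nrow(object@values), ncol(object@values),
    diff(object@binEdges[1:2])))
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf(
    "Spectrum: %d bins, df = %.4g Hz, window %d frames starting at %d\n",
    length(object@frequencies), object@fps / object@windowLength,
    object@windowLength, object@windowStart))
})

setMethod("show", "BeatAnalysis", function(object) {
  ok <- sum(!vapply(object@traces, is.null, logical(1)))
  cat(sprintf(
    "BeatAnalysis: %d/%d frames traced, %d kymographs, %.4g fps\n",
    ok, length(object@traces), length(object@kymographs), object@fps))
})
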