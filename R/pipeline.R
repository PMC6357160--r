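#' Trace every frame of a movie
#'
#' Runs rough reconstruction, start-point policies, upscaling and the
#' two-pass sub-pixel refinement on every frame. Frames whose
#' reconstruction fails yield `NULL` entries (with the error recorded in
#' the `"failures"` attribute) rather than aborting the movie.
#'
#' @param stack a background-corrected [ImageStack-class].
#' @param settings a [TraceSettings-class].
#' @param roi optional logical ROI mask.
#' @param intermediatesDir when `saveIntermediates` is set, per-frame
#'   skeleton masks (TIFF) and rough traces (CSV) are written here.
#' @return a list of [FlagellarTrace-class] objects (or `NULL` per failed
#'   frame), with attribute `"failures"`.
#' @export
traceStack <- function(stack, settings, roi = NULL,
                       intermediatesDir = NULL) {
  nf <- nFrames(stack)
  px <- pixelSize(stack)
  rough <- vector("list", nf)
  failures <- character(0)
  for (i in seq_len(nf)) {
    fr <- stack@frames[, , i]
    res <- try({
      pts <- roughTraceFrame(fr, settings, roi)
      applyStartPointPolicy(pts, fr, settings)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      failures <- c(failures, sprintf("frame %d: %s", i,
                                      conditionMessage(attr(res, "condition"))))
      rough[[i]] <- NULL
    } else rough[[i]] <- res
  }
  if (settings@unifyStartPoints) {
    ok <- !vapply(rough, is.null, logical(1))
    if (any(ok)) {
      starts <- do.call(rbind, lapply(rough[ok], function(p)
        c(x = p$x[1], y = p$y[1])))
      mx <- mean(starts[, "x"]); my <- mean(starts[, "y"])
      for (i in which(ok)) {
        rough[[i]]$x[1] <- mx
        rough[[i]]$y[1] <- my
      }
    }
  }
  if (settings@saveIntermediates && !is.null(intermediatesDir)) {
    dir.create(intermediatesDir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(nf)) {
      if (is.null(rough[[i]])) next
      utils::write.csv(rough[[i]],
                       file.path(intermediatesDir,
                                 sprintf("rough_trace_%04d.csv", i)),
                       row.names = FALSE)
    }
  }
  traces <- vector("list", nf)
  for (i in seq_len(nf)) {
    if (is.null(rough[[i]])) next
    fr <- stack@frames[, , i]
    res <- try({
      up <- upscalePointList(rough[[i]], settings@upscalingFold)
      refineTrace(fr, up, settings, px, frameIndex = i)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      failures <- c(failures, sprintf("frame %d (refine): %s", i,
                                      conditionMessage(attr(res, "condition"))))
      traces[[i]] <- NULL
    } else traces[[i]] <- res
  }
  attr(traces, "failures") <- failures
  traces
}

#' Full single-cell analysis of an image stack
#'
#' Applies the selected background correction, traces and refines every
#' frame, derives the head parameters (position, orientation angle Theta
#' with per-movie unwrapping, rolling intensity) and the flagellar
#' parameters (head-frame coordinates, tangential angle, curvature,
#' curvature angle, z-width, intensity), and assembles kymographs.
#'
#' @param stack an [ImageStack-class].
#' @param settings a [TraceSettings-class].
#' @param roi optional logical ROI mask.
#' @param background background-correction scheme.
#' @param rollingBallRadiusPx ball radius for `"rolling-ball"`.
#' @param kymographParams point columns to turn into kymographs.
#' @param binWidthUm kymograph bin width (default: pixel size).
#' @return a [BeatAnalysis-class].
#' @export
analyzeStack <- function(stack, settings, roi = NULL,
                         background = c("none", "min-projection",
                                        "rolling-ball"),
                         rollingBallRadiusPx = 10,
                         kymographParams = c("xHeadUm", "yHeadUm",
                                             "tangentAngleDeg", "curvature",
                                             "curvatureAngleDeg", "zWidth",
                                             "intensity"),
                         binWidthUm = NULL) {
  background <- match.arg(background)
  corrected <- switch(background,
    "none" = stack,
    "min-projection" = minProjectionSubtract(stack),
    "rolling-ball" = rollingBallSubtract(stack, rollingBallRadiusPx))
  traces <- traceStack(corrected, settings, roi)
  nf <- length(traces)
  theta <- rep(NA_real_, nf)
  head <- data.frame(frame = seq_len(nf),
                     time = (seq_len(nf) - 1) / fps(stack),
                     x = NA_real_, y = NA_real_,
                     xUm = NA_real_, yUm = NA_real_,
                     thetaDeg = NA_real_, rollingMax = NA_real_)
  for (i in seq_len(nf)) {
    if (is.null(traces[[i]])) next
    traces[[i]] <- annotateKinematics(traces[[i]], settings,
                                      corrected@frames[, , i])
    pts <- traces[[i]]@points
    head$x[i] <- pts$x[1]; head$y[i] <- pts$y[1]
    head$xUm[i] <- pts$x[1] * pixelSize(stack)
    head$yUm[i] <- pts$y[1] * pixelSize(stack)
    theta[i] <- attr(pts, "thetaDeg")
    head$rollingMax[i] <- attr(pts, "rollingMax")
  }
  head$thetaDeg <- thetaSeries(theta)
  kymos <- list()
  if (any(!vapply(traces, is.null, logical(1)))) {
    for (par in kymographParams) {
      k <- try(buildKymograph(traces, par, binWidthUm, fps(stack)),
               silent = TRUE)
      if (!inherits(k, "try-error")) kymos[[par]] <- k
    }
  }
  new("BeatAnalysis", traces = traces, head = head, kymographs = kymos,
      settings = settings, fps = fps(stack), pixelSize = pixelSize(stack))
}

#' Frequency summary of a head parameter
#'
#' Amplitude spectrum (optionally sliding-window) of one column of the
#' head table, with primary/secondary peaks and center-of-mass.
#'
#' @param analysis a [BeatAnalysis-class].
#' @param parameter `"thetaDeg"` or `"rollingMax"` (or any head column).
#' @param windowFrames window length; defaults to the settings profile's
#'   FFT window, capped at the movie length.
#' @return a data.frame of spectral summaries (one row per window).
#' @export
headFrequency <- function(analysis, parameter = "thetaDeg",
                          windowFrames = NULL) {
  sig <- analysis@head[[parameter]]
  if (is.null(sig)) stop("unknown head parameter: ", parameter)
  if (is.null(windowFrames))
    windowFrames <- min(analysis@settings@fftWindowFrames, length(sig))
  spl <- slidingWindowSpectra(sig, windowFrames, analysis@fps)
  out <- do.call(rbind, lapply(spl, findPrimarySecondary))
  rownames(out) <- NULL
  out
}

#' Flagellar frequency map of an analysis
#'
#' Convenience wrapper: per-arc-length-bin spectral summaries of one
#' flagellar parameter kymograph, honouring the settings profile's
#' skip-initial arc length.
#'
#' @param analysis a [BeatAnalysis-class].
#' @param parameter kymograph name (default curvature angle).
#' @param windowFrames optional FFT window (default: full series).
#' @return see [flagellarFrequencyMap()].
#' @export
analysisFrequencyMap <- function(analysis, parameter = "curvatureAngleDeg",
                                 windowFrames = NULL) {
  k <- analysis@kymographs[[parameter]]
  if (is.null(k)) stop("no kymograph for parameter: ", parameter)
  flagellarFrequencyMap(k, analysis@fps,
                        analysis@settings@fftSkipInitialUm, windowFrames)
}
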