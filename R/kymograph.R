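#' Build an arc-length-by-time kymograph
#'
#' Assigns every trace point's parameter value to the uniform arc-length
#' bin containing it; multiple points per bin are averaged, bins without
#' data in a frame are masked. The default bin width is one pixel in
#' micrometres, the native sampling resolution.
#'
#' @param traces list of [FlagellarTrace-class] objects (entries may be
#'   `NULL` for failed frames).
#' @param parameter name of the point column to encode.
#' @param binWidthUm bin width in micrometres; defaults to the pixel size.
#' @param fps frames per second (for the time axis).
#' @return a [Kymograph-class].
#' @export
buildKymograph <- function(traces, parameter, binWidthUm = NULL, fps = 1) {
  ok <- !vapply(traces, is.null, logical(1))
  if (!any(ok)) stop("no valid frames")
  px <- traces[[which(ok)[1]]]@pixelSize
  if (is.null(binWidthUm)) binWidthUm <- px
  stopifnot(binWidthUm > 0)
  maxArc <- max(vapply(traces[ok], function(tr)
    max(tr@points$arcLengthUm), numeric(1)))
  edges <- seq(0, maxArc + binWidthUm, by = binWidthUm)
  nb <- length(edges) - 1L
  nf <- length(traces)
  vals <- matrix(NA_real_, nb, nf)
  for (j in seq_len(nf)) {
    if (!ok[j]) next
    pts <- traces[[j]]@points
    if (!parameter %in% names(pts)) stop("unknown parameter: ", parameter)
    v <- pts[[parameter]]
    bin <- pmin(pmax(floor(pts$arcLengthUm / binWidthUm) + 1L, 1L), nb)
    keep <- is.finite(v)
    if (!any(keep)) next
    agg <- tapply(v[keep], bin[keep], mean)
    vals[as.integer(names(agg)), j] <- agg
  }
  new("Kymograph", parameter = parameter, values = vals,
      mask = is.na(vals), binEdges = edges,
      times = (seq_len(nf) - 1) / fps)
}

#' Kymograph as a data.frame
#'
#' @param kymo a [Kymograph-class].
#' @return a data.frame with the arc-length bin centers in the first column
#'   and one column per frame.
#' @export
kymographAsDataFrame <- function(kymo) {
  df <- data.frame(arcLengthUm = arcBinCenters(kymo))
  vals <- kymo@values
  colnames(vals) <- sprintf("frame%04d", seq_len(ncol(vals)))
  cbind(df, as.data.frame(vals))
}

#' Write a kymograph to CSV at full precision
#'
#' Numbers are written with 17 significant digits so a re-import
#' reconstructs the matrix bit-identically.
#'
#' @param kymo a [Kymograph-class].
#' @param path destination CSV.
#' @export
writeKymographCsv <- function(kymo, path) {
  df <- kymographAsDataFrame(kymo)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v)
    ifelse(is.na(v), "", sprintf("%.17g", v)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a kymograph CSV written by [exportResults()]
#'
#' @param path CSV file.
#' @param parameter parameter name to store.
#' @param fps frames per second of the source movie.
#' @return a [Kymograph-class].
#' @export
readKymographCsv <- function(path, parameter = "value", fps = 1) {
  df <- utils::read.csv(path, check.names = FALSE)
  centers <- as.numeric(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  dimnames(vals) <- NULL
  storage.mode(vals) <- "double"
  w <- if (length(centers) > 1) centers[2] - centers[1] else 1
  edges <- c(centers - w / 2, centers[length(centers)] + w / 2)
  new("Kymograph", parameter = parameter, values = vals,
      mask = is.na(vals), binEdges = edges,
      times = (seq_len(ncol(vals)) - 1) / fps)
}

# Fixed color scales per parameter so exported heatmaps are comparable
# across runs; NULL means scale to the data range.
.kymographScales <- list(
  curvatureAngleDeg = c(-90, 90),
  curvature = c(-0.5, 0.5),
  tangentAngleDeg = c(-360, 360),
  yHeadUm = c(-25, 25),
  xHeadUm = c(0, 60)
)

.writeHeatmap <- function(kymo, path) {
  zlim <- .kymographScales[[kymo@parameter]]
  v <- kymo@values
  if (is.null(zlim)) zlim <- range(v, na.rm = TRUE)
  if (!all(is.finite(zlim)) || diff(zlim) == 0) zlim <- c(0, 1)
  v[v < zlim[1]] <- zlim[1]; v[v > zlim[2]] <- zlim[2]
  grDevices::png(path, width = 800, height = 500)
  on.exit(grDevices::dev.off())
  graphics::image(x = kymo@times, y = arcBinCenters(kymo), z = t(v),
                  zlim = zlim, col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "time (s)", ylab = "arc length (um)",
                  main = kymo@parameter, useRaster = TRUE)
  invisible(path)
}

#' Export a complete analysis to a results folder
#'
#' Writes, into a newly created per-cell folder: the per-frame trace CSV,
#' the head parameter CSV, one kymograph CSV and PNG heatmap per flagellar
#' parameter, frequency CSVs (head parameters and the curvature-angle
#' frequency map), a JSON settings snapshot and a log file.
#'
#' @param analysis a [BeatAnalysis-class].
#' @param dir destination folder (created; must not exist or be empty).
#' @return invisibly, the vector of files written.
#' @export
exportResults <- function(analysis, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create destination: ", dir)
  written <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
    p
  }
  traceDf <- do.call(rbind, lapply(analysis@traces, function(tr) {
    if (is.null(tr)) return(NULL)
    pts <- tr@points
    cols <- intersect(c("x", "y", "arcLengthUm", "fitA", "fitC", "fitD",
                        "fitR2", "accepted", "zWidth", "intensity",
                        "xHeadUm", "yHeadUm", "tangentAngleDeg",
                        "curvature", "curvatureAngleDeg"), names(pts))
    cbind(frame = tr@frame, index = seq_len(nrow(pts)), pts[cols])
  }))
  wr(traceDf, "trace.csv")
  wr(analysis@head, "head.csv")
  for (nm in names(analysis@kymographs)) {
    k <- analysis@kymographs[[nm]]
    pCsv <- file.path(dir, paste0("kymograph_", nm, ".csv"))
    writeKymographCsv(k, pCsv)
    written <- c(written, pCsv)
    p <- file.path(dir, paste0("kymograph_", nm, ".png"))
    .writeHeatmap(k, p)
    written <- c(written, p)
  }
  # head-parameter frequency summaries
  headFreq <- do.call(rbind, lapply(c("thetaDeg", "rollingMax"),
    function(par) {
      sig <- analysis@head[[par]]
      sm <- try(findPrimarySecondary(
        amplitudeSpectrum(sig, analysis@fps)), silent = TRUE)
      if (inherits(sm, "try-error"))
        sm <- data.frame(primaryHz = NA, secondaryHz = NA, comHz = NA,
                         primaryAmp = NA, secondaryAmp = NA, windowStart = 1)
      cbind(parameter = par, sm)
    }))
  wr(headFreq, "frequency_head.csv")
  if ("curvatureAngleDeg" %in% names(analysis@kymographs)) {
    fm <- try(flagellarFrequencyMap(
      analysis@kymographs[["curvatureAngleDeg"]], analysis@fps,
      analysis@settings@fftSkipInitialUm), silent = TRUE)
    if (!inherits(fm, "try-error"))
      wr(fm, "frequency_curvatureAngle.csv")
  }
  pSet <- file.path(dir, "settings.json")
  writeSettings(analysis@settings, pSet)
  written <- c(written, pSet)
  pLog <- file.path(dir, "log.txt")
  writeLines(c(
    sprintf("flagellaR %s", as.character(utils::packageVersion("flagellaR"))),
    sprintf("exported: %s", format(Sys.time())),
    sprintf("frames: %d (traced: %d)", length(analysis@traces),
            sum(!vapply(analysis@traces, is.null, logical(1)))),
    sprintf("fps: %g, pixel size: %g um", analysis@fps,
            analysis@pixelSize)), pLog)
  written <- c(written, pLog)
  invisible(written)
}
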