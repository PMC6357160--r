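#' Construct an ImageStack from in-memory frames
#'
#' @param frames a numeric array `[row, col, frame]` or a list of equally
#'   sized matrices.
#' @param fps frames per second (Hz).
#' @param pixelSize micrometres per pixel.
#' @param bitDepth source bit depth (informational; intensities are processed
#'   as real numbers and never rescaled).
#' @return an [ImageStack-class].
#' @export
imageStack <- function(frames, fps, pixelSize, bitDepth = 16) {
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
      stop("all frames must share identical dimensions")
    frames <- array(unlist(frames), dim = c(d, length(frames)))
  }
  storage.mode(frames) <- "double"
  new("ImageStack", frames = frames, fps = fps, pixelSize = pixelSize,
      bitDepth = bitDepth)
}

#' Load a calibrated multi-page TIFF stack
#'
#' Reads a grayscale multi-page TIFF and attaches acquisition calibration.
#' Intensities are returned on the original integer scale of the file
#' (8- or 16-bit), cast to doubles; no rescaling is performed.
#'
#' @param path path to a readable multi-page grayscale TIFF.
#' @inheritParams imageStack
#' @return an [ImageStack-class].
#' @export
readImageStack <- function(path, fps, pixelSize) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2, logical(1))))
    stop("RGB input is not supported; supply a grayscale stack")
  if (length(pages) < 2)
    stop("at least 2 frames required for time-resolved analysis")
  bits <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- if (max(pages[[1]]) > 255) 16 else 8
  imageStack(lapply(pages, function(p) { storage.mode(p) <- "double"; p }),
             fps = fps, pixelSize = pixelSize, bitDepth = bits)
}

#' Write an ImageStack to a multi-page TIFF
#'
#' @param stack an [ImageStack-class].
#' @param path destination file.
#' @export
writeImageStack <- function(stack, path) {
  scale <- 2^stack@bitDepth - 1
  pages <- lapply(seq_len(nFrames(stack)), function(i) {
    m <- stack@frames[, , i] / scale
    m[m > 1] <- 1
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = stack@bitDepth)
  invisible(path)
}

#' Subtract the per-pixel time minimum from every frame
#'
#' Computes a minimum-intensity projection over time and subtracts it from
#' every frame, removing static background. Negative results are clipped to
#' zero (they cannot occur here, but the contract is enforced).
#'
#' @param stack an [ImageStack-class] with at least two frames.
#' @return the corrected [ImageStack-class].
#' @export
minProjectionSubtract <- function(stack) {
  if (nFrames(stack) < 2) stop("at least 2 frames required")
  f <- stack@frames
  mn <- f[, , 1]
  for (i in seq_len(dim(f)[3])[-1]) mn <- pmin(mn, f[, , i])
  for (i in seq_len(dim(f)[3])) f[, , i] <- pmax(f[, , i] - mn, 0)
  initialize(stack, frames = f)
}

# Ball structuring function offsets/heights for a radius (heights <= 0).
.ballElement <- function(radius) {
  r <- floor(radius)
  d <- expand.grid(dx = -r:r, dy = -r:r)
  keep <- d$dx^2 + d$dy^2 <= radius^2
  d <- d[keep, , drop = FALSE]
  d$g <- sqrt(radius^2 - d$dx^2 - d$dy^2) - radius
  d
}

# Grayscale opening of one frame with a ball structuring function; this is
# the rolling-ball background: the upper envelope of all ball positions that
# fit under the intensity surface.
.rollingBallBackground <- function(frame, elem) {
  nr <- nrow(frame); nc <- ncol(frame)
  ero <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(elem))) {
    dx <- elem$dx[k]; dy <- elem$dy[k]; g <- elem$g[k]
    tr <- max(1, 1 - dy):min(nr, nr - dy)
    tc <- max(1, 1 - dx):min(nc, nc - dx)
    ero[tr, tc] <- pmin(ero[tr, tc], frame[tr + dy, tc + dx] - g)
  }
  bg <- matrix(-Inf, nr, nc)
  for (k in seq_len(nrow(elem))) {
    dx <- elem$dx[k]; dy <- elem$dy[k]; g <- elem$g[k]
    tr <- max(1, 1 + dy):min(nr, nr + dy)
    tc <- max(1, 1 + dx):min(nc, nc + dx)
    bg[tr, tc] <- pmax(bg[tr, tc], ero[tr - dy, tc - dx] + g)
  }
  bg
}

#' Rolling-ball background subtraction
#'
#' Estimates a smooth per-frame background as the grayscale opening of the
#' intensity surface with a ball of the given radius (the classic
#' rolling-ball construction: the background under a pixel is the highest
#' point reached by a ball of that radius rolled beneath the whole surface),
#' and subtracts it. Structures narrower than the ball (the flagellum) are
#' preserved; broad gradients are removed. No pre-smoothing is applied and
#' bright-objects-on-dark-background polarity is assumed.
#'
#' @param stack an [ImageStack-class].
#' @param radiusPx ball radius in pixels (>= 1).
#' @return the corrected [ImageStack-class].
#' @export
rollingBallSubtract <- function(stack, radiusPx = 10) {
  if (radiusPx < 1) stop("radiusPx must be >= 1")
  d <- dim(stack@frames)
  if (radiusPx > min(d[1], d[2]))
    stop("radiusPx larger than the shorter image side")
  elem <- .ballElement(radiusPx)
  f <- stack@frames
  for (i in seq_len(d[3])) {
    bg <- .rollingBallBackground(f[, , i], elem)
    f[, , i] <- pmax(f[, , i] - bg, 0)
  }
  initialize(stack, frames = f)
}

#' Build a region-of-interest mask
#'
#' The ROI restricts where the pipeline searches for the flagellum and,
#' optionally, where the Gaussian blur is applied. Supply either a rectangle
#' `c(x, y, width, height)` in 0-based pixel coordinates, a polygon as a list
#' with components `x` and `y`, or the path of a mask TIFF (non-zero =
#' inside).
#'
#' @param dim image dimensions `c(rows, cols)` (ignored for mask files).
#' @param rectangle,polygon,maskFile exactly one ROI specification.
#' @return a logical matrix with at least one `TRUE` pixel.
#' @export
roiMask <- function(dim, rectangle = NULL, polygon = NULL, maskFile = NULL) {
  if (!is.null(maskFile)) {
    m <- tiff::readTIFF(maskFile, as.is = TRUE)
    if (length(base::dim(m)) > 2) m <- m[, , 1]
    mask <- m > 0
  } else if (!is.null(rectangle)) {
    stopifnot(length(rectangle) == 4)
    mask <- matrix(FALSE, dim[1], dim[2])
    xs <- max(0, round(rectangle[1])):min(dim[2] - 1,
                                          round(rectangle[1] + rectangle[3] - 1))
    ys <- max(0, round(rectangle[2])):min(dim[1] - 1,
                                          round(rectangle[2] + rectangle[4] - 1))
    mask[ys + 1, xs + 1] <- TRUE
  } else if (!is.null(polygon)) {
    g <- expand.grid(x = 0:(dim[2] - 1), y = 0:(dim[1] - 1))
    inside <- pracma::inpolygon(g$x, g$y, polygon$x, polygon$y,
                                boundary = TRUE)
    mask <- matrix(FALSE, dim[1], dim[2])
    mask[cbind(g$y + 1, g$x + 1)] <- inside
  } else {
    stop("supply one of rectangle, polygon or maskFile")
  }
  if (!any(mask)) stop("ROI mask has no pixels set")
  mask
}
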