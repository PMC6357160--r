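# Internal helpers. Coordinates are 0-based with pixel centers at integers;
# x indexes columns, y indexes rows.

# Bilinear interpolation of frame values at sub-pixel (x, y) positions.
.bilinear <- function(frame, x, y) {
  nr <- nrow(frame); nc <- ncol(frame)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x0 <- pmin(pmax(x0, 0), nc - 1); y0 <- pmin(pmax(y0, 0), nr - 1)
  x1 <- pmin(x0 + 1, nc - 1); y1 <- pmin(y0 + 1, nr - 1)
  v00 <- frame[cbind(y0 + 1, x0 + 1)]
  v01 <- frame[cbind(y0 + 1, x1 + 1)]
  v10 <- frame[cbind(y1 + 1, x0 + 1)]
  v11 <- frame[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

.insideFrame <- function(frame, x, y) {
  x >= 0 & x <= ncol(frame) - 1 & y >= 0 & y <= nrow(frame) - 1
}

# Lower median: for even counts the smaller of the two central values.
.lowerMedian <- function(v) {
  v <- sort(v)
  v[floor((length(v) + 1) / 2)]
}

# Angle of a pixel-space vector in degrees, screen-math convention:
# counterclockwise positive on screen, i.e. y (= row) measured downward
# contributes negatively. A point below the head is at a negative angle.
.angleOfDeg <- function(vx, vy) atan2(-vy, vx) * 180 / pi

.wrapDeg180 <- function(a) ((a + 180) %% 360) - 180

# Unwrap a degree series so consecutive differences stay within (-180, 180].
.unwrapDeg <- function(a) {
  if (length(a) < 2) return(a)
  ok <- is.finite(a)
  if (sum(ok) < 2) return(a)
  idx <- which(ok)
  v <- a[idx]
  d <- .wrapDeg180(diff(v))
  a[idx] <- cumsum(c(v[1], d))
  a
}

# Mean intensity of integer pixels within a disk (center 0-based, radius px).
.diskMean <- function(frame, cx, cy, r) {
  xs <- seq(max(0, floor(cx - r)), min(ncol(frame) - 1, ceiling(cx + r)))
  ys <- seq(max(0, floor(cy - r)), min(nrow(frame) - 1, ceiling(cy + r)))
  g <- expand.grid(x = xs, y = ys)
  keep <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2
  if (!any(keep)) return(NA_real_)
  mean(frame[cbind(g$y[keep] + 1, g$x[keep] + 1)])
}

# Intensity-weighted centroid of pixels within a disk.
.diskCom <- function(frame, cx, cy, r) {
  xs <- seq(max(0, floor(cx - r)), min(ncol(frame) - 1, ceiling(cx + r)))
  ys <- seq(max(0, floor(cy - r)), min(nrow(frame) - 1, ceiling(cy + r)))
  g <- expand.grid(x = xs, y = ys)
  keep <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2
  g <- g[keep, , drop = FALSE]
  w <- frame[cbind(g$y + 1, g$x + 1)]
  if (sum(w) <= 0) return(c(cx, cy))
  c(sum(g$x * w) / sum(w), sum(g$y * w) / sum(w))
}

# Evaluate an expression with a temporary RNG seed, restoring global state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Physical pixel size behind a magnifying objective
#'
#' Converts a camera chip pixel pitch and the total optical magnification to
#' the sample-plane sampling step, the step size at which normal profiles and
#' head cross-lines are sampled.
#'
#' @param cameraPixelUm camera pixel pitch in micrometres.
#' @param magnification total optical magnification.
#' @return sample-plane pixel size in micrometres per pixel.
#' @examples
#' cameraPixelSizeUm(11, 20) # 0.55 um/px
#' @export
cameraPixelSizeUm <- function(cameraPixelUm, magnification) {
  stopifnot(cameraPixelUm > 0, magnification > 0)
  cameraPixelUm / magnification
}
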