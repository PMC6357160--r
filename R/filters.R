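# Cache of 1-D blur operator matrices keyed by (n, sigma).
.blurCache <- new.env(parent = emptyenv())

# Dense n x n operator applying a reflected-boundary Gaussian along one axis.
.blurMatrix <- function(n, sigma) {
  key <- paste(n, signif(sigma, 12), sep = "_")
  if (!is.null(.blurCache[[key]])) return(.blurCache[[key]])
  r <- max(1L, ceiling(3.5 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  B <- matrix(0, n, n)
  idx <- seq_len(n)
  for (o in -r:r) {
    j <- idx + o
    # mirror reflection without repeating the edge pixel
    j <- ifelse(j < 1, 2 - j, j)
    j <- ifelse(j > n, 2 * n - j, j)
    j <- pmin(pmax(j, 1), n)
    B[cbind(idx, j)] <- B[cbind(idx, j)] + k[o + r + 1]
  }
  .blurCache[[key]] <- B
  B
}

#' Isotropic Gaussian blur of one frame
#'
#' Separable Gaussian smoothing with mirror-reflected borders. When `roi` is
#' given together with `onlyInsideRoi = TRUE`, only pixels inside the ROI are
#' replaced by their blurred values; all other pixels are returned untouched
#' (used to blur a structured head while preserving the fine flagellum).
#'
#' @param frame numeric matrix.
#' @param sigma Gaussian sigma in pixels (> 0).
#' @param roi optional logical ROI mask of the same dimensions.
#' @param onlyInsideRoi restrict the blur to the ROI.
#' @return the blurred matrix.
#' @export
gaussBlur <- function(frame, sigma, roi = NULL, onlyInsideRoi = FALSE) {
  stopifnot(sigma > 0)
  out <- .blurMatrix(nrow(frame), sigma) %*% frame %*%
    t(.blurMatrix(ncol(frame), sigma))
  if (!is.null(roi) && onlyInsideRoi) {
    res <- frame
    res[roi] <- out[roi]
    return(res)
  }
  out
}

# 256-bin histogram spanning the frame's min..max (ImageJ 8-bit semantics).
.hist256 <- function(v) {
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("no threshold exists for a constant frame")
  bin <- pmin(floor((v - lo) / (hi - lo) * 256), 255)
  counts <- tabulate(bin + 1L, nbins = 256L)
  centers <- lo + (0:255 + 0.5) * (hi - lo) / 256
  list(counts = counts, centers = centers, lo = lo, hi = hi)
}

# Otsu: exhaustive maximization of the between-class variance over the
# 256 candidate split positions (split after bin t).
.otsuBin <- function(counts) {
  n <- sum(counts)
  idx <- 0:255
  w0 <- cumsum(counts)
  s0 <- cumsum(counts * idx)
  total <- s0[256]
  best <- -Inf; bestT <- 0L
  for (t in 1:255) {
    n0 <- w0[t]; n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- s0[t] / n0
    mu1 <- (total - s0[t]) / n1
    bc <- n0 * n1 * (mu0 - mu1)^2
    if (bc > best) { best <- bc; bestT <- t - 1L }
  }
  bestT
}

# Li: exhaustive minimization of the minimum cross-entropy criterion.
# Gray levels are the 1-based bin ordinals so the logarithms are defined.
.liBin <- function(counts) {
  g <- 1:256
  cg <- cumsum(counts * g)
  cn <- cumsum(counts)
  total_g <- cg[256]; total_n <- cn[256]
  best <- Inf; bestT <- 0L
  for (t in 1:255) {
    n0 <- cn[t]; n1 <- total_n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- cg[t] / n0
    mu1 <- (total_g - cg[t]) / n1
    eta <- -cg[t] * log(mu0) - (total_g - cg[t]) * log(mu1)
    if (eta < best) { best <- eta; bestT <- t - 1L }
  }
  bestT
}

# Triangle: line from the histogram peak to the far end of the longer tail;
# the threshold bin maximizes the perpendicular distance to that line.
.triangleBin <- function(counts) {
  peak <- which.max(counts) - 1L
  nz <- which(counts > 0) - 1L
  lo <- min(nz); hi <- max(nz)
  flip <- (peak - lo) > (hi - peak)   # put the longer tail on the right
  h <- counts
  if (flip) { h <- rev(h); peak <- 255L - peak; hi <- 255L - lo }
  # line from (peak, h[peak]) to (hi, 0)
  x1 <- peak; y1 <- h[peak + 1L]; x2 <- hi; y2 <- 0
  if (x2 <= x1) return(if (flip) 255L - peak else peak)
  xs <- (x1 + 1L):x2
  num <- abs((y2 - y1) * xs - (x2 - x1) * h[xs + 1L] + x2 * y1 - y2 * x1)
  t <- xs[which.max(num)]
  if (flip) 255L - t else t
}

#' Automatic histogram threshold
#'
#' Computes a global threshold on a 256-bin histogram spanning the frame's
#' min-max range, using one of the published algorithms `"Li"` (minimum
#' cross entropy), `"Triangle"` (geometric construction) or `"Otsu"`
#' (between-class variance). Pixels strictly above the threshold value are
#' foreground. If `roi` is given, foreground outside the ROI is cleared.
#'
#' @param frame numeric matrix; must not be constant.
#' @param method `"Li"`, `"Triangle"` or `"Otsu"`.
#' @param roi optional logical ROI mask.
#' @return a logical foreground mask with attribute `"threshold"` (the
#'   threshold intensity, the center of the selected histogram bin).
#' @export
autoThreshold <- function(frame, method = c("Li", "Triangle", "Otsu"),
                          roi = NULL) {
  method <- match.arg(method)
  h <- .hist256(as.vector(frame))
  bin <- switch(method,
                Li = .liBin(h$counts),
                Triangle = .triangleBin(h$counts),
                Otsu = .otsuBin(h$counts))
  thr <- h$centers[bin + 1L]
  mask <- frame > thr
  if (!is.null(roi)) mask <- mask & roi
  attr(mask, "threshold") <- thr
  mask
}
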