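# Exact open-path ordering by Held-Karp dynamic programming (small n).
.sortExact <- function(pts) {
  n <- nrow(pts)
  D <- as.matrix(stats::dist(pts))
  full <- bitwShiftL(1L, n) - 1L
  nS <- full + 1L
  dp <- matrix(Inf, nS, n)
  par <- matrix(0L, nS, n)
  for (j in 1:n) dp[bitwShiftL(1L, j - 1L) + 1L, j] <- 0
  for (S in 1:full) {
    row <- dp[S + 1L, ]
    if (all(!is.finite(row))) next
    for (j in 1:n) {
      if (!is.finite(row[j])) next
      if (bitwAnd(S, bitwShiftL(1L, j - 1L)) == 0L) next
      base <- row[j]
      for (m in 1:n) {
        bit <- bitwShiftL(1L, m - 1L)
        if (bitwAnd(S, bit) != 0L) next
        S2 <- S + bit
        cand <- base + D[j, m]
        if (cand < dp[S2 + 1L, m]) {
          dp[S2 + 1L, m] <- cand
          par[S2 + 1L, m] <- j
        }
      }
    }
  }
  j <- which.min(dp[full + 1L, ])
  ord <- integer(n)
  S <- full
  for (k in n:1) {
    ord[k] <- j
    pj <- par[S + 1L, j]
    S <- S - bitwShiftL(1L, j - 1L)
    j <- pj
    if (j == 0L) break
  }
  ord
}

# Nearest-neighbour chain from a given start index.
.nnChain <- function(D, start) {
  n <- nrow(D)
  ord <- integer(n)
  used <- rep(FALSE, n)
  ord[1] <- start; used[start] <- TRUE
  for (k in 2:n) {
    d <- D[ord[k - 1], ]
    d[used] <- Inf
    ord[k] <- which.min(d)
    used[ord[k]] <- TRUE
  }
  ord
}

.pathLength <- function(D, ord) {
  sum(D[cbind(ord[-length(ord)], ord[-1])])
}

# Vectorized 2-opt: reverse segments while any reversal shortens the path.
.twoOpt <- function(D, ord, maxIter = 200L) {
  n <- length(ord)
  if (n < 4) return(ord)
  for (iter in seq_len(maxIter)) {
    seg <- D[cbind(ord[-n], ord[-1])]        # d(i, i+1), length n-1
    # gain of reversing ord[(i+1)..j] for 1 <= i < j <= n-1:
    # seg[i] + seg[j] - d(ord[i], ord[j]) - d(ord[i+1], ord[j+1])
    A <- outer(seg, seg, "+")
    A <- A - D[ord[-n], ord[-n]][, , drop = FALSE]
    A <- A - D[ord[-1], ord[-1]]
    A[!upper.tri(A)] <- -Inf
    mx <- max(A)
    if (mx <= 1e-12) break
    ij <- which(A == mx, arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    ord[(i + 1):j] <- rev(ord[(i + 1):j])
  }
  ord
}

#' Order a point list along the flagellum
#'
#' Finds an ordering of the points that minimizes the total consecutive
#' Euclidean distance. For lists of up to 10 points the exact minimum is
#' computed by dynamic programming over subsets; for larger lists (the thin,
#' nearly one-dimensional point sets that skeletons produce)
#' nearest-neighbour chains are grown from each of the two mutually farthest
#' points and the shorter chain is polished by 2-opt segment reversals.
#'
#' @param pts data.frame with columns `x`, `y` (and optionally others, which
#'   are carried along).
#' @return the reordered data.frame.
#' @export
sortPointList <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(pts)
  xy <- as.matrix(pts[, c("x", "y")])
  if (n <= 10) {
    ord <- .sortExact(xy)
  } else {
    D <- as.matrix(stats::dist(xy))
    far <- which(D == max(D), arr.ind = TRUE)[1, ]
    o1 <- .nnChain(D, far[1]); o2 <- .nnChain(D, far[2])
    ord <- if (.pathLength(D, o1) <= .pathLength(D, o2)) o1 else o2
    ord <- .twoOpt(D, ord)
  }
  pts[ord, , drop = FALSE]
}

#' Orient a trace head-first
#'
#' Compares the mean image intensity in circular disks (default radius 8 px)
#' around the two ends of a sorted point list and inverts the list if the
#' first end is dimmer: in dark-field images the head scatters far more light
#' than the flagellar tip. Equal means keep the current order.
#'
#' @param pts sorted point data.frame (columns `x`, `y`).
#' @param frame the intensity frame (matrix).
#' @param radiusPx disk radius in pixels.
#' @return the (possibly inverted) data.frame.
#' @export
orientHeadFirst <- function(pts, frame, radiusPx = 8) {
  n <- nrow(pts)
  if (n < 2) return(pts)
  m1 <- .diskMean(frame, pts$x[1], pts$y[1], radiusPx)
  m2 <- .diskMean(frame, pts$x[n], pts$y[n], radiusPx)
  if (isTRUE(m1 < m2)) pts <- pts[n:1, , drop = FALSE]
  rownames(pts) <- NULL
  pts
}

#' Apply the start-point policies
#'
#' If `addHeadComFirstPoint` is set, the intensity-weighted center of mass of
#' the radius-8 disk around the first point is prepended. If
#' `unifyStartPoints` is set and the start positions of all frames are
#' supplied (second pass over the movie), the first point is replaced by
#' their mean. When both are requested, the center of mass is prepended
#' first and unification then acts on the prepended point.
#'
#' @param pts head-first point data.frame.
#' @param frame the intensity frame.
#' @param settings a [TraceSettings-class].
#' @param allFrameStarts optional matrix/data.frame of all frames' first
#'   points (columns `x`, `y`), required for unification.
#' @param radiusPx head disk radius in pixels.
#' @return the updated data.frame.
#' @export
applyStartPointPolicy <- function(pts, frame, settings,
                                  allFrameStarts = NULL, radiusPx = 8) {
  if (settings@addHeadComFirstPoint) {
    com <- .diskCom(frame, pts$x[1], pts$y[1], radiusPx)
    first <- pts[1, , drop = FALSE]
    first$x <- com[1]; first$y <- com[2]
    if ("provenance" %in% names(first)) first$provenance <- "head-com"
    pts <- rbind(first, pts)
  }
  if (settings@unifyStartPoints && !is.null(allFrameStarts)) {
    pts$x[1] <- mean(allFrameStarts[, "x"])
    pts$y[1] <- mean(allFrameStarts[, "y"])
  }
  rownames(pts) <- NULL
  pts
}

#' Upscale a point list by linear interpolation
#'
#' Inserts `fold - 1` equidistant, linearly interpolated points between each
#' consecutive pair, so the output has `fold * n - (fold - 1)` points.
#' Endpoints and total polyline length are preserved exactly.
#'
#' @param pts point data.frame (columns `x`, `y`).
#' @param fold upscaling factor (>= 1).
#' @return the upscaled data.frame (`provenance` marks inserted points).
#' @export
upscalePointList <- function(pts, fold) {
  stopifnot(fold >= 1, nrow(pts) >= 2)
  fold <- as.integer(round(fold))
  if (fold == 1) return(pts)
  n <- nrow(pts)
  # fractional index positions 1, 1 + 1/fold, ..., n
  tt <- seq(1, n, by = 1 / fold)
  i0 <- pmin(floor(tt), n - 1)
  fr <- tt - i0
  out <- data.frame(
    x = pts$x[i0] * (1 - fr) + pts$x[i0 + 1] * fr,
    y = pts$y[i0] * (1 - fr) + pts$y[i0 + 1] * fr)
  if ("provenance" %in% names(pts)) {
    out$provenance <- ifelse(abs(fr) < 1e-12, pts$provenance[i0],
                             "interpolated")
    out$provenance[length(tt)] <- pts$provenance[n]
  }
  out
}

#' Rough flagellar trace of one frame
#'
#' Runs the reconstruction chain on a background-corrected frame:
#' Gaussian blur, automatic threshold, optional second blur of the binary
#' mask (re-binarized at 0.5), thinning to a skeleton, extraction of the
#' longest path, ordering, and head-first orientation.
#'
#' @param frame numeric matrix (background-corrected).
#' @param settings a [TraceSettings-class].
#' @param roi optional logical ROI mask.
#' @return an ordered head-first point data.frame.
#' @export
roughTraceFrame <- function(frame, settings, roi = NULL) {
  blurred <- gaussBlur(frame, settings@gaussSigma, roi,
                       settings@blurOnlyInsideRoi)
  mask <- autoThreshold(blurred, settings@thresholdMethod, roi)
  if (settings@repeatGaussAfterBinarization) {
    soft <- gaussBlur(mask * 1.0, settings@gaussSigma)
    mask <- soft >= 0.5
  }
  skel <- skeletonizeFrame(mask)
  pts <- extractSkeletonPath(skel)
  if (nrow(pts) < 3) stop("usable trace requires at least 3 points")
  pts <- sortPointList(pts)
  orientHeadFirst(pts, frame)
}
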