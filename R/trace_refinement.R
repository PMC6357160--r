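#' Tangent and normal vectors along a point list
#'
#' The tangent at point `i` is the unit vector between the points `k`
#' positions before and after `i`, with `k = floor(maxVectorLength / 2)`;
#' near the ends the nearest available points are used instead. The normal
#' is the tangent rotated by +90 degrees, `n = (-t_y, t_x)`; with this
#' construction the cross product of tangent and normal is always positive,
#' so the orientation test never flips the normal.
#'
#' @param pts point data.frame with columns `x`, `y`.
#' @param maxVectorLength secant support length in points (>= 2).
#' @return `pts` with columns `tx`, `ty`, `nx`, `ny` added.
#' @export
computeTangentsNormals <- function(pts, maxVectorLength) {
  stopifnot(maxVectorLength >= 2)
  n <- nrow(pts)
  if (n < 2) stop("at least 2 points required")
  k <- floor(maxVectorLength / 2)
  lo <- pmax(1, seq_len(n) - k)
  hi <- pmin(n, seq_len(n) + k)
  vx <- pts$x[hi] - pts$x[lo]
  vy <- pts$y[hi] - pts$y[lo]
  bad <- which(vx == 0 & vy == 0)
  for (i in bad) {
    # coincident support: widen to the nearest distinct neighbours
    l <- lo[i]; h <- hi[i]
    while ((pts$x[h] == pts$x[l] && pts$y[h] == pts$y[l]) &&
           (l > 1 || h < n)) {
      if (l > 1) l <- l - 1
      if (h < n) h <- h + 1
    }
    vx[i] <- pts$x[h] - pts$x[l]
    vy[i] <- pts$y[h] - pts$y[l]
  }
  len <- sqrt(vx^2 + vy^2)
  len[len == 0] <- 1
  pts$tx <- vx / len
  pts$ty <- vy / len
  pts$nx <- -pts$ty
  pts$ny <- pts$tx
  pts
}

#' Sample an intensity profile along a normal line
#'
#' Samples the frame at offsets of one pixel length along the normal through
#' a point, from `-R` to `+R` pixels with `R = round(normalRadiusUm /
#' pixelSize)`. Each sample is bilinearly interpolated from the four
#' surrounding pixels. Samples falling outside the frame are dropped
#' (truncated profile, flagged). Optionally the profile is smoothed with a
#' 3-tap moving average.
#'
#' @param frame numeric matrix.
#' @param px,py point position (0-based pixels).
#' @param nx,ny unit normal.
#' @param normalRadiusUm half-length of the line in micrometres.
#' @param pixelSize micrometres per pixel.
#' @param smooth apply the 3-tap moving average.
#' @return a data.frame with columns `offset` (px) and `value`, with
#'   attribute `"truncated"`.
#' @export
sampleNormalProfile <- function(frame, px, py, nx, ny, normalRadiusUm,
                                pixelSize, smooth = FALSE) {
  R <- max(1L, as.integer(round(normalRadiusUm / pixelSize)))
  off <- (-R):R
  xs <- px + off * nx
  ys <- py + off * ny
  ok <- .insideFrame(frame, xs, ys)
  truncated <- !all(ok)
  off <- off[ok]; xs <- xs[ok]; ys <- ys[ok]
  val <- if (length(off)) .bilinear(frame, xs, ys) else numeric(0)
  if (smooth && length(val) >= 3) {
    sm <- val
    m <- length(val)
    sm[2:(m - 1)] <- (val[1:(m - 2)] + val[2:(m - 1)] + val[3:m]) / 3
    sm[1] <- mean(val[1:2]); sm[m] <- mean(val[(m - 1):m])
    val <- sm
  }
  out <- data.frame(offset = off, value = val)
  attr(out, "truncated") <- truncated
  out
}

# Levenberg-Marquardt least squares for the offset Gaussian
# y = baseline + a * exp(-(x - c)^2 / (2 d^2)), analytic Jacobian.
.gaussLM <- function(x, y, init, maxIter = 1000L) {
  th <- init   # c(baseline, a, c, d)
  m <- length(x)
  J <- matrix(1, m, 4)
  model <- function(t) t[1] + t[2] * exp(-(x - t[3])^2 / (2 * t[4]^2))
  r <- y - model(th)
  sse <- sum(r^2)
  lambda <- 1e-3
  conv <- FALSE
  for (it in seq_len(maxIter)) {
    d2 <- th[4]^2
    dx <- x - th[3]
    E <- exp(-dx^2 / (2 * d2))
    J[, 2] <- E
    J[, 3] <- th[2] * E * dx / d2
    J[, 4] <- th[2] * E * dx^2 / (th[4] * d2)
    g <- crossprod(J, r)
    H <- crossprod(J)
    if (any(!is.finite(H))) break
    step <- tryCatch(solve(H + lambda * diag(diag(H) + 1e-12, 4), g),
                     error = function(e) NULL)
    if (is.null(step)) {
      lambda <- lambda * 10
      if (lambda > 1e10) break
      next
    }
    cand <- th + as.numeric(step)
    if (abs(cand[4]) < 1e-4) cand[4] <- sign(cand[4] + 1e-12) * 1e-4
    rc <- y - model(cand)
    sc <- sum(rc^2)
    if (is.finite(sc) && sc < sse) {
      relDrop <- (sse - sc) / max(sse, 1e-300)
      th <- cand; r <- rc; sse <- sc
      lambda <- max(lambda / 3, 1e-12)
      if (relDrop < 1e-10) { conv <- TRUE; break }
    } else {
      lambda <- lambda * 5
      if (lambda > 1e10) { conv <- TRUE; break }
    }
  }
  list(theta = th, sse = sse, converged = conv || maxIter == 0)
}

#' Fit a Gaussian curve to a normal intensity profile
#'
#' Least-squares fit of `y = baseline + a * exp(-(x - c)^2 / (2 d^2))` by
#' Levenberg-Marquardt with an iteration cap of 1000. Initial values:
#' baseline at the profile minimum, height `a` at max - min, center `c` at
#' the offset of the maximum, width `d` at half the normal radius. The
#' width is reported positive. The fit is accepted when all four criteria
#' hold: `r2 > 0.8`, `a > 0`, `d < 2 * normalRadiusPx` and
#' `|c| < normalRadiusPx`.
#'
#' @param profile data.frame with columns `offset` and `value` (>= 5 rows).
#' @param normalRadiusPx normal radius in pixels (criteria 3 and 4).
#' @param maxIter iteration cap.
#' @return a one-row data.frame with columns `fitA`, `fitC`, `fitD`,
#'   `fitR2`, `fitBaseline`, `accepted`.
#' @export
fitGaussianProfile <- function(profile, normalRadiusPx, maxIter = 1000L) {
  bad <- data.frame(fitA = NA_real_, fitC = NA_real_, fitD = NA_real_,
                    fitR2 = NA_real_, fitBaseline = NA_real_,
                    accepted = FALSE)
  if (is.null(profile) || nrow(profile) < 5) return(bad)
  x <- profile$offset; y <- profile$value
  sstot <- sum((y - mean(y))^2)
  if (sstot <= 0) return(bad)
  init <- c(min(y), max(y) - min(y), x[which.max(y)], normalRadiusPx / 2)
  fit <- .gaussLM(x, y, init, maxIter)
  th <- fit$theta
  a <- th[2]; cc <- th[3]; d <- abs(th[4])
  r2 <- 1 - fit$sse / sstot
  accepted <- isTRUE(fit$converged) && is.finite(r2) &&
    r2 > 0.8 && a > 0 && d < 2 * normalRadiusPx && abs(cc) < normalRadiusPx
  data.frame(fitA = a, fitC = cc, fitD = d, fitR2 = r2,
             fitBaseline = th[1], accepted = accepted)
}

# Fit profiles for every point of a trace and bind the results.
# Numerically identical to sampleNormalProfile + fitGaussianProfile, but
# without per-point data.frame allocation (tens of thousands of fits per
# movie make that overhead the pipeline bottleneck).
.fitTraceProfiles <- function(frame, pts, settings, pixelSize) {
  R <- max(1L, as.integer(round(settings@normalRadiusUm / pixelSize)))
  n <- nrow(pts)
  fitA <- fitC <- fitD <- fitR2 <- fitBaseline <- rep(NA_real_, n)
  accepted <- rep(FALSE, n)
  off0 <- (-R):R
  for (i in seq_len(n)) {
    xs <- pts$x[i] + off0 * pts$nx[i]
    ys <- pts$y[i] + off0 * pts$ny[i]
    ok <- .insideFrame(frame, xs, ys)
    off <- off0[ok]
    if (length(off) < 5) next
    y <- .bilinear(frame, xs[ok], ys[ok])
    if (settings@smoothNormalProfile && length(y) >= 3) {
      m <- length(y)
      sm <- y
      sm[2:(m - 1)] <- (y[1:(m - 2)] + y[2:(m - 1)] + y[3:m]) / 3
      sm[1] <- mean(y[1:2]); sm[m] <- mean(y[(m - 1):m])
      y <- sm
    }
    sstot <- sum((y - mean(y))^2)
    if (sstot <= 0) next
    init <- c(min(y), max(y) - min(y), off[which.max(y)], R / 2)
    fit <- .gaussLM(off, y, init)
    th <- fit$theta
    fitBaseline[i] <- th[1]
    fitA[i] <- th[2]; fitC[i] <- th[3]; fitD[i] <- abs(th[4])
    fitR2[i] <- 1 - fit$sse / sstot
    accepted[i] <- isTRUE(fit$converged) && is.finite(fitR2[i]) &&
      fitR2[i] > 0.8 && fitA[i] > 0 && fitD[i] < 2 * R && abs(fitC[i]) < R
  }
  pts$fitA <- fitA; pts$fitC <- fitC; pts$fitD <- fitD
  pts$fitR2 <- fitR2; pts$fitBaseline <- fitBaseline
  pts$accepted <- accepted
  pts
}

# TRUE for points within the head disk (radius 8 px around the first point).
.headPointMask <- function(pts, radiusPx = 8) {
  (pts$x - pts$x[1])^2 + (pts$y - pts$y[1])^2 <= radiusPx^2
}

#' Shift points onto the fitted profile centers
#'
#' Every point whose Gaussian fit was accepted is shifted by `c * n` along
#' its normal so that it sits on the center of the intensity profile.
#' Rejected points stay in place. When `excludeHeadFromCorrection` is set,
#' points within 8 px of the first point are exempt.
#'
#' @param pts point data.frame with tangents/normals and fit columns.
#' @param settings a [TraceSettings-class].
#' @return the corrected data.frame (column `corrected` marks moved points).
#' @export
centerCorrect <- function(pts, settings) {
  head <- if (settings@excludeHeadFromCorrection) .headPointMask(pts)
          else rep(FALSE, nrow(pts))
  move <- pts$accepted & !head & is.finite(pts$fitC)
  pts$x[move] <- pts$x[move] + pts$fitC[move] * pts$nx[move]
  pts$y[move] <- pts$y[move] + pts$fitC[move] * pts$ny[move]
  pts$corrected <- move
  pts
}

#' Remove tip-scatter outliers from a trace
#'
#' Single simultaneous sweep over the interior triplets of the list: a
#' point is removed when its distance from its predecessor strictly
#' exceeds its distance to its successor by more than a relative jitter
#' guard, the signature of stray points that jumped off the curve (points
#' that leapt away sit far from the previous point but close to where the
#' curve resumes). All triplets are evaluated on the original neighbours
#' before any removal; endpoints are never removed.
#'
#' @param pts point data.frame (>= 3 rows to have any effect).
#' @param tolerance relative slack: a point is removed when
#'   `dPrev > (1 + tolerance) * dNext`. Zero applies the strict rule. The
#'   refinement pipeline uses 0.5: in an upscaled list the gaps are
#'   sub-pixel and nearly equal, so the strict rule would remove roughly
#'   every second point on jitter alone (and any point where the pixel
#'   lattice switches between straight and diagonal steps, gap ratio
#'   sqrt(2)), while genuine off-curve stragglers show gap ratios well
#'   above 1.5.
#' @return the pruned data.frame.
#' @export
removeOutliers <- function(pts, tolerance = 0) {
  n <- nrow(pts)
  if (n < 3) return(pts)
  i <- 2:(n - 1)
  dPrev <- sqrt((pts$x[i] - pts$x[i - 1])^2 + (pts$y[i] - pts$y[i - 1])^2)
  dNext <- sqrt((pts$x[i + 1] - pts$x[i])^2 + (pts$y[i + 1] - pts$y[i])^2)
  keep <- c(TRUE, !(dPrev > (1 + tolerance) * dNext), TRUE)
  out <- pts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Median-projection smoothing core: for target value/position and a set of
# candidate predictions with displacements, pick the prediction whose
# displacement is nearest the lower median; ties -> lowest index.
.medianPick <- function(disp) {
  med <- .lowerMedian(disp)
  which.min(abs(disp - med))
}

#' Median-projection smoothing of trace coordinates
#'
#' For each point, lines through all pairs of up to `neighborCount` upstream
#' and downstream points (excluding the point itself; fewer near the ends)
#' are generated; the point is orthogonally projected onto each line and
#' replaced by the projection whose displacement is nearest to the (lower)
#' median displacement. All projections are computed from the original
#' coordinates. Locally the flagellum is close to a line, so this removes
#' jitter without flattening curvature; the median makes it robust to
#' individual stray points.
#'
#' @param pts point data.frame.
#' @param neighborCount neighbours included on each side (>= 1).
#' @return the smoothed data.frame.
#' @export
smoothXY <- function(pts, neighborCount) {
  stopifnot(neighborCount >= 1)
  n <- nrow(pts)
  if (n < 3) return(pts)
  X <- pts$x; Y <- pts$y
  newX <- X; newY <- Y
  # pair templates reused across points with the same window shape
  pairCache <- new.env(parent = emptyenv())
  pairsFor <- function(nb) {
    key <- paste(nb[1] - nb[length(nb)], length(nb), sep = "_")
    tpl <- pairCache[[key]]
    if (is.null(tpl)) {
      tpl <- utils::combn(seq_along(nb), 2)
      pairCache[[key]] <- tpl
    }
    matrix(nb[tpl], nrow = 2)
  }
  for (i in seq_len(n)) {
    nb <- c(if (i > 1) max(1, i - neighborCount):(i - 1),
            if (i < n) (i + 1):min(n, i + neighborCount))
    if (length(nb) < 2) next
    pr <- pairsFor(nb)
    ax <- X[pr[1, ]]; ay <- Y[pr[1, ]]
    bx <- X[pr[2, ]]; by <- Y[pr[2, ]]
    dx <- bx - ax; dy <- by - ay
    l2 <- dx^2 + dy^2
    okp <- l2 > 1e-24
    if (!any(okp)) next
    tpar <- ((X[i] - ax) * dx + (Y[i] - ay) * dy) / l2
    prx <- ax + tpar * dx
    pry <- ay + tpar * dy
    disp <- sqrt((X[i] - prx)^2 + (Y[i] - pry)^2)
    idx <- which(okp)
    pick <- idx[.medianPick(disp[idx])]
    newX[i] <- prx[pick]; newY[i] <- pry[pick]
  }
  pts$x <- newX; pts$y <- newY
  pts
}

#' Arc-length parameterization
#'
#' Assigns each point its arc length: zero at the first point, then the
#' cumulative sum of consecutive Euclidean distances scaled to micrometres.
#' Coincident consecutive points are merged first so arc lengths are
#' strictly increasing.
#'
#' @param pts point data.frame.
#' @param pixelSize micrometres per pixel.
#' @return the data.frame with column `arcLengthUm`.
#' @export
computeArcLengths <- function(pts, pixelSize) {
  n <- nrow(pts)
  if (n >= 2) {
    d <- sqrt(diff(pts$x)^2 + diff(pts$y)^2)
    dup <- which(d < 1e-12)
    if (length(dup)) {
      pts <- pts[-(dup + 1L), , drop = FALSE]
      rownames(pts) <- NULL
      return(computeArcLengths(pts, pixelSize))
    }
    pts$arcLengthUm <- c(0, cumsum(d)) * pixelSize
  } else {
    pts$arcLengthUm <- rep(0, n)
  }
  pts
}

#' Median-projection smoothing of the fit widths (relative z)
#'
#' Applies the same median-projection scheme as [smoothXY()] to the
#' one-dimensional width-versus-arc-length signal: for each point, lines
#' through pairs of neighbouring `(l, d)` samples predict the width at the
#' point's arc length; the prediction whose displacement is nearest the
#' median is adopted. Neighbours are restricted to the same
#' `neighborCount` window and additionally to arc distances at most
#' `arcDistanceLimitUm`; with fewer than 2 eligible neighbours (including
#' the case `arcDistanceLimitUm = 0`) the width is kept unsmoothed.
#'
#' @param pts point data.frame with `arcLengthUm` and `fitD` columns.
#' @param arcDistanceLimitUm arc-distance cutoff in micrometres.
#' @param neighborCount neighbours included on each side.
#' @return the data.frame with column `zWidth` added.
#' @export
smoothZWidths <- function(pts, arcDistanceLimitUm, neighborCount = 15) {
  n <- nrow(pts)
  l <- pts$arcLengthUm
  d <- pts$fitD
  z <- d
  pairCache <- new.env(parent = emptyenv())
  pairsFor <- function(nb) {
    key <- as.character(length(nb))
    tpl <- pairCache[[key]]
    if (is.null(tpl)) {
      tpl <- utils::combn(seq_along(nb), 2)
      pairCache[[key]] <- tpl
    }
    matrix(nb[tpl], nrow = 2)
  }
  for (i in seq_len(n)) {
    if (!is.finite(d[i])) next
    nb <- c(if (i > 1) max(1, i - neighborCount):(i - 1),
            if (i < n) (i + 1):min(n, i + neighborCount))
    nb <- nb[is.finite(d[nb]) & abs(l[nb] - l[i]) <= arcDistanceLimitUm]
    if (length(nb) < 2) next
    pr <- pairsFor(nb)
    la <- l[pr[1, ]]; da <- d[pr[1, ]]
    lb <- l[pr[2, ]]; db <- d[pr[2, ]]
    okp <- abs(lb - la) > 1e-12
    if (!any(okp)) next
    pred <- da + (db - da) * (l[i] - la) / (lb - la)
    disp <- abs(d[i] - pred)
    idx <- which(okp)
    pick <- idx[.medianPick(disp[idx])]
    z[i] <- pred[pick]
  }
  pts$zWidth <- z
  pts
}

#' Refine a rough trace to sub-pixel precision
#'
#' Runs the full two-pass refinement on an upscaled rough point list:
#'
#' Pass 1: tangents/normals, normal-profile Gaussian fits, center
#' correction, outlier removal, median-projection xy smoothing, arc lengths.
#'
#' Pass 2: outlier removal, recomputed tangents/normals, refitted profiles,
#' center correction, optional removal of points with rejected fits
#' (`filterPointsByFits`), arc lengths, z-width smoothing, and a final
#' tangent/normal refresh for the kinematics stage.
#'
#' @param frame the background-corrected intensity frame.
#' @param pts upscaled head-first point data.frame.
#' @param settings a [TraceSettings-class].
#' @param pixelSize micrometres per pixel.
#' @param frameIndex 1-based frame index stored in the result.
#' @param passes 2 for the full refinement; 1 stops after the first
#'   correction/smoothing pass (diagnostics).
#' @return a [FlagellarTrace-class].
#' @export
refineTrace <- function(frame, pts, settings, pixelSize, frameIndex = 1,
                        passes = 2) {
  # pass 1
  pts <- computeTangentsNormals(pts, settings@maxVectorLengthPoints)
  pts <- .fitTraceProfiles(frame, pts, settings, pixelSize)
  pts <- centerCorrect(pts, settings)
  pts <- removeOutliers(pts, tolerance = 0.5)
  pts <- smoothXY(pts, settings@smoothingNeighborCount)
  pts <- computeArcLengths(pts, pixelSize)
  if (passes >= 2) {
    pts <- removeOutliers(pts, tolerance = 0.5)
    pts <- computeTangentsNormals(pts, settings@maxVectorLengthPoints)
    pts <- .fitTraceProfiles(frame, pts, settings, pixelSize)
    pts <- centerCorrect(pts, settings)
    if (settings@filterPointsByFits) {
      keep <- pts$accepted
      if (settings@excludeHeadFromCorrection)
        keep <- keep | .headPointMask(pts)
      if (sum(keep) >= 3) {
        pts <- pts[keep, , drop = FALSE]
        rownames(pts) <- NULL
      }
    }
    pts <- computeArcLengths(pts, pixelSize)
  }
  pts <- smoothZWidths(pts, settings@zSmoothingArcDistanceUm,
                       settings@smoothingNeighborCount)
  pts <- computeTangentsNormals(pts, settings@maxVectorLengthPoints)
  pts$intensity <- pts$fitA
  new("FlagellarTrace", points = pts, frame = as.numeric(frameIndex),
      pixelSize = pixelSize)
}
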