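#' Head-midpiece vector and orientation angle
#'
#' The head-midpiece vector runs from the first trace point to the trace
#' point nearest to the reference arc length; the head orientation angle
#' Theta is the angle of this vector against the image x-axis. Angles are
#' reported in degrees in the screen-math convention (counterclockwise
#' positive; a reference point below the head, at larger row index, gives a
#' negative angle).
#'
#' @param trace a [FlagellarTrace-class] or its point data.frame with
#'   `arcLengthUm`.
#' @param referenceArcLengthUm the reference arc length (micrometres).
#' @return a list with `v` (pixel-space vector), `thetaDeg`, and `valid`
#'   (`FALSE` when the trace is shorter than the reference arc length).
#' @export
headMidpieceVector <- function(trace, referenceArcLengthUm) {
  pts <- if (is(trace, "FlagellarTrace")) trace@points else trace
  l <- pts$arcLengthUm
  if (max(l) < referenceArcLengthUm)
    return(list(v = c(NA_real_, NA_real_), thetaDeg = NA_real_,
                valid = FALSE))
  i <- which.min(abs(l - referenceArcLengthUm))
  v <- c(pts$x[i] - pts$x[1], pts$y[i] - pts$y[1])
  list(v = v, thetaDeg = .angleOfDeg(v[1], v[2]), valid = TRUE)
}

#' Transform trace coordinates into the head frame
#'
#' Rigid transform that places the head at the origin and aligns the
#' head-midpiece vector with the +x axis. Coordinates are returned in
#' micrometres; the reference point maps to `(|v| * pixelSize, 0)`.
#'
#' @param trace a [FlagellarTrace-class] or point data.frame.
#' @param v head-midpiece vector in pixel units.
#' @param pixelSize micrometres per pixel.
#' @return a data.frame with columns `xHeadUm`, `yHeadUm`.
#' @export
transformToHeadFrame <- function(trace, v, pixelSize) {
  pts <- if (is(trace, "FlagellarTrace")) trace@points else trace
  stopifnot(sqrt(sum(v^2)) > 0)
  theta <- atan2(-v[2], v[1])
  ux <- pts$x - pts$x[1]
  uy <- -(pts$y - pts$y[1])      # screen-math y
  data.frame(
    xHeadUm = (cos(theta) * ux + sin(theta) * uy) * pixelSize,
    yHeadUm = (-sin(theta) * ux + cos(theta) * uy) * pixelSize)
}

#' Tangential angle along the flagellum
#'
#' Angle between each point's tangent vector and the image x-axis, in
#' degrees, unwrapped along arc length so the series is continuous.
#'
#' @param trace a [FlagellarTrace-class] or point data.frame with tangents.
#' @return numeric vector of angles (degrees).
#' @export
tangentialAngle <- function(trace) {
  pts <- if (is(trace, "FlagellarTrace")) trace@points else trace
  .unwrapDeg(.angleOfDeg(pts$tx, pts$ty))
}

# Signed angle (radians) from tangent 1 to tangent 2, screen-math sign.
.tangentAngleRad <- function(t1x, t1y, t2x, t2y) {
  cross <- t1x * (-t2y) - (-t1y) * t2x
  dot <- t1x * t2x + t1y * t2y
  atan2(cross, dot)
}

#' Geometric curvature along the flagellum
#'
#' The curvature at arc length `s` is the signed angle between the tangents
#' at `s - Q/2` and `s + Q/2` divided by their actual arc separation
#' (rad/um), with `Q` the reference distance. Near the ends a smaller
#' distance is chosen (the support is clamped to the trace). The sign
#' follows the screen-math convention used for all angles.
#'
#' @param trace a [FlagellarTrace-class] or point data.frame with tangents
#'   and `arcLengthUm`.
#' @param referenceDistanceUm tangent separation `Q` in micrometres.
#' @return numeric vector of curvatures (rad/um), `NA` where the support
#'   degenerates.
#' @export
curvatureSeries <- function(trace, referenceDistanceUm) {
  pts <- if (is(trace, "FlagellarTrace")) trace@points else trace
  l <- pts$arcLengthUm
  n <- nrow(pts)
  half <- referenceDistanceUm / 2
  i1 <- vapply(pmax(l - half, l[1]),
               function(s) which.min(abs(l - s)), integer(1))
  i2 <- vapply(pmin(l + half, l[n]),
               function(s) which.min(abs(l - s)), integer(1))
  ds <- l[i2] - l[i1]
  ang <- .tangentAngleRad(pts$tx[i1], pts$ty[i1], pts$tx[i2], pts$ty[i2])
  out <- ang / ds
  out[ds <= .Machine$double.eps] <- NA_real_
  out
}

#' Curvature angle along the flagellum
#'
#' The curvature angle at arc length `s` is the signed angle (degrees)
#' between the tangent at `s` and the tangent at `s - Q`. For `s < Q` the
#' first trace point provides the upstream tangent (shortened support).
#'
#' @inheritParams curvatureSeries
#' @return numeric vector of curvature angles (degrees).
#' @export
curvatureAngleSeries <- function(trace, referenceDistanceUm) {
  pts <- if (is(trace, "FlagellarTrace")) trace@points else trace
  l <- pts$arcLengthUm
  iUp <- vapply(pmax(l - referenceDistanceUm, l[1]),
                function(s) which.min(abs(l - s)), integer(1))
  idx <- seq_len(nrow(pts))
  .tangentAngleRad(pts$tx[iUp], pts$ty[iUp], pts$tx[idx], pts$ty[idx]) *
    180 / pi
}

#' Maximum intensity on the head cross-line
#'
#' Samples a line through the first trace point, oriented normal to the
#' head-midpiece vector, of half-length `radiusPx`, in steps of one pixel.
#' At each step the intensity is averaged across the 9-pixel thickness of
#' the line (sampled at one-pixel steps along the head-midpiece direction,
#' bilinearly interpolated); the maximum of these step means is returned.
#' While the cell rolls about its longitudinal axis, the light scattered by
#' the elliptical head oscillates, so this signal carries the rolling
#' frequency.
#'
#' @param frame intensity frame.
#' @param p1 head position `c(x, y)` (0-based pixels).
#' @param v head-midpiece vector (pixel units).
#' @param radiusPx half-length of the cross-line in pixels.
#' @param thickness line thickness in pixels (fixed to 9 in the reference
#'   workflow).
#' @return the maximum step mean, with attribute `"truncated"` when part of
#'   the line left the frame.
#' @export
headRollingSignal <- function(frame, p1, v, radiusPx, thickness = 9) {
  len <- sqrt(sum(v^2))
  if (len == 0) stop("head-midpiece vector has zero length")
  u <- v / len                 # along the head axis
  w <- c(-u[2], u[1])          # cross-line direction
  steps <- (-radiusPx):radiusPx
  halfT <- (thickness - 1) / 2
  thick <- (-halfT):halfT
  truncated <- FALSE
  means <- rep(NA_real_, length(steps))
  for (k in seq_along(steps)) {
    xs <- p1[1] + steps[k] * w[1] + thick * u[1]
    ys <- p1[2] + steps[k] * w[2] + thick * u[2]
    ok <- .insideFrame(frame, xs, ys)
    if (!all(ok)) truncated <- TRUE
    if (!any(ok)) next
    means[k] <- mean(.bilinear(frame, xs[ok], ys[ok]))
  }
  out <- max(means, na.rm = TRUE)
  attr(out, "truncated") <- truncated
  out
}

#' Unwrap a per-frame angle series
#'
#' Adjusts successive frames by multiples of 360 degrees so consecutive
#' differences stay within (-180, 180], making the series suitable for
#' spectral analysis.
#'
#' @param thetaDeg numeric vector of angles in degrees (may contain `NA`).
#' @return the unwrapped series.
#' @export
thetaSeries <- function(thetaDeg) .unwrapDeg(thetaDeg)

#' Annotate a trace with kinematic parameters
#'
#' Computes the head-midpiece vector, Theta, head-frame coordinates,
#' tangential angle, curvature and curvature angle for one refined trace
#' and stores them as extra point columns plus attributes.
#'
#' @param trace a [FlagellarTrace-class].
#' @param settings a [TraceSettings-class].
#' @param frame the intensity frame (for the rolling signal); may be `NULL`.
#' @return the annotated [FlagellarTrace-class]; the head parameters are in
#'   `attr(tracePoints(x), ...)`-free form: columns plus the
#'   `headTheta`/`headV`/`rollingMax` attributes of the object's points.
#' @export
annotateKinematics <- function(trace, settings, frame = NULL) {
  pts <- trace@points
  hv <- headMidpieceVector(pts, settings@referenceVectorArcLengthUm)
  if (hv$valid) {
    hf <- transformToHeadFrame(pts, hv$v, trace@pixelSize)
    pts$xHeadUm <- hf$xHeadUm
    pts$yHeadUm <- hf$yHeadUm
  } else {
    pts$xHeadUm <- NA_real_
    pts$yHeadUm <- NA_real_
  }
  pts$tangentAngleDeg <- tangentialAngle(pts)
  pts$curvature <- curvatureSeries(pts, settings@curvatureReferenceDistanceUm)
  pts$curvatureAngleDeg <-
    curvatureAngleSeries(pts, settings@curvatureReferenceDistanceUm)
  attr(pts, "thetaDeg") <- hv$thetaDeg
  attr(pts, "headV") <- hv$v
  attr(pts, "rollingMax") <-
    if (!is.null(frame) && hv$valid)
      as.numeric(headRollingSignal(frame, c(pts$x[1], pts$y[1]), hv$v,
                                   settings@headRotationRadiusPx))
    else NA_real_
  initialize(trace, points = pts)
}
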