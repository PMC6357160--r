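#' Parameters for the synthetic dark-field movie renderer
#'
#' Describes a kinematic flagellar waveform plus rendering options. The
#' flagellum is built from an analytic tangent-angle field
#' `phi(s, t) = psi(t) + B(s) sin(2 pi (f t - s / lambda) + phase) + ...`
#' whose unit tangents are integrated along arc length, so the ground-truth
#' arc length is exactly the curve parameter and curvature fields are known
#' in closed form. `psi(t)` is the base orientation plus optional rocking
#' (yaw) oscillations; extra harmonic terms can be gated to an arc-length
#' interval (with smooth 2 um shoulders). The tube is drawn by max-blending
#' Gaussian cross-sections whose width sigma(s, t) encodes defocus; the
#' head is a bright anisotropic Gaussian blob aligned with the proximal
#' tangent, optionally intensity-modulated at the rolling frequency.
#'
#' @param nFrames,fps number of frames and frame rate (Hz).
#' @param width,height image size in pixels.
#' @param pixelSize micrometres per pixel.
#' @param lengthUm flagellum length in micrometres.
#' @param beatHz fundamental beat frequency (must satisfy Nyquist).
#' @param waveAmpRad tangent-angle amplitude of the fundamental (rad).
#' @param wavelengthUm wavelength of the traveling wave (micrometres).
#' @param phase phase offset (rad).
#' @param rampUm amplitude envelope: the tangent-angle amplitude grows
#'   linearly from 0 at the head to its full value at this arc length.
#' @param harmonics data.frame with columns `mult`, `ampRad`, `gateLoUm`,
#'   `gateHiUm` (and optionally `wavelengthUm`), or `NULL`.
#' @param yaw data.frame with columns `ampDeg`, `hz`, `phase` describing
#'   base-orientation rocking, or `NULL`.
#' @param baseAngleDeg overall orientation of the cell (degrees,
#'   screen-math convention).
#' @param headStartPx head position `c(x, y)` in 0-based pixels.
#' @param mode `"tethered"` (fixed head) or `"swimming"` (drifting head).
#' @param headSpeedUmPerS,headDirDeg drift speed and direction for
#'   swimming mode.
#' @param tubeIntensity peak tube intensity (arbitrary units) at the
#'   reference (in-focus) width `tubeSigmaPx[1]`; where the tube defocuses
#'   to a larger sigma its peak dims by `tubeSigmaPx[1] / sigma`, so the
#'   integrated cross-section flux is conserved (defocused segments appear
#'   wider and dimmer, as in real dark-field movies).
#' @param tubeSigmaPx tube Gaussian sigma in pixels; length 2 for a linear
#'   head-to-tip defocus profile (> 0.5 px).
#' @param sigmaModAmpPx,sigmaModHz defocus oscillation: sigma gains
#'   `amp * |sin(2 pi f t)|`, emulating a flagellum crossing the focal
#'   plane at frequency `f` (the width signal then oscillates at `2 f`).
#' @param tipFadeUm tube intensity fades linearly to zero over this arc
#'   length at the tip (distal thinning seen in real dark-field movies).
#' @param headAxesPx head Gaussian sigmas `c(along axis, across axis)`.
#' @param headIntensity peak head intensity.
#' @param rollingDepth,rollingHz relative modulation depth and frequency of
#'   the head intensity.
#' @param background constant background level.
#' @param noiseSd additive Gaussian noise standard deviation (0 = off).
#' @param poissonScale Poisson noise scale: counts are drawn as
#'   `rpois(intensity * scale) / scale` (0 = off).
#' @return a validated `SynthParams` list.
#' @export
synthParams <- function(nFrames = 64, fps = 200, width = 160, height = 160,
                        pixelSize = 0.55, lengthUm = 55,
                        beatHz = 11, waveAmpRad = 0.9, wavelengthUm = 36,
                        phase = 0, rampUm = 10,
                        harmonics = NULL, yaw = NULL,
                        baseAngleDeg = 0,
                        headStartPx = c(25, height / 2),
                        mode = c("tethered", "swimming"),
                        headSpeedUmPerS = 0, headDirDeg = 0,
                        tubeIntensity = 120, tubeSigmaPx = c(2, 2),
                        sigmaModAmpPx = 0, sigmaModHz = 0,
                        tipFadeUm = 4,
                        headAxesPx = c(4, 2.5),
                        headIntensity = 400, rollingDepth = 0,
                        rollingHz = 0,
                        background = 4, noiseSd = 0, poissonScale = 0) {
  mode <- match.arg(mode)
  if (length(tubeSigmaPx) == 1) tubeSigmaPx <- rep(tubeSigmaPx, 2)
  p <- list(nFrames = nFrames, fps = fps, width = width, height = height,
            pixelSize = pixelSize, lengthUm = lengthUm, beatHz = beatHz,
            waveAmpRad = waveAmpRad, wavelengthUm = wavelengthUm,
            phase = phase, rampUm = rampUm, harmonics = harmonics,
            yaw = yaw, baseAngleDeg = baseAngleDeg,
            headStartPx = headStartPx, mode = mode,
            headSpeedUmPerS = headSpeedUmPerS, headDirDeg = headDirDeg,
            tubeIntensity = tubeIntensity, tubeSigmaPx = tubeSigmaPx,
            sigmaModAmpPx = sigmaModAmpPx, sigmaModHz = sigmaModHz,
            tipFadeUm = tipFadeUm, headAxesPx = headAxesPx,
            headIntensity = headIntensity, rollingDepth = rollingDepth,
            rollingHz = rollingHz, background = background,
            noiseSd = noiseSd, poissonScale = poissonScale)
  fAll <- c(beatHz, rollingHz, sigmaModHz * 2,
            if (!is.null(harmonics)) harmonics$mult * beatHz,
            if (!is.null(yaw)) yaw$hz)
  if (any(fAll >= fps / 2))
    stop("all frequencies must satisfy the Nyquist bound (< fps/2)")
  if (any(tubeSigmaPx <= 0.5)) stop("tube sigma must exceed 0.5 px")
  stopifnot(nFrames >= 2, lengthUm > 0, pixelSize > 0)
  class(p) <- "SynthParams"
  p
}

#' Reference render presets
#'
#' `"mouse-tethered"`: a head-tethered cell imaged at 200 fps behind 16x
#' magnification (0.6875 um/px); `"human-swimming"`: a rolling,
#' freely-swimming cell at 500 fps behind 20x magnification (0.55 um/px)
#' whose base orientation rocks at the rolling frequency with a beat at
#' three times the roll.
#'
#' @param name preset name.
#' @param ... overrides passed to [synthParams()].
#' @return a `SynthParams` list.
#' @export
synthPreset <- function(name = c("mouse-tethered", "human-swimming"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "mouse-tethered" = list(
      nFrames = 200, fps = 200, width = 220, height = 220,
      pixelSize = 0.6875, lengthUm = 100, beatHz = 11,
      waveAmpRad = 0.9, wavelengthUm = 60, rampUm = 15,
      headStartPx = c(30, 110), mode = "tethered"),
    "human-swimming" = list(
      nFrames = 500, fps = 500, width = 200, height = 200,
      pixelSize = 0.55, lengthUm = 50, beatHz = 27,
      waveAmpRad = 0.7, wavelengthUm = 36, rampUm = 10,
      yaw = data.frame(ampDeg = c(14, 5), hz = c(9, 27), phase = c(0, 1)),
      rollingDepth = 0.35, rollingHz = 9,
      headStartPx = c(30, 100), mode = "tethered"))
  do.call(synthParams, utils::modifyList(base, list(...)))
}

# Tangent-angle field phi(s, t) in radians (screen-math convention) for a
# vector of arc lengths s (um) at time t (s).
.phiField <- function(p, s, t) {
  env <- if (p$rampUm > 0) pmin(1, s / p$rampUm) else rep(1, length(s))
  phi <- p$baseAngleDeg * pi / 180 +
    p$waveAmpRad * env *
      sin(2 * pi * (p$beatHz * t - s / p$wavelengthUm) + p$phase)
  if (!is.null(p$yaw))
    for (k in seq_len(nrow(p$yaw)))
      phi <- phi + p$yaw$ampDeg[k] * pi / 180 *
        sin(2 * pi * p$yaw$hz[k] * t + p$yaw$phase[k])
  if (!is.null(p$harmonics)) {
    for (k in seq_len(nrow(p$harmonics))) {
      h <- p$harmonics[k, ]
      lam <- if (!is.null(h$wavelengthUm) && is.finite(h$wavelengthUm))
        h$wavelengthUm else p$wavelengthUm / h$mult
      gate <- .smoothGate(s, h$gateLoUm, h$gateHiUm, 2)
      phi <- phi + h$ampRad * gate *
        sin(2 * pi * (h$mult * p$beatHz * t - s / lam) + p$phase)
    }
  }
  phi
}

# Smooth 0/1 gate over [lo, hi] with smoothstep shoulders of given width.
.smoothGate <- function(s, lo, hi, shoulder = 2) {
  up <- pmin(pmax((s - lo) / shoulder, 0), 1)
  dn <- pmin(pmax((hi - s) / shoulder, 0), 1)
  f <- function(u) u * u * (3 - 2 * u)
  f(up) * f(dn)
}

# Defocus profile sigma(s, t) in pixels.
.sigmaField <- function(p, s, t) {
  base <- p$tubeSigmaPx[1] +
    (p$tubeSigmaPx[2] - p$tubeSigmaPx[1]) * s / p$lengthUm
  if (p$sigmaModAmpPx > 0)
    base <- base + p$sigmaModAmpPx * abs(sin(2 * pi * p$sigmaModHz * t))
  base
}

# Head position (px) at time t.
.headAt <- function(p, t) {
  if (p$mode == "swimming" && p$headSpeedUmPerS != 0) {
    d <- p$headDirDeg * pi / 180
    p$headStartPx + p$headSpeedUmPerS * t / p$pixelSize *
      c(cos(d), -sin(d))
  } else p$headStartPx
}

# Integrate the tangent field into a centerline (matrix ns x 2, px).
.centerlineAt <- function(p, sGrid, t) {
  phi <- .phiField(p, sGrid, t)
  dsPx <- diff(sGrid) / p$pixelSize
  # trapezoidal integration of the unit tangents
  cx <- cumsum(c(0, dsPx * (cos(phi[-length(phi)]) + cos(phi[-1])) / 2))
  cy <- cumsum(c(0, dsPx * (-sin(phi[-length(phi)]) - sin(phi[-1])) / 2))
  h <- .headAt(p, t)
  cbind(x = h[1] + cx, y = h[2] + cy)
}

# Stamp a radially symmetric Gaussian into the canvas by max-blending.
.stampGauss <- function(canvas, cx, cy, sigma, amp) {
  if (amp <= 0) return(canvas)
  w <- ceiling(3 * sigma)
  xs <- max(0, floor(cx - w)):min(ncol(canvas) - 1, ceiling(cx + w))
  ys <- max(0, floor(cy - w)):min(nrow(canvas) - 1, ceiling(cy + w))
  if (!length(xs) || !length(ys)) return(canvas)
  dx2 <- (xs - cx)^2
  dy2 <- (ys - cy)^2
  g <- amp * exp(-(outer(dy2, dx2, "+")) / (2 * sigma^2))
  sub <- canvas[ys + 1, xs + 1, drop = FALSE]
  canvas[ys + 1, xs + 1] <- pmax(sub, g)
  canvas
}

# Stamp an anisotropic Gaussian (head blob) aligned with direction phi.
.stampHead <- function(canvas, cx, cy, phi, axes, amp) {
  w <- ceiling(3 * max(axes))
  xs <- max(0, floor(cx - w)):min(ncol(canvas) - 1, ceiling(cx + w))
  ys <- max(0, floor(cy - w)):min(nrow(canvas) - 1, ceiling(cy + w))
  if (!length(xs) || !length(ys)) return(canvas)
  gx <- outer(rep(1, length(ys)), xs - cx)
  gy <- outer(ys - cy, rep(1, length(xs)))
  du <- gx * cos(phi) - gy * sin(phi)    # along the head axis
  dv <- gx * sin(phi) + gy * cos(phi)
  g <- amp * exp(-(du^2 / (2 * axes[1]^2) + dv^2 / (2 * axes[2]^2)))
  sub <- canvas[ys + 1, xs + 1, drop = FALSE]
  canvas[ys + 1, xs + 1] <- pmax(sub, g)
  canvas
}

#' Render a synthetic dark-field movie with ground truth
#'
#' Draws, for every frame, the constant background, the head blob
#' (optionally intensity-modulated at the rolling frequency) and the
#' flagellar tube (Gaussian cross-sections of width sigma(s, t)
#' max-blended along the analytic centerline, sampled at 0.25 px steps),
#' then applies seeded noise. Rendering is deterministic per seed.
#'
#' @param params a `SynthParams` list from [synthParams()].
#' @param seed integer seed for the noise generator.
#' @return a list with `stack` (an [ImageStack-class]) and `truth`: the
#'   per-frame sub-pixel centerlines, the arc-length grid, the analytic
#'   tangent-angle, curvature, curvature-angle and defocus-width fields,
#'   the true head orientation series, and the generating frequencies.
#' @export
renderMovie <- function(params, seed = 1) {
  p <- params
  stopifnot(inherits(p, "SynthParams"))
  ds <- 0.25 * p$pixelSize
  sGrid <- seq(0, p$lengthUm, by = ds)
  times <- (seq_len(p$nFrames) - 1) / p$fps
  fade <- if (p$tipFadeUm > 0)
    pmin(1, (p$lengthUm - sGrid) / p$tipFadeUm) else rep(1, length(sGrid))
  framesList <- vector("list", p$nFrames)
  centerlines <- vector("list", p$nFrames)
  phiMat <- matrix(NA_real_, p$nFrames, length(sGrid))
  sigMat <- matrix(NA_real_, p$nFrames, length(sGrid))
  for (fi in seq_len(p$nFrames)) {
    t <- times[fi]
    cl <- .centerlineAt(p, sGrid, t)
    sig <- .sigmaField(p, sGrid, t)
    margin <- 3 * max(sig) + 1
    if (any(cl[, 1] < margin) || any(cl[, 1] > p$width - 1 - margin) ||
        any(cl[, 2] < margin) || any(cl[, 2] > p$height - 1 - margin))
      stop("flagellum exits frame: increase image size")
    canvas <- matrix(0, p$height, p$width)
    for (k in seq_along(sGrid))
      canvas <- .stampGauss(canvas, cl[k, 1], cl[k, 2], sig[k],
                            p$tubeIntensity * fade[k] *
                              p$tubeSigmaPx[1] / sig[k])
    phi0 <- .phiField(p, 0, t)
    headAmp <- p$headIntensity *
      (1 + p$rollingDepth * sin(2 * pi * p$rollingHz * t))
    canvas <- .stampHead(canvas, cl[1, 1], cl[1, 2], phi0,
                         p$headAxesPx, headAmp)
    framesList[[fi]] <- canvas + p$background
    centerlines[[fi]] <- cl
    phiMat[fi, ] <- .phiField(p, sGrid, t)
    sigMat[fi, ] <- sig
  }
  if (p$noiseSd > 0 || p$poissonScale > 0) {
    framesList <- .withSeed(seed, lapply(framesList, function(fr) {
      if (p$poissonScale > 0)
        fr <- matrix(stats::rpois(length(fr), fr * p$poissonScale) /
                       p$poissonScale, nrow(fr))
      if (p$noiseSd > 0)
        fr <- fr + matrix(stats::rnorm(length(fr), sd = p$noiseSd),
                          nrow(fr))
      pmax(fr, 0)
    }))
  }
  stack <- imageStack(framesList, fps = p$fps, pixelSize = p$pixelSize,
                      bitDepth = 16)
  # curvature field: d phi / d s by central differences on the fine grid
  kappa <- t(apply(phiMat, 1, function(ph)
    c(NA, diff(ph, lag = 2) / (2 * ds), NA)))
  truth <- list(
    sGridUm = sGrid,
    centerlines = centerlines,
    phiRad = phiMat,
    kappaRadPerUm = kappa,
    sigmaPx = sigMat,
    times = times,
    beatHz = p$beatHz,
    rollingHz = p$rollingHz,
    harmonics = p$harmonics,
    yaw = p$yaw,
    params = p,
    seed = seed)
  list(stack = stack, truth = truth)
}

#' Analytic curvature angle of a rendered movie
#'
#' Curvature angle field cA(s, t) (degrees) implied by the generator's
#' tangent-angle field: the angle at `s` minus the angle at `s - Q`
#' (shortened support near the head, matching the tracker's convention).
#'
#' @param truth the `truth` component of [renderMovie()].
#' @param referenceDistanceUm tangent separation `Q` in micrometres.
#' @return matrix frames x arc positions, degrees.
#' @export
truthCurvatureAngle <- function(truth, referenceDistanceUm) {
  s <- truth$sGridUm
  iUp <- vapply(pmax(s - referenceDistanceUm, 0),
                function(v) which.min(abs(s - v)), integer(1))
  (truth$phiRad - truth$phiRad[, iUp, drop = FALSE]) * 180 / pi
}

#' True head orientation series of a rendered movie
#'
#' Theta implied by the true centerlines: the angle of the vector from the
#' curve start to the curve point at the reference arc length, unwrapped.
#'
#' @param truth the `truth` component of [renderMovie()].
#' @param referenceArcLengthUm reference arc length (micrometres).
#' @return numeric vector, degrees (unwrapped).
#' @export
truthTheta <- function(truth, referenceArcLengthUm) {
  i <- which.min(abs(truth$sGridUm - referenceArcLengthUm))
  th <- vapply(truth$centerlines, function(cl)
    .angleOfDeg(cl[i, 1] - cl[1, 1], cl[i, 2] - cl[1, 2]), numeric(1))
  .unwrapDeg(th)
}

# Minimum distance from points to a polyline (proper segment projection).
.distToPolyline <- function(px, py, qx, qy) {
  ax <- qx[-length(qx)]; ay <- qy[-length(qy)]
  bx <- qx[-1]; by <- qy[-1]
  dx <- bx - ax; dy <- by - ay
  l2 <- dx^2 + dy^2
  l2[l2 == 0] <- 1e-300
  vapply(seq_along(px), function(i) {
    tpar <- pmin(pmax(((px[i] - ax) * dx + (py[i] - ay) * dy) / l2, 0), 1)
    min((px[i] - (ax + tpar * dx))^2 + (py[i] - (ay + tpar * dy))^2)
  }, numeric(1)) |> sqrt()
}

#' Score tracking results against the renderer's ground truth
#'
#' @param traces list of [FlagellarTrace-class] (as from [traceStack()]).
#' @param truth the `truth` component of [renderMovie()].
#' @param referenceArcLengthUm reference arc length for the Theta
#'   comparison (micrometres).
#' @param excludeHeadRadiusPx trace points within this distance of the true
#'   head center are excluded from the centerline error (the head blob is
#'   not part of the thin tube the sub-pixel model describes).
#' @param acceptedOnly use only points with accepted Gaussian fits.
#' @return a list with `rmsCenterlinePx`, `arcLengthRelErr` (relative to
#'   the true flagellum length), `thetaRmsDeg`, and the per-frame errors.
#' @export
scoreAgainstTruth <- function(traces, truth, referenceArcLengthUm = 10,
                              excludeHeadRadiusPx = 8,
                              acceptedOnly = TRUE) {
  nf <- length(traces)
  errs <- vector("list", nf)
  arcErr <- rep(NA_real_, nf)
  thErr <- rep(NA_real_, nf)
  thTrue <- truthTheta(truth, referenceArcLengthUm)
  L <- max(truth$sGridUm)
  for (fi in seq_len(nf)) {
    tr <- traces[[fi]]
    if (is.null(tr)) next
    pts <- tr@points
    cl <- truth$centerlines[[fi]]
    keep <- rep(TRUE, nrow(pts))
    if (acceptedOnly && "accepted" %in% names(pts))
      keep <- keep & pts$accepted
    keep <- keep &
      (pts$x - cl[1, 1])^2 + (pts$y - cl[1, 2])^2 > excludeHeadRadiusPx^2
    if (any(keep))
      errs[[fi]] <- .distToPolyline(pts$x[keep], pts$y[keep],
                                    cl[, 1], cl[, 2])
    arcErr[fi] <- abs(max(pts$arcLengthUm) - L) / L
    hv <- headMidpieceVector(pts, referenceArcLengthUm)
    if (hv$valid) thErr[fi] <- hv$thetaDeg
  }
  all <- unlist(errs)
  thErrSeries <- .wrapDeg180(.unwrapDeg(thErr) - thTrue[seq_len(nf)])
  list(
    rmsCenterlinePx = if (length(all)) sqrt(mean(all^2)) else NA_real_,
    arcLengthRelErr = mean(arcErr, na.rm = TRUE),
    thetaRmsDeg = sqrt(mean(thErrSeries^2, na.rm = TRUE)),
    perFrameRms = vapply(errs, function(e)
      if (length(e)) sqrt(mean(e^2)) else NA_real_, numeric(1)))
}
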