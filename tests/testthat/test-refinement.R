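test_that("tangents and normals follow the curve and its ends", {
  # straight horizontal list
  st <- computeTangentsNormals(data.frame(x = 0:20, y = 5), 14)
  expect_true(all(st$tx == 1 & st$ty == 0))
  expect_true(all(st$nx == 0 & st$ny == 1))
  # quarter circle: tangents within 2 degrees of the analytic direction
  th <- seq(0, pi / 2, length.out = 200)
  ct <- computeTangentsNormals(data.frame(x = 50 * cos(th),
                                          y = 50 * sin(th)), 14)
  i <- 20:180
  dotp <- pmin(1, abs(ct$tx[i] * (-sin(th[i])) + ct$ty[i] * cos(th[i])))
  expect_lt(max(acos(dotp)) * 180 / pi, 2)
  # first point uses the one-sided forward secant
  k <- 7
  v <- c(ct$tx[1], ct$ty[1])
  w <- c(50 * cos(th[1 + k]) - 50, 50 * sin(th[1 + k]))
  expect_equal(v / sqrt(sum(v^2)), w / sqrt(sum(w^2)), tolerance = 1e-12)
})

test_that("normal profiles are bilinear and hit the rendered tube center", {
  fr <- matrix(0, 10, 10)
  fr[5, 5] <- 80   # value at 0-based (4, 4)
  expect_equal(flagellaR:::.bilinear(fr, 4, 4), 80)
  # midpoint of 4 pixels valued 0,0,100,100
  fr2 <- matrix(0, 4, 4); fr2[3, 2:3] <- 100   # rows y=2 high, y=1 low
  expect_equal(flagellaR:::.bilinear(fr2, 1.5, 1.5), 50)
  # profile across a rendered Gaussian tube
  p <- synthParams(nFrames = 2, fps = 64, width = 120, height = 120,
                   lengthUm = 40, beatHz = 11, waveAmpRad = 0,
                   tubeSigmaPx = c(2, 2), tubeIntensity = 100,
                   headIntensity = 0, background = 0, tipFadeUm = 0)
  m <- renderMovie(p, seed = 1)
  fr3 <- frames(m$stack)[, , 1]
  cl <- m$truth$centerlines[[1]]
  mid <- which.min(abs(m$truth$sGridUm - 20))
  prof <- sampleNormalProfile(fr3, cl[mid, 1], cl[mid, 2], 0, 1,
                              5, 0.55, smooth = FALSE)
  expect_false(attr(prof, "truncated"))
  expect_equal(nrow(prof), 2 * round(5 / 0.55) + 1)
  expect_lt(abs(max(prof$value) - 100) / 100, 0.02)
  # the profile maximum sits within half a sample of the true center
  expect_lte(abs(prof$offset[which.max(prof$value)]), 0.5)
  # truncation at the frame edge
  pe <- sampleNormalProfile(fr3, 2, 2, 0, 1, 5, 0.55)
  expect_true(attr(pe, "truncated"))
})

test_that("Gaussian profile fits recover exact parameters and reject
           non-peaks", {
  x <- -9:9
  y <- 2 + 120 * exp(-(x - 0.7)^2 / (2 * 1.8^2))
  f <- fitGaussianProfile(data.frame(offset = x, value = y), 9)
  expect_true(f$accepted)
  expect_equal(f$fitBaseline, 2, tolerance = 1e-3)
  expect_equal(f$fitA, 120, tolerance = 1e-3 * 120)
  expect_equal(f$fitC, 0.7, tolerance = 1e-3)
  expect_equal(f$fitD, 1.8, tolerance = 1e-3 * 1.8)
  # agreement with an independent Levenberg-Marquardt implementation
  set.seed(5)
  yn <- y + rnorm(19, 0, 4)
  f2 <- fitGaussianProfile(data.frame(offset = x, value = yn), 9)
  nl <- minpack.lm::nls.lm(
    par = list(b = min(yn), a = max(yn) - min(yn),
               c = x[which.max(yn)], d = 4.5),
    fn = function(p) yn - (p$b + p$a * exp(-(x - p$c)^2 / (2 * p$d^2))))
  expect_equal(f2$fitA, nl$par$a, tolerance = 1e-6)
  expect_equal(f2$fitC, nl$par$c, tolerance = 1e-6)
  expect_equal(f2$fitD, abs(nl$par$d), tolerance = 1e-6)
  # pure-noise profiles are rejected via the r2 criterion
  rej <- 0
  for (k in 1:100) {
    fp <- fitGaussianProfile(data.frame(offset = x,
                                        value = rnorm(19, 50, 10)), 9)
    if (!fp$accepted) rej <- rej + 1
  }
  expect_gte(rej, 95)
  # a negative-amplitude dip fails the a > 0 criterion
  fd <- fitGaussianProfile(data.frame(offset = x,
                                      value = 100 - 80 * exp(-x^2 / 8)), 9)
  expect_false(fd$accepted)
  expect_lte(fd$fitA, 0)
  # too-short profiles are skipped
  expect_false(fitGaussianProfile(data.frame(offset = -1:1,
                                             value = c(1, 5, 1)), 9)$accepted)
})

test_that("center correction shifts accepted points along their normals", {
  pts <- data.frame(x = c(10, 11, 12), y = c(10, 10, 10),
                    tx = 1, ty = 0, nx = 0, ny = 1,
                    fitA = 5, fitC = c(0, 1.4, 2), fitD = 1, fitR2 = 0.99,
                    fitBaseline = 0, accepted = c(TRUE, TRUE, FALSE))
  s <- mouseQuick(excludeHeadFromCorrection = FALSE)
  out <- centerCorrect(pts, s)
  expect_equal(out$y, c(10, 11.4, 10))   # c=0 identity; rejected untouched
  # head exemption: points within 8 px of p1 stay put
  s2 <- mouseQuick(excludeHeadFromCorrection = TRUE)
  out2 <- centerCorrect(pts, s2)
  expect_equal(out2$y, c(10, 10, 10))
})

test_that("outlier removal drops stragglers but not equally spaced points", {
  tri <- data.frame(x = c(0, 5, 6), y = 0)
  out <- removeOutliers(tri)
  expect_equal(out$x, c(0, 6))
  eq <- data.frame(x = seq(0, 10, by = 2), y = 0)
  expect_equal(removeOutliers(eq)$x, eq$x)
  # injected off-curve stragglers: an off-curve point inflates both its
  # adjacent gaps about equally, so the triplet rule removes the point
  # where the polyline lands after the jump; the stragglers themselves are
  # then flattened onto the curve by the median-projection smoother
  n <- 200
  pts <- data.frame(x = seq(0, 60, length.out = n),
                    y = sin(seq(0, 3, length.out = n)) * 10)
  bad <- c(50, 120, 180)
  pts$y[bad] <- pts$y[bad] + c(4, -5, 4.5)
  out2 <- removeOutliers(pts, tolerance = 0.5)
  removedIdx <- which(!(round(pts$x, 9) %in% round(out2$x, 9)))
  expect_setequal(removedIdx, bad + 1)
  sm <- smoothXY(out2, 15)
  resid <- abs(sm$y - sin(sm$x / 60 * 3) * 10)
  expect_lt(max(resid), 0.2)
})

test_that("median-projection smoothing flattens jitter and keeps lines
           fixed", {
  line <- data.frame(x = seq(0, 30, by = 1), y = 2)
  sm <- smoothXY(line, 5)
  expect_equal(sm$x, line$x, tolerance = 1e-12)
  expect_equal(sm$y, line$y, tolerance = 1e-12)
  # a single 1-px offset collapses below 0.2 px
  off <- line; off$y[15] <- 3
  sm2 <- smoothXY(off, 5)
  expect_lt(abs(sm2$y[15] - 2), 0.2)
})

test_that("arc lengths accumulate Euclidean steps in micrometres", {
  px <- data.frame(x = 0:10, y = 0)
  out <- computeArcLengths(px, 0.55)
  expect_equal(out$arcLengthUm, 0.55 * (0:10))
  # quarter circle at 0.5 px sampling within 0.5% of the analytic length
  th <- seq(0, pi / 2, length.out = ceiling(pi / 2 * 20 / 0.5))
  qc <- computeArcLengths(data.frame(x = 20 * cos(th), y = 20 * sin(th)),
                          0.55)
  expect_lt(abs(max(qc$arcLengthUm) - pi / 2 * 20 * 0.55) /
              (pi / 2 * 20 * 0.55), 0.005)
  # single segment
  seg <- computeArcLengths(data.frame(x = c(0, 3), y = 0), 0.7)
  expect_equal(seg$arcLengthUm, c(0, 2.1))
  # coincident consecutive points are merged
  dup <- computeArcLengths(data.frame(x = c(0, 1, 1, 2), y = 0), 1)
  expect_equal(nrow(dup), 3)
  expect_true(all(diff(dup$arcLengthUm) > 0))
})

test_that("z-width smoothing removes spikes and respects the arc cutoff", {
  n <- 60
  pts <- data.frame(x = seq(0, 30, length.out = n), y = 0)
  pts <- computeArcLengths(pts, 1)
  pts$fitD <- seq(2, 4, length.out = n)
  outC <- smoothZWidths(transform(pts, fitD = 3), 9.6, 15)
  expect_equal(outC$zWidth, rep(3, n), tolerance = 1e-12)
  spk <- pts; spk$fitD[30] <- spk$fitD[30] + 2
  out <- smoothZWidths(spk, 9.6, 15)
  expect_lte(abs(out$zWidth[30] - pts$fitD[30]), 0.2 * 2)
  # zero arc-distance limit: no eligible neighbours, unchanged
  out0 <- smoothZWidths(spk, 0, 15)
  expect_equal(out0$zWidth, spk$fitD)
})

test_that("full two-pass refinement reaches sub-pixel accuracy and the
           second pass does not degrade the first", {
  m <- beatMovie64()
  s <- mouseQuick()
  fr <- frames(m$stack)[, , 7]
  rough <- roughTraceFrame(fr, s)
  up <- upscalePointList(rough, 3)
  tr <- refineTrace(fr, up, s, pixelSize(m$stack), 7)
  pts <- tracePoints(tr)
  cl <- m$truth$centerlines[[7]]
  keep <- pts$accepted &
    (pts$x - cl[1, 1])^2 + (pts$y - cl[1, 2])^2 > 64
  d2 <- flagellaR:::.distToPolyline(pts$x[keep], pts$y[keep],
                                    cl[, 1], cl[, 2])
  expect_lt(sqrt(mean(d2^2)), 0.2)
  # the rough trace is strictly worse than the refined one
  roughKeep <- (up$x - cl[1, 1])^2 + (up$y - cl[1, 2])^2 > 64
  dRough <- flagellaR:::.distToPolyline(up$x[roughKeep], up$y[roughKeep],
                                        cl[, 1], cl[, 2])
  expect_gt(sqrt(mean(dRough^2)), sqrt(mean(d2^2)))
  # arc-length metric fidelity: the trace's arc difference between two
  # interior anchors equals their true arc separation within 2%. (The
  # trace's TOTAL length exceeds the centerline's by the drawn tube's end
  # caps and the head blob's backward skeleton, so totals are only a
  # loose check.)
  pr2 <- projectOnPolyline(pts$x, pts$y, cl[, 1], cl[, 2],
                           m$truth$sGridUm)
  i5 <- which.min(abs(pr2$arc - 5)); i45 <- which.min(abs(pr2$arc - 45))
  span <- pts$arcLengthUm[i45] - pts$arcLengthUm[i5]
  trueSpan <- pr2$arc[i45] - pr2$arc[i5]
  expect_lt(abs(span - trueSpan) / trueSpan, 0.02)
  expect_lt(abs(max(pts$arcLengthUm) - 50) / 50, 0.05)
  # two-pass contract: the second pass does not degrade the first
  tr1 <- refineTrace(fr, up, s, pixelSize(m$stack), 7, passes = 1)
  p1 <- tracePoints(tr1)
  k1 <- p1$accepted & (p1$x - cl[1, 1])^2 + (p1$y - cl[1, 2])^2 > 64
  dP1 <- flagellaR:::.distToPolyline(p1$x[k1], p1$y[k1], cl[, 1], cl[, 2])
  expect_lte(sqrt(mean(d2^2)), sqrt(mean(dP1^2)) + 1e-9)
})

test_that("smoothed z-widths track a monotone defocus profile", {
  p <- synthParams(nFrames = 2, fps = 64, width = 150, height = 150,
                   lengthUm = 45, beatHz = 11, waveAmpRad = 0.3,
                   tubeSigmaPx = c(1.5, 3))
  m <- renderMovie(p, seed = 12)
  s <- mouseQuick()
  fr <- frames(m$stack)[, , 1]
  tr <- refineTrace(fr, upscalePointList(roughTraceFrame(fr, s), 3), s,
                    pixelSize(m$stack), 1)
  pts <- tracePoints(tr)
  # beyond the head blob's photometric reach (~3 sigma of its long axis),
  # where the normal profiles sample the tube alone
  sel <- pts$accepted & pts$arcLengthUm > 8 & pts$arcLengthUm < 42 &
    is.finite(pts$zWidth)
  rho <- cor(pts$arcLengthUm[sel], pts$zWidth[sel], method = "spearman")
  expect_gt(rho, 0.95)
})
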