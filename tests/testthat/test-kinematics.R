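test_that("the head-midpiece vector and Theta follow the documented sign
           convention", {
  tr <- data.frame(x = c(0, 5, 10), y = c(0, 0, 0))
  tr <- computeArcLengths(computeTangentsNormals(tr, 2), 1)
  hv <- headMidpieceVector(tr, 10)
  expect_true(hv$valid)
  expect_equal(hv$thetaDeg, 0)
  # reference point below the head (y-down) gives -90 degrees
  trDown <- data.frame(x = c(0, 0, 0), y = c(0, 5, 10))
  trDown <- computeArcLengths(computeTangentsNormals(trDown, 2), 1)
  expect_equal(headMidpieceVector(trDown, 10)$thetaDeg, -90)
  # trace shorter than the reference arc length is flagged
  expect_false(headMidpieceVector(tr, 50)$valid)
})

test_that("head-frame transform maps the head to the origin and the
           reference onto +x", {
  th <- seq(0, 1, length.out = 80)
  pts <- data.frame(x = 30 * cos(th), y = 30 * sin(th))
  pts <- computeArcLengths(computeTangentsNormals(pts, 6), 0.55)
  hv <- headMidpieceVector(pts, 10)
  hf <- transformToHeadFrame(pts, hv$v, 0.55)
  expect_equal(hf$xHeadUm[1], 0, tolerance = 1e-9)
  expect_equal(hf$yHeadUm[1], 0, tolerance = 1e-9)
  iRef <- which.min(abs(pts$arcLengthUm - 10))
  expect_equal(hf$xHeadUm[iRef], sqrt(sum(hv$v^2)) * 0.55,
               tolerance = 1e-6)
  expect_equal(hf$yHeadUm[iRef], 0, tolerance = 1e-6)
})

test_that("tangential angles are continuous, analytic and equivariant", {
  st <- straightTrace(0)
  expect_equal(tangentialAngle(st), rep(0, nrow(st)))
  # quarter circle sweeps 90 degrees
  qc <- circleTrace(20, pi / 2)
  ta <- tangentialAngle(qc)
  expect_lt(abs(abs(ta[length(ta)] - ta[1]) - 90), 2)
  # rotating the trace shifts all angles by the rotation
  a30 <- straightTrace(30)
  expect_equal(tangentialAngle(a30), rep(30, nrow(a30)), tolerance = 1e-9)
})

test_that("curvature equals 1/R on circles with the right sign and
           parity", {
  st <- straightTrace(0)
  expect_true(all(abs(curvatureSeries(st, 10)) < 1e-12))
  circ <- circleTrace(20, pi)
  kap <- curvatureSeries(circ, 10)
  interior <- 100:500
  expect_lt(max(abs(abs(kap[interior]) - 0.05)) / 0.05, 0.03)
  # mirroring flips the sign
  mir <- circleTrace(20, pi, clockwiseOnScreen = FALSE)
  expect_equal(curvatureSeries(mir, 10)[300], -kap[300], tolerance = 1e-9)
})

test_that("curvature angle matches the analytic arc geometry and the
           curvature internally", {
  st <- straightTrace(0)
  expect_true(all(abs(curvatureAngleSeries(st, 10)) < 1e-12))
  circ <- circleTrace(20, pi)
  cA <- curvatureAngleSeries(circ, 10)
  # |cA| = Q/R rad = 28.65 deg on the interior
  i <- 300
  expect_lt(abs(abs(cA[i]) - 10 / 20 * 180 / pi) / (10 / 20 * 180 / pi),
            0.02)
  # internal consistency: kappa * Q equals cA in radians (1%)
  kap <- curvatureSeries(circ, 10)
  expect_lt(abs(kap[i] * 10 - cA[i] * pi / 180) / abs(cA[i] * pi / 180),
            0.01)
  # proximal points use shortened upstream support and stay defined
  expect_true(all(is.finite(cA)))
})

test_that("the head rolling signal takes the cross-line maximum", {
  fr <- matrix(30, 60, 60)
  expect_equal(as.numeric(headRollingSignal(fr, c(30, 30), c(10, 0), 10)),
               30)
  # bright spot 4 px off the head along the cross-line (v = (0,10) makes
  # the cross-line horizontal)
  fr[31, 35] <- 150
  got <- headRollingSignal(fr, c(30, 30), c(0, 10), 10)
  expect_gte(as.numeric(got), 0.9 * 150 / 9 + 30 * 8 / 9 - 1)
  # thickness averaging: a full-thickness stripe returns its value
  fr2 <- matrix(30, 60, 60)
  fr2[, 35] <- 150
  expect_equal(as.numeric(headRollingSignal(fr2, c(30, 30), c(0, 10), 10)),
               150)
  # truncation flag when the line leaves the frame
  t1 <- headRollingSignal(fr, c(2, 2), c(0, 10), 10)
  expect_true(attr(t1, "truncated"))
})

test_that("Theta unwrapping keeps frame-to-frame steps below 180 deg", {
  th <- c(170, 179, -178, -170, -179, 178)
  un <- thetaSeries(th)
  expect_true(all(abs(diff(un)) < 180))
  expect_equal(un[3], 182)
  # NA frames pass through
  un2 <- thetaSeries(c(10, NA, 20))
  expect_true(is.na(un2[2]))
})

test_that("kinematics are invariant to translation and equivariant to
           rotation", {
  th <- seq(0, 2, length.out = 300)
  base <- data.frame(x = 40 * cos(th) + 10, y = 40 * sin(th) + 5)
  mk <- function(df) computeArcLengths(computeTangentsNormals(df, 6), 0.55)
  t0 <- mk(base)
  tTrans <- mk(transform(base, x = x + 13.7, y = y - 4.2))
  expect_equal(curvatureSeries(tTrans, 10), curvatureSeries(t0, 10),
               tolerance = 1e-9)
  expect_equal(curvatureAngleSeries(tTrans, 10),
               curvatureAngleSeries(t0, 10), tolerance = 1e-9)
  expect_equal(headMidpieceVector(tTrans, 10)$thetaDeg,
               headMidpieceVector(t0, 10)$thetaDeg, tolerance = 1e-9)
  # proper rotation by 40 degrees: kappa and cA unchanged, Theta shifted
  a <- 40 * pi / 180
  rot <- data.frame(x = cos(a) * base$x + sin(a) * base$y,
                    y = -sin(a) * base$x + cos(a) * base$y)
  tRot <- mk(rot)
  expect_equal(curvatureSeries(tRot, 10), curvatureSeries(t0, 10),
               tolerance = 1e-6)
  expect_equal(flagellaR:::.wrapDeg180(
    headMidpieceVector(tRot, 10)$thetaDeg -
      headMidpieceVector(t0, 10)$thetaDeg), 40, tolerance = 1e-6)
  # head-frame y is invariant to both
  hv0 <- headMidpieceVector(t0, 10)
  hvR <- headMidpieceVector(tRot, 10)
  expect_equal(transformToHeadFrame(tRot, hvR$v, 0.55)$yHeadUm,
               transformToHeadFrame(t0, hv0$v, 0.55)$yHeadUm,
               tolerance = 1e-6)
})
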