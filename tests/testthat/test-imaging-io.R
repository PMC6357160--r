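test_that("TIFF stacks round-trip with calibration and raw intensity scale", {
  arr <- array(0, c(32, 48, 3))
  arr[5, 7, ] <- c(1000, 40000, 123)
  arr[20, 30, ] <- 7
  st <- imageStack(arr, fps = 200, pixelSize = 0.6875, bitDepth = 16)
  path <- tempfile(fileext = ".tif")
  writeImageStack(st, path)
  rt <- readImageStack(path, fps = 200, pixelSize = 0.6875)
  expect_equal(nFrames(rt), 3)
  expect_equal(dim(frames(rt))[1:2], c(32, 48))
  expect_equal(fps(rt), 200)
  expect_equal(pixelSize(rt), 0.6875)
  # 16-bit values preserved exactly, no rescaling
  expect_equal(frames(rt)[5, 7, 2], 40000)
  expect_equal(frames(rt)[20, 30, 1], 7)
})

test_that("single-frame and RGB input are rejected", {
  path <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 8, 8), path)
  expect_error(readImageStack(path, 100, 0.5), "at least 2 frames")
  rgb <- array(0.3, c(8, 8, 3))
  pathRgb <- tempfile(fileext = ".tif")
  tiff::writeTIFF(list(rgb, rgb), pathRgb)
  expect_error(readImageStack(pathRgb, 100, 0.5), "RGB")
})

test_that("min projection subtraction removes the static background", {
  # constant stack -> all zero
  cst <- imageStack(list(matrix(7, 10, 10), matrix(7, 10, 10)), 100, 0.5)
  expect_true(all(frames(minProjectionSubtract(cst)) == 0))
  # per-pixel time series (5, 9, 5) -> (0, 4, 0)
  arr <- array(5, c(4, 4, 3)); arr[2, 2, ] <- c(5, 9, 5)
  out <- frames(minProjectionSubtract(imageStack(arr, 100, 0.5)))
  expect_equal(out[2, 2, ], c(0, 4, 0))
  expect_true(all(out[1, 1, ] == 0))
  # moving object on constant background: background pixels exactly 0
  p <- synthParams(nFrames = 6, fps = 64, width = 120, height = 120,
                   lengthUm = 40, beatHz = 11, background = 20)
  m <- renderMovie(p, seed = 1)
  corr <- frames(minProjectionSubtract(m$stack))
  far <- corr[1:10, 1:10, ]   # corner never touched by the cell
  expect_true(all(far == 0))
  # per-pixel time minimum is exactly zero everywhere
  expect_true(all(apply(corr, c(1, 2), min) == 0))
})

test_that("rolling-ball background subtraction matches its definition", {
  # flat frame fully removed
  u <- imageStack(list(matrix(50, 40, 40), matrix(50, 40, 40)), 100, 0.5)
  expect_true(all(frames(rollingBallSubtract(u, 10)) <= 1))
  # single bright pixel retains >= 90% of its value
  sp <- matrix(0, 40, 40); sp[20, 20] <- 100
  rs <- rollingBallSubtract(imageStack(list(sp, sp), 100, 0.5), 10)
  expect_gte(frames(rs)[20, 20, 1], 90)
  # direct-definition oracle (independent double-loop erosion/dilation)
  set.seed(31)
  fr <- matrix(runif(625, 0, 50), 25, 25)
  oracleBg <- function(I, r) {
    els <- expand.grid(dx = -r:r, dy = -r:r)
    els <- els[els$dx^2 + els$dy^2 <= r^2, ]
    els$g <- sqrt(r^2 - els$dx^2 - els$dy^2) - r
    nr <- nrow(I); nc <- ncol(I)
    E <- matrix(NA_real_, nr, nc); B <- matrix(NA_real_, nr, nc)
    for (i in 1:nr) for (j in 1:nc) {
      v <- Inf
      for (k in seq_len(nrow(els))) {
        ii <- i + els$dy[k]; jj <- j + els$dx[k]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
          v <- min(v, I[ii, jj] - els$g[k])
      }
      E[i, j] <- v
    }
    for (i in 1:nr) for (j in 1:nc) {
      v <- -Inf
      for (k in seq_len(nrow(els))) {
        ii <- i - els$dy[k]; jj <- j - els$dx[k]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
          v <- max(v, E[ii, jj] + els$g[k])
      }
      B[i, j] <- v
    }
    B
  }
  got <- rollingBallSubtract(imageStack(list(fr, fr), 100, 0.5), 6)
  want <- pmax(fr - oracleBg(fr, 6), 0)
  expect_lt(max(abs(frames(got)[, , 1] - want)), 1)
  # broad hill mostly removed, thin ridge preserved
  xg <- matrix(rep(1:80, each = 80), 80); yg <- t(xg)
  hill <- 100 * exp(-((xg - 40)^2 + (yg - 40)^2) / (2 * 40^2))
  ridge <- hill; ridge[40:41, ] <- ridge[40:41, ] + 60
  rr <- frames(rollingBallSubtract(imageStack(list(ridge, ridge), 100, 0.5),
                                   10))[, , 1]
  expect_gte(1 - max(rr[30, ]) / max(hill), 0.8)
  ridgeContrast <- rr[40, 40] - rr[30, 40]
  expect_lt(abs(ridgeContrast - 60) / 60, 0.1)
  # radius validation
  expect_error(rollingBallSubtract(u, 100), "shorter image side")
})

test_that("corrections are idempotent on zero-background data and never
           increase intensities", {
  p <- synthParams(nFrames = 4, fps = 64, width = 100, height = 100,
                   lengthUm = 30, beatHz = 11, background = 0,
                   headIntensity = 0)
  m <- renderMovie(p, seed = 2)
  a1 <- frames(minProjectionSubtract(m$stack))
  # a zero-background moving object: background already 0, object untouched
  # except where the time-minimum is nonzero (overlap region of all frames)
  expect_true(all(a1 <= frames(m$stack) + 1e-12))
  still <- imageStack(list(frames(m$stack)[, , 1], frames(m$stack)[, , 1] * 0),
                      64, 0.55)
  expect_true(all(abs(frames(minProjectionSubtract(still)) -
                        frames(still)) <= 1))
  # rolling ball: near-impulse structures are untouched to within 1 unit
  sp <- matrix(0, 60, 60); sp[30, 30] <- 100; sp[12, 45] <- 60
  spStack <- imageStack(list(sp, sp), 64, 0.55)
  rbSp <- rollingBallSubtract(spStack, 10)
  expect_true(all(abs(frames(rbSp) - frames(spStack)) <= 1))
  # on a smooth Gaussian tube the top-hat residual legitimately skims a
  # few percent per pass (the ball reaches slightly up under any smooth
  # ridge); the second pass changes nothing beyond that skim
  rb <- rollingBallSubtract(m$stack, 10)
  expect_true(all(frames(rb) <= frames(m$stack) + 1e-12))
  rb2 <- rollingBallSubtract(rb, 10)
  expect_true(all(abs(frames(rb2) - frames(rb)) <= 0.03 * max(frames(rb))))
})

test_that("settings profiles round-trip through YAML and JSON", {
  s <- humanSettings(gaussSigma = 2.5, fftWindowFrames = 300)
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    writeSettings(s, path)
    s2 <- readSettings(path)
    for (sl in slotNames(s)) expect_equal(slot(s2, sl), slot(s, sl))
  }
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(no_such_setting = 1), bad)
  expect_error(readSettings(bad), "unknown settings key")
})

test_that("ROI masks cover rectangles and polygons", {
  m <- roiMask(c(20, 30), rectangle = c(5, 2, 10, 4))
  expect_equal(sum(m), 40)
  expect_true(m[3, 6] && m[6, 15] && !m[7, 6] && !m[3, 16])
  tri <- roiMask(c(20, 20), polygon = list(x = c(0, 19, 0), y = c(0, 0, 19)))
  expect_true(tri[1, 1] && !tri[20, 20])
  expect_error(roiMask(c(10, 10)), "supply one")
})
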