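test_that("amplitude spectra recover exact-bin sinusoids", {
  t <- (0:199) / 200
  sp <- amplitudeSpectrum(3 * sin(2 * pi * 11 * t), 200)
  f <- spectrumFrequencies(sp); a <- spectrumAmplitudes(sp)
  expect_equal(max(f), 100)                     # Nyquist bound fps/2
  expect_equal(f[2] - f[1], 1)                  # spacing fps/W
  expect_equal(f[which.max(a)], 11)
  expect_equal(max(a), 3, tolerance = 1e-9)
  expect_lt(max(a[f != 11]) / max(a), 1e-6)
  # constant signal: all amplitudes zero after mean subtraction
  expect_true(all(spectrumAmplitudes(amplitudeSpectrum(rep(5, 64), 64))
                  < 1e-12))
  # two sines 9 + 27 Hz with 2:1 amplitudes at 500 fps
  t5 <- (0:499) / 500
  sp2 <- amplitudeSpectrum(2 * sin(2 * pi * 9 * t5) +
                             sin(2 * pi * 27 * t5), 500)
  a2 <- spectrumAmplitudes(sp2); f2 <- spectrumFrequencies(sp2)
  expect_equal(a2[f2 == 9] / a2[f2 == 27], 2, tolerance = 1e-3)
})

test_that("missing frames are interpolated up to 10% and rejected beyond", {
  t <- (0:99) / 100
  x <- sin(2 * pi * 10 * t)
  x[c(20, 45, 80)] <- NA
  sp <- amplitudeSpectrum(x, 100)
  expect_equal(spectrumFrequencies(sp)[which.max(spectrumAmplitudes(sp))],
               10)
  x2 <- x; x2[1:15] <- NA
  expect_error(amplitudeSpectrum(x2, 100), "10%")
})

test_that("sliding windows count positions at stride 1 and track a chirp", {
  x <- rnorm(500)
  expect_length(slidingWindowSpectra(x, 500, 500), 1)
  expect_length(slidingWindowSpectra(x[1:300], 200, 500), 101)
  expect_error(slidingWindowSpectra(x[1:100], 200, 500), "window")
  # chirp 8 -> 14 Hz over 1000 frames: per-window primary non-decreasing
  n <- 1000; fs <- 200
  tt <- (0:(n - 1)) / fs
  f0 <- 8; f1 <- 14
  phase <- 2 * pi * (f0 * tt + (f1 - f0) / (2 * max(tt)) * tt^2)
  chirp <- sin(phase)
  spl <- slidingWindowSpectra(chirp, 200, fs)
  prim <- vapply(spl[seq(1, length(spl), by = 40)], function(s)
    findPrimarySecondary(s)$primaryHz, numeric(1))
  expect_true(all(diff(prim) >= 0))
  expect_gte(prim[length(prim)], prim[1] + 4)
})

test_that("primary/secondary peaks respect local maxima, adjacency and
           ties", {
  mkSpec <- function(a, fps = 100)
    new("Spectrum", frequencies = seq_along(a) * fps / (2 * length(a)),
        amplitudes = a, windowLength = 2 * length(a), windowStart = 1,
        fps = fps)
  # isolated peaks at 11 and 23 Hz (23 smaller)
  a <- rep(0.1, 50); a[11] <- 5; a[23] <- 3
  s <- findPrimarySecondary(mkSpec(a))
  expect_equal(s$primaryHz, 11)
  expect_equal(s$secondaryHz, 23)
  # single peak: secondary missing
  a2 <- rep(0.1, 50); a2[20] <- 4
  s2 <- findPrimarySecondary(mkSpec(a2))
  expect_equal(s2$primaryHz, 20)
  expect_true(is.na(s2$secondaryHz))
  # equal peaks at 10 and 20 Hz: tie goes to the lower frequency
  a3 <- rep(0.1, 50); a3[c(10, 20)] <- 4
  s3 <- findPrimarySecondary(mkSpec(a3))
  expect_equal(s3$primaryHz, 10)
  expect_equal(s3$secondaryHz, 20)
  # a leakage shoulder next to the primary is larger than the distant peak
  # but is no local maximum, so the distant peak is the secondary
  a4 <- rep(0, 50); a4[20] <- 5; a4[21] <- 3; a4[35] <- 1
  s4 <- findPrimarySecondary(mkSpec(a4))
  expect_equal(s4$primaryHz, 20)
  expect_equal(s4$secondaryHz, 35)
  # monotone spectrum: global max as primary, no secondary
  s5 <- findPrimarySecondary(mkSpec(seq(0.1, 1, length.out = 30)))
  expect_equal(s5$primaryHz, 30 * 100 / 60)
  expect_true(is.na(s5$secondaryHz))
})

test_that("the spectrum center-of-mass is the amplitude-weighted mean
           frequency", {
  mk <- function(f, a, fps = 250)
    new("Spectrum", frequencies = f, amplitudes = a,
        windowLength = 2 * length(f), windowStart = 1, fps = fps)
  expect_equal(spectrumCom(mk(c(5, 11, 30), c(0, 7, 0))), 11)
  expect_equal(spectrumCom(mk(c(10, 20), c(1, 1), fps = 40)), 15)
  expect_equal(spectrumCom(mk(1:100, rep(2, 100))), 50.5)
  expect_true(is.na(spectrumCom(mk(c(1, 2), c(0, 0)))))
  # COM is bounded by the analyzed frequencies
  set.seed(3)
  for (k in 1:20) {
    a <- runif(40)
    sp <- mk(1:40, a, fps = 80)
    expect_gte(spectrumCom(sp), 1)
    expect_lte(spectrumCom(sp), 40)
  }
})

test_that("Parseval: one-sided amplitudes carry the signal variance", {
  set.seed(4)
  for (k in 1:5) {
    W <- 101   # odd length: no Nyquist bin, the 2/W relation is exact
    x <- rnorm(W)
    sp <- amplitudeSpectrum(x, 100)
    ss <- sum((x - mean(x))^2)
    expect_lt(abs(sum(spectrumAmplitudes(sp)^2) - 2 * ss / W) /
                (2 * ss / W), 1e-6)
  }
})

test_that("the flagellar frequency map analyzes rows beyond the skip
           length", {
  # synthetic kymograph: rows oscillate at 7 Hz, distal rows add 14 Hz
  fps <- 64; nf <- 64
  tt <- (0:(nf - 1)) / fps
  nb <- 30
  vals <- matrix(NA_real_, nb, nf)
  for (r in 1:nb) {
    vals[r, ] <- 20 * sin(2 * pi * 7 * tt + r / 5) +
      if (r > 24) 8 * sin(2 * pi * 14 * tt) else 0
  }
  k <- new("Kymograph", parameter = "curvatureAngleDeg", values = vals,
           mask = matrix(FALSE, nb, nf),
           binEdges = seq(0, nb), times = tt)
  fm <- flagellarFrequencyMap(k, fps, skipInitialUm = 3)
  expect_true(all(fm$arcLengthUm > 3))
  expect_equal(nrow(fm), sum(seq(0.5, nb - 0.5) > 3))
  expect_true(all(fm$primaryHz == 7))
  expect_true(all(fm$secondaryHz[fm$arcLengthUm > 25] == 14))
  # proximal rows are pure sinusoids: any secondary is numerical noise
  prox <- fm[fm$arcLengthUm < 24, ]
  expect_true(all(is.na(prox$secondaryHz) | prox$secondaryAmp < 1e-6))
  expect_error(flagellarFrequencyMap(k, fps, skipInitialUm = 50),
               "skipped")
})
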