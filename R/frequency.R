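# Fill missing values by linear interpolation; error above the tolerance.
.fillMissing <- function(signal, maxMissingFrac = 0.1) {
  bad <- which(!is.finite(signal))
  if (!length(bad)) return(signal)
  if (length(bad) / length(signal) > maxMissingFrac)
    stop("more than 10% of frames failed: frames ",
         paste(utils::head(bad, 20), collapse = ", "),
         if (length(bad) > 20) ", ..." else "")
  ok <- which(is.finite(signal))
  if (length(ok) < 2) stop("not enough valid frames to interpolate")
  signal[bad] <- stats::approx(ok, signal[ok], xout = bad, rule = 2)$y
  signal
}

#' One-sided amplitude spectrum of a time signal
#'
#' Discrete Fourier amplitude spectrum of the mean-subtracted signal with a
#' rectangular window and `2/W` one-sided normalization; the DC bin is
#' excluded, so bins sit at `k * fps / W`, `k = 1..floor(W/2)`. Up to 10%
#' missing values (failed frames) are filled by linear interpolation;
#' more raise an error listing the failed frames.
#'
#' @param signal numeric vector (length >= 2).
#' @param fps sampling rate in Hz.
#' @param windowStart 1-based index recorded in the result (bookkeeping for
#'   sliding windows).
#' @return a [Spectrum-class].
#' @export
amplitudeSpectrum <- function(signal, fps, windowStart = 1) {
  W <- length(signal)
  if (W < 2) stop("signal must have at least 2 samples")
  x <- .fillMissing(as.numeric(signal))
  x <- x - mean(x)
  X <- stats::fft(x)
  k <- seq_len(W %/% 2)
  new("Spectrum",
      frequencies = k * fps / W,
      amplitudes = 2 / W * Mod(X[k + 1]),
      windowLength = W,
      windowStart = windowStart,
      fps = fps)
}

#' Sliding-window spectra
#'
#' When the window equals the signal length a single spectrum is returned;
#' otherwise one spectrum per window position at stride 1 (maximal
#' overlap).
#'
#' @param signal numeric vector.
#' @param windowFrames window length in frames (<= signal length).
#' @param fps sampling rate in Hz.
#' @return a list of [Spectrum-class] objects.
#' @export
slidingWindowSpectra <- function(signal, windowFrames, fps) {
  n <- length(signal)
  if (windowFrames > n) stop("window longer than the signal")
  x <- .fillMissing(as.numeric(signal))
  starts <- seq_len(n - windowFrames + 1L)
  lapply(starts, function(s)
    amplitudeSpectrum(x[s:(s + windowFrames - 1L)], fps, windowStart = s))
}

# Indices of strict local maxima; the two outermost bins are eligible with
# a one-sided comparison (so monotone spectra keep their global maximum).
.localMaxima <- function(a) {
  n <- length(a)
  if (n == 1) return(1L)
  leftOk <- c(TRUE, a[-1] > a[-n])
  rightOk <- c(a[-n] > a[-1], TRUE)
  which(leftOk & rightOk)
}

#' Primary and secondary spectral peaks and center-of-mass
#'
#' The primary frequency is the largest local maximum of the amplitude
#' sequence; the secondary frequency is the second-largest local maximum at
#' a bin not adjacent (at least 2 bins away) to the primary, so
#' spectral-leakage shoulders cannot masquerade as a second peak. Ties go
#' to the lower frequency. A spectrum without local maxima falls back to
#' the global maximum as primary with the secondary missing. The
#' center-of-mass is the amplitude-weighted mean frequency over all
#' (non-DC) bins; it summarizes the distribution and amplitude of all
#' frequency peaks.
#'
#' @param spectrum a [Spectrum-class] (>= 3 bins for peak analysis).
#' @return a one-row data.frame with `primaryHz`, `secondaryHz`, `comHz`,
#'   `primaryAmp`, `secondaryAmp`, `windowStart`.
#' @export
findPrimarySecondary <- function(spectrum) {
  f <- spectrum@frequencies
  a <- spectrum@amplitudes
  if (length(a) < 3) stop("at least 3 spectral bins required")
  lm <- .localMaxima(a)
  res <- data.frame(primaryHz = NA_real_, secondaryHz = NA_real_,
                    comHz = spectrumCom(spectrum),
                    primaryAmp = NA_real_, secondaryAmp = NA_real_,
                    windowStart = spectrum@windowStart)
  if (!length(lm)) {
    p <- which.max(a)
    res$primaryHz <- f[p]; res$primaryAmp <- a[p]
    return(res)
  }
  ordLm <- lm[order(-a[lm], f[lm])]
  p <- ordLm[1]
  res$primaryHz <- f[p]; res$primaryAmp <- a[p]
  sec <- ordLm[abs(ordLm - p) > 1]
  if (length(sec)) {
    s <- sec[1]
    res$secondaryHz <- f[s]; res$secondaryAmp <- a[s]
  }
  res
}

#' Center-of-mass of an amplitude spectrum
#'
#' Amplitude-weighted mean frequency over all non-DC bins; `NA` when the
#' total amplitude is zero.
#'
#' @param spectrum a [Spectrum-class].
#' @return the center-of-mass frequency in Hz.
#' @export
spectrumCom <- function(spectrum) {
  a <- spectrum@amplitudes
  if (sum(a) <= 0) return(NA_real_)
  sum(spectrum@frequencies * a) / sum(a)
}

#' Frequency analysis of every arc-length bin of a kymograph
#'
#' Each arc-length row with bin-center arc length strictly above
#' `skipInitialUm` is analyzed independently: amplitude spectrum of the
#' row's time series, then primary/secondary peaks and center-of-mass.
#' Rows with more than 10% missing frames yield `NA` summaries; if every
#' row is skipped an error is raised.
#'
#' @param kymo a [Kymograph-class].
#' @param fps sampling rate in Hz.
#' @param skipInitialUm skip rows with arc length at or below this value.
#' @param windowFrames optional window length; defaults to the full series.
#' @return a data.frame with one row per analyzed arc-length bin:
#'   `arcLengthUm`, `primaryHz`, `secondaryHz`, `comHz`, `primaryAmp`,
#'   `secondaryAmp`. With a window shorter than the series, one row per
#'   (bin, window) combination, keyed by `windowStart`.
#' @export
flagellarFrequencyMap <- function(kymo, fps, skipInitialUm = 0,
                                  windowFrames = NULL) {
  centers <- arcBinCenters(kymo)
  rows <- which(centers > skipInitialUm)
  if (!length(rows)) stop("all arc-length rows skipped")
  vals <- kymo@values
  vals[kymo@mask] <- NA_real_
  if (is.null(windowFrames) || windowFrames >= ncol(vals))
    windowFrames <- ncol(vals)
  out <- lapply(rows, function(r) {
    series <- vals[r, ]
    spl <- try(slidingWindowSpectra(series, windowFrames, fps),
               silent = TRUE)
    if (inherits(spl, "try-error")) {
      return(data.frame(arcLengthUm = centers[r], primaryHz = NA_real_,
                        secondaryHz = NA_real_, comHz = NA_real_,
                        primaryAmp = NA_real_, secondaryAmp = NA_real_,
                        windowStart = 1))
    }
    sm <- do.call(rbind, lapply(spl, findPrimarySecondary))
    cbind(arcLengthUm = centers[r],
          sm[, c("primaryHz", "secondaryHz", "comHz", "primaryAmp",
                 "secondaryAmp", "windowStart")])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
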