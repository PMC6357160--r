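---
title: "Quantifying the flagellar beat: model, parameters and numerical choices"
author: "flagellaR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the flagellar beat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

A beating sperm flagellum is a thin, bright curve moving across a dark
background in a high-speed movie (dark-field or epifluorescence, hundreds
of frames per second). flagellaR reconstructs that curve in every frame to
sub-pixel precision, parameterizes it by arc length, and reduces the movie
to physically meaningful time series: where the head is and how it is
oriented (angle Theta), how strongly the flagellum bends at every position
(curvature and curvature angle), how far each segment sits from the focal
plane (a relative z proxy), and at which frequencies all of these
oscillate.

The pipeline has three stages:

1. **Rough reconstruction** (per frame). Gaussian blur, automatic
   histogram threshold (Li, Triangle or Otsu on a 256-bin histogram
   spanning the frame's min-max range, mirroring 8-bit histogram
   semantics), optionally a second blur of the binary mask (re-binarized
   at 0.5), Zhang-Suen thinning to an 8-connected one-pixel skeleton,
   extraction of a single path (largest component, then the longest
   endpoint-to-endpoint geodesic; side branches are dropped), ordering of
   the pixels along the curve, and head-first orientation by comparing
   mean intensities in radius-8 disks around the two ends (in dark-field
   the head scatters far more light than the tip).

2. **Sub-pixel refinement** (two passes). The point list is upscaled by
   linear interpolation, tangents and normals are computed from k-point
   secants, and the intensity profile along each normal (bilinear
   interpolation at one-pixel steps) is fitted with an offset Gaussian
   `y = baseline + a exp(-(x - c)^2 / (2 d^2))`. Accepted fits (all of:
   r^2 > 0.8, a > 0, d < 2R, |c| < R, with R the normal radius in pixels)
   shift their point by `c` along the normal onto the profile center.
   Outliers are removed, the track is smoothed by median projection (see
   below), arc lengths are accumulated, and the whole fit-correct cycle
   runs a second time. The fitted width `d` becomes the relative z proxy
   (defocused segments appear wider), the fitted height `a` the local
   intensity.

3. **Kinematics and spectra**. The head-midpiece vector (first point to
   the point at a reference arc length) defines Theta and the cell-fixed
   coordinate frame; tangential angle, curvature (angle between tangents
   Q/2 before and after, divided by their arc separation) and curvature
   angle (tangent at s versus tangent at s - Q) describe local bending.
   Every parameter is binned into an arc-length-by-time kymograph, and
   every time series (head-level or per arc bin) gets a rectangular-window
   amplitude spectrum with primary peak, secondary peak and amplitude
   center-of-mass.

## Settings

Every stage is governed by one settings profile (`traceSettings()`;
`mouseSettings()` and `humanSettings()` are the two reference profiles for
tethered mouse cells at 200 fps / 0.6875 um/px and freely swimming human
cells at 500 fps / 0.55 um/px).

| setting | unit | mouse | human | role |
|---|---|---|---|---|
| thresholdMethod | - | Li | Triangle | histogram threshold |
| gaussSigma | px | 3 | 2 | pre-threshold blur |
| repeatGaussAfterBinarization | flag | off | on | soften the mask before thinning |
| blurOnlyInsideRoi | flag | on | off | blur the head, keep the tube sharp |
| upscalingFold | - | 3 | 3 | points inserted per skeleton pixel pair |
| addHeadComFirstPoint | flag | off | off | prepend the head disk's intensity centroid |
| unifyStartPoints | flag | off | off | pin the start to the movie-mean position |
| filterPointsByFits | flag | off | off | drop points with rejected fits (pass 2) |
| maxVectorLengthPoints | points | 14 | 20 | tangent secant support |
| normalRadiusUm | um | 5 | 6 | half-length of each normal profile |
| excludeHeadFromCorrection | flag | on | off | keep head points (within 8 px of the start) on the skeleton |
| smoothNormalProfile | flag | on | on | 3-tap average before fitting |
| zSmoothingArcDistanceUm | um | 9.6 | 9.6 | arc window for width smoothing |
| smoothingNeighborCount | points | 15 | 15 | neighbours per side, median projection |
| referenceVectorArcLengthUm | um | 10 | 6.4 | head-midpiece vector length |
| curvatureReferenceDistanceUm | um | 10 | 10 | tangent separation Q |
| fftWindowFrames | frames | 200 | 500 | FFT window (sliding if shorter than the movie) |
| fftSkipInitialUm | um | 0 | 0 | skip flagellar spectra at/below this arc length |
| headRotationRadiusPx | px | 10 | 10 | half-length of the rolling cross-line |

Two settings deserve comment. The **head exclusion** (radius 8 px around
the first point, the same radius used for orientation) keeps the sub-pixel
correction away from the head blob, whose cross-profile is not Gaussian;
those points stay on the skeleton and are therefore pinned to the pixel
lattice by design. The **skip-initial arc length** exists because, for a
tethered cell, parameter time series inside the head carry no flagellar
information: their true oscillation amplitude is near zero and tiny
measurement harmonics dominate the spectrum. The validation scenarios in
this package set it to 5 um (just beyond the 8 px head disk at
0.55 um/px); the reference profiles keep 0 so nothing is hidden by
default.

## The median-projection smoother

At the few-micrometre scale a flagellum is locally straight, so jitter can
be removed by projecting each point onto a line through two of its
neighbours. With up to 15 neighbours per side, all neighbour pairs propose
a projection; the point adopts the projection whose displacement is
nearest to the median displacement (lower median for even counts; ties go
to the lowest pair index). The median makes the smoother robust to stray
neighbours without flattening genuine curvature. The same scheme smooths
the width-versus-arc-length signal, with neighbours additionally restricted
to a 9.6 um arc window; a zero window disables smoothing.

## Outlier removal

A point that jumped off the curve inflates both of its adjacent gaps by
roughly the same amount, so the classic triplet rule - remove p_i when the
gap before it exceeds the gap after it - removes the point where the
polyline lands after the jump, and the smoother then pulls the straggler
itself back onto the curve. Applied strictly, however, the rule fires on
sub-pixel jitter alone (in an upscaled list all gaps are nearly equal, and
a strict inequality decides by noise), removing about half of the points
per sweep and degrading kymograph coverage. `removeOutliers()` therefore
exposes a relative slack: the pipeline removes a point only when its
leading gap exceeds 1.5 times its trailing gap, which ignores both jitter
and the sqrt(2) gap ratio of the pixel lattice while still catching
genuine stragglers (gap ratios well above 2).

## Numerical choices

- **Coordinates**: 0-based, pixel centers at integers, x = column,
  y = row. Angles are reported in degrees, counterclockwise positive on
  screen (a point below the head, i.e. at a larger row, is at a negative
  angle). Theta series are unwrapped over time so frame-to-frame steps
  stay within (-180, 180]; tangential angles are unwrapped along arc
  length.
- **Gaussian blur** is separable with mirror-reflected borders, so a
  restricted-to-ROI blur and a 90-degree-rotated image behave exactly like
  the unrotated interior.
- **Rolling-ball background** is the grayscale opening with a ball
  structuring function (no pre-smoothing, bright objects on dark
  background). Opening is idempotent; the subtracted residual skims a few
  percent off smooth wide ridges per pass, which is inherent to the
  construction.
- **Profile fits** use Levenberg-Marquardt with the analytic Jacobian,
  iteration cap 1000, initialized at baseline = min, a = max - min,
  c = offset of the maximum, d = half the normal radius. r^2 is
  1 - SS_res / SS_tot over the profile samples; d is reported positive.
  Non-convergent or degenerate fits are rejected, never guessed.
- **Ordering**: lists of up to 10 points are ordered exactly (dynamic
  programming over subsets); longer lists - the thin, nearly
  one-dimensional sets skeletons produce - use nearest-neighbour chains
  from the two mutually farthest points polished by 2-opt reversals.
- **Spectra** use a rectangular window, one-sided 2/W normalization and
  exclude the DC bin (also from the center-of-mass). Sliding windows move
  at stride 1. The secondary peak must be a strict local maximum at least
  two bins from the primary, so leakage shoulders cannot pose as a second
  peak; ties go to the lower frequency. Up to 10% missing frames are
  filled by linear interpolation; more abort the series.
- **Degenerate inputs** fail loudly: constant frames have no threshold,
  empty masks no skeleton, closed-loop skeletons no endpoints, too-short
  profiles no fit.

## The synthetic renderer

`renderMovie()` draws dark-field-like movies with exact ground truth. The
centerline is built from an analytic tangent-angle field
`phi(s, t) = psi(t) + B(s) sin(2 pi (f t - s / lambda) + phase) + ...`
whose unit tangents are integrated along s; arc length is therefore
exactly the curve parameter, and curvature (d phi / d s) and curvature
angle (phi(s) - phi(s - Q)) are known in closed form. `psi(t)` adds rigid
rocking terms (e.g. a rolling cell whose orientation oscillates at the
roll frequency and at three times it); gated harmonic terms confine extra
wave components to an arc interval with 2 um smoothstep shoulders. The
tube is drawn by max-blending Gaussian cross-sections sampled every
0.25 px; its width sigma(s, t) encodes defocus, and the peak dims as
sigma_ref / sigma so the cross-section flux is conserved (defocused
segments appear wider *and* dimmer, as in real dark-field movies - without
this a defocused tip would outshine the head). The head is a bright
anisotropic Gaussian aligned with the proximal tangent, optionally
intensity-modulated at the rolling frequency; its default brightness
(400 versus 120 for the tube) reflects the strong head scattering that
the orientation step relies on. Intensity fades linearly over the last
4 um of the tube (distal thinning). Noise (additive Gaussian and/or
Poisson) is applied last under a caller-supplied seed; rendering is
deterministic per seed.

What the renderer does **not** emulate: overlapping cells and debris,
uneven illumination, motion blur within an exposure, true 3-D projection
of a non-planar beat (the z proxy is prescribed directly through
sigma(s, t)), and head shapes beyond an ellipse. Green tests on these
renders therefore demonstrate the correctness of the algorithms under
controlled conditions, not robustness to every artifact of real data.

## Validation scale and known limitations

The test-suite and the acceptance script validate on movies of 16-200
frames at 64-200 fps and 150-200 px frame size (flagella of 45-55 um),
sizes at which a movie analyzes in well under two minutes on one core;
frequencies are always placed on exact FFT bins so recovery can be
asserted without tolerance.

Known limitations, visible in the tests:

- Trace **totals** overshoot the true centerline length by up to ~4%
  (phase-dependent): the drawn tube's end caps and the head blob's
  backward skeleton extend the detected structure. Interior arc *spans*
  are accurate to well under 2%; on analytic curves the arc-length sum is
  accurate to fractions of a percent.
- Points inside the head disk are lattice-pinned (by the head exclusion),
  so they are not rotation-equivariant at the sub-pixel level, and the
  curvature angle inherits that region over its Q = 10 um upstream
  support. Outside it, a 90-degree rotation moves recovered coordinates
  by ~0.02 px.
- The relative z proxy is uncalibrated and sign-blind: a flagellum
  crossing the focal plane at f produces a width signal at 2f (the
  doubling is itself reproduced as a test).
- Near the head of a tethered cell the true oscillation amplitude of the
  bending parameters approaches zero and spectra there are dominated by
  measurement harmonics; use the skip-initial setting when analyzing
  tethered cells.
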