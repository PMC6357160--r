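# Shared fixtures and small oracles. Expensive movies are built once per
# test run and memoized.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtureCache[[name]]))
    .fixtureCache[[name]] <- force(builder())
  .fixtureCache[[name]]
}

# Rotate an image matrix 90 degrees clockwise; 0-based point (x, y) maps to
# (nrow - 1 - y, x).
rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

rot90cwPoints <- function(x, y, nr) list(x = nr - 1 - y, y = x)

rot90cwPointsBack <- function(xp, yp, nr) list(x = yp, y = nr - 1 - xp)

# Open-path minimum length by exhaustive permutation enumeration
# (vectorized over the permutation matrix; cached per n).
.permCache <- new.env(parent = emptyenv())

permPathMin <- function(xy) {
  n <- nrow(xy)
  key <- as.character(n)
  per <- .permCache[[key]]
  if (is.null(per)) {
    per <- e1071::permutations(n)
    .permCache[[key]] <- per
  }
  D <- as.matrix(stats::dist(xy))
  tot <- numeric(nrow(per))
  for (j in 1:(n - 1)) tot <- tot + D[cbind(per[, j], per[, j + 1])]
  min(tot)
}

pathLen <- function(pts) sum(sqrt(diff(pts$x)^2 + diff(pts$y)^2))

# Analytic traces (no imaging) for the kinematic derivations.
straightTrace <- function(angleDeg = 0, n = 120, stepPx = 0.5,
                          pixelSize = 1) {
  a <- angleDeg * pi / 180
  pts <- data.frame(x = (0:(n - 1)) * stepPx * cos(a),
                    y = -(0:(n - 1)) * stepPx * sin(a))
  pts <- computeTangentsNormals(pts, 6)
  computeArcLengths(pts, pixelSize)
}

circleTrace <- function(radiusUm = 20, span = pi, n = 600, pixelSize = 1,
                        clockwiseOnScreen = TRUE) {
  th <- seq(0, span, length.out = n)
  y <- if (clockwiseOnScreen) radiusUm * sin(th) else -radiusUm * sin(th)
  pts <- data.frame(x = radiusUm * cos(th), y = y)
  pts <- computeTangentsNormals(pts, 4)
  computeArcLengths(pts, pixelSize)
}

# Project points onto a polyline: returns distance and arc position of the
# foot of the perpendicular (interior = FALSE marks overhang onto the first
# or last segment).
projectOnPolyline <- function(px, py, qx, qy, qarc) {
  ax <- qx[-length(qx)]; ay <- qy[-length(qy)]
  bx <- qx[-1]; by <- qy[-1]
  dx <- bx - ax; dy <- by - ay
  l2 <- pmax(dx^2 + dy^2, 1e-300)
  nSeg <- length(ax)
  out <- vapply(seq_along(px), function(i) {
    tpar <- pmin(pmax(((px[i] - ax) * dx + (py[i] - ay) * dy) / l2, 0), 1)
    d2 <- (px[i] - (ax + tpar * dx))^2 + (py[i] - (ay + tpar * dy))^2
    j <- which.min(d2)
    c(sqrt(d2[j]), qarc[j] + tpar[j] * (qarc[j + 1] - qarc[j]),
      as.numeric(j > 1 && j < nSeg))
  }, numeric(3))
  list(dist = out[1, ], arc = out[2, ], interior = out[3, ] > 0.5)
}

# A short noise-free beat movie shared by several pipeline tests.
beatMovie64 <- function() fixture("beat64", function() {
  p <- synthParams(nFrames = 64, fps = 64, width = 150, height = 150,
                   lengthUm = 50, beatHz = 11)
  renderMovie(p, seed = 3)
})

mouseQuick <- function(...) mouseSettings(gaussSigma = 2, ...)

analyzedBeat64 <- function() fixture("beat64Analyzed", function() {
  m <- beatMovie64()
  analyzeStack(m$stack, mouseQuick(), binWidthUm = 1.1)
})
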