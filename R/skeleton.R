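#' Skeletonize a binary mask by iterative thinning
#'
#' Reduces foreground objects to 1-pixel-wide, 8-connected medial-axis
#' skeletons by Zhang-Suen iterative thinning. Connectivity (the number of
#' connected components) is preserved; free line ends are not eroded.
#'
#' @param mask logical matrix (foreground `TRUE`).
#' @return logical skeleton matrix.
#' @export
skeletonizeFrame <- function(mask) {
  if (!any(mask)) stop("no object found")
  # thin only the foreground bounding box (padded), then reinsert
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  sub <- mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  thinned <- .zhangSuen(sub)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[rows[1]:rows[2], cols[1]:cols[2]] <- thinned
  out
}

.zhangSuen <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  # 1-px FALSE pad so neighbor shifts never index outside
  p <- matrix(FALSE, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- mask
  ri <- 2:(nr + 1); ci <- 2:(nc + 1)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbors in ImageJ order: p2 = N, then clockwise
      p2 <- p[ri - 1, ci];     p3 <- p[ri - 1, ci + 1]
      p4 <- p[ri, ci + 1];     p5 <- p[ri + 1, ci + 1]
      p6 <- p[ri + 1, ci];     p7 <- p[ri + 1, ci - 1]
      p8 <- p[ri, ci - 1];     p9 <- p[ri - 1, ci - 1]
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      core <- p[ri, ci] & b >= 2 & b <= 6 & a == 1
      del <- if (step == 1)
        core & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      else
        core & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      if (any(del)) {
        q <- p[ri, ci]
        q[del] <- FALSE
        p[ri, ci] <- q
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p[ri, ci]
}

#' Extract the single flagellar path from a skeleton
#'
#' Resolves the skeleton to one ordered point list: the largest connected
#' skeleton component is kept, and within it the longest endpoint-to-endpoint
#' path (shortest-path metric with Euclidean step weights on the 8-connected
#' pixel graph); side branches and smaller components are discarded.
#'
#' @param skeleton logical skeleton matrix.
#' @return a data.frame with 0-based `x` (column) and `y` (row) coordinates
#'   ordered along the path, and a `provenance` column (`"skeleton"`).
#' @export
extractSkeletonPath <- function(skeleton) {
  px <- which(skeleton, arr.ind = TRUE)
  if (nrow(px) == 0) stop("no object found")
  y <- px[, 1] - 1L; x <- px[, 2] - 1L
  n <- length(x)
  if (n == 1)
    return(data.frame(x = as.numeric(x), y = as.numeric(y),
                      provenance = "skeleton"))
  id <- matrix(0L, nrow(skeleton), ncol(skeleton))
  id[px] <- seq_len(n)
  # 8-neighbour edges (each counted once via 4 forward offsets)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (o in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    r2 <- px[, 1] + o[1]; c2 <- px[, 2] + o[2]
    ok <- r2 >= 1 & r2 <= nrow(skeleton) & c2 >= 1 & c2 <= ncol(skeleton)
    nb <- integer(n); nb[ok] <- id[cbind(r2[ok], c2[ok])]
    hit <- which(nb > 0)
    from <- c(from, hit); to <- c(to, nb[hit])
    w <- c(w, rep(sqrt(sum(o^2)), length(hit)))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  sub <- igraph::induced_subgraph(g, keep)
  deg <- igraph::degree(sub)
  ends <- which(deg <= 1)
  if (length(ends) == 0) stop("cyclic skeleton")
  dm <- igraph::distances(sub, v = ends, to = ends)
  best <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  sp <- igraph::shortest_paths(sub, from = ends[best[1]],
                               to = ends[best[2]])$vpath[[1]]
  orig <- keep[as.integer(sp)]
  data.frame(x = as.numeric(x[orig]), y = as.numeric(y[orig]),
             provenance = "skeleton")
}
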