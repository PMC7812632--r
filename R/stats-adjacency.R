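#' @include AllClasses.R
NULL

## azimuthal equidistant projection of 3-D head-frame sensor positions:
## polar angle from +z becomes the radius, azimuth is preserved.
azimuthalProjection <- function(pos) {
  stopifnot(is.matrix(pos), ncol(pos) == 3L)
  r <- sqrt(rowSums(pos^2))
  if (any(r < 1e-12))
    stop("degenerate sensor position at the head center")
  theta <- acos(pmin(pmax(pos[, 3L] / r, -1), 1))
  phi <- atan2(pos[, 2L], pos[, 1L])
  cbind(x = theta * cos(phi), y = theta * sin(phi))
}

## brute-force Delaunay edges by the empty-circumcircle property.
## O(n^4) worst case, fine for sensor counts (<= ~128).
delaunayEdges <- function(pts) {
  n <- nrow(pts)
  if (n < 3L)
    stop("geometry error: need at least 3 positioned channels")
  ctr <- scale(pts, scale = FALSE)
  if (svd(ctr, nu = 0L, nv = 0L)$d[2L] < 1e-9 * max(abs(pts), 1))
    stop("geometry error: sensor positions are collinear or degenerate")
  adj <- matrix(FALSE, n, n)
  scl <- max(dist(pts))
  eps <- 1e-9 * scl
  for (i in 1:(n - 2L)) for (j in (i + 1L):(n - 1L)) for (k in (j + 1L):n) {
    p1 <- pts[i, ]; p2 <- pts[j, ]; p3 <- pts[k, ]
    d <- 2 * (p1[1L] * (p2[2L] - p3[2L]) + p2[1L] * (p3[2L] - p1[2L]) +
                p3[1L] * (p1[2L] - p2[2L]))
    if (abs(d) < eps * scl) next              # collinear triple
    u1 <- sum(p1^2); u2 <- sum(p2^2); u3 <- sum(p3^2)
    cx <- (u1 * (p2[2L] - p3[2L]) + u2 * (p3[2L] - p1[2L]) +
             u3 * (p1[2L] - p2[2L])) / d
    cy <- (u1 * (p3[1L] - p2[1L]) + u2 * (p1[1L] - p3[1L]) +
             u3 * (p2[1L] - p1[1L])) / d
    rad2 <- (p1[1L] - cx)^2 + (p1[2L] - cy)^2
    d2 <- (pts[, 1L] - cx)^2 + (pts[, 2L] - cy)^2
    inside <- d2 < rad2 - eps * sqrt(rad2)
    inside[c(i, j, k)] <- FALSE
    if (!any(inside)) {
      adj[i, j] <- adj[j, i] <- TRUE
      adj[j, k] <- adj[k, j] <- TRUE
      adj[i, k] <- adj[k, i] <- TRUE
    }
  }
  adj
}

#' A priori channel neighborhood across space and frequencies
#'
#' Builds the boolean channel-neighborhood matrix from sensor positions
#' (Delaunay triangulation of the azimuthal-equidistant 2-D projection by
#' default, or a plain distance threshold), then expands it across F
#' frequency bins: node (channel c, bin f) is adjacent to (c', f) when the
#' channels neighbor each other and to (c, f +/- 1) across adjacent bins.
#' With a single bin the expanded matrix equals the channel matrix.
#'
#' @param x an \linkS4class{EpochArray} with positions, or a channels x 3
#'   position matrix.
#' @param freqsHz frequency bins over which statistics will be clustered
#'   (default a single pseudo-bin, i.e. space-only adjacency).
#' @param rule "delaunay" (default) or "distance".
#' @param distThreshold neighbor distance (meters in the 3-D frame) for
#'   \code{rule = "distance"}; default 1.3x the minimal inter-sensor
#'   distance.
#' @return An \linkS4class{AdjacencyStructure}.
#' @seealso [statsCluster()], [interCellAdjacency()]
#' @export
conMatrix <- function(x, freqsHz = numeric(0),
                      rule = c("delaunay", "distance"),
                      distThreshold = NULL) {
  rule <- match.arg(rule)
  if (is(x, "EpochArray")) {
    if (positionFree(x))
      stop("adjacency construction refuses position-free containers")
    pos <- chPositions(x)
  } else {
    pos <- as.matrix(x)
  }
  if (nrow(pos) < 3L)
    stop("geometry error: need at least 3 positioned channels")
  n <- nrow(pos)
  if (rule == "delaunay") {
    adj <- delaunayEdges(azimuthalProjection(pos))
  } else {
    dmat <- as.matrix(dist(pos))
    if (is.null(distThreshold))
      distThreshold <- 1.3 * min(dmat[dmat > 0])
    adj <- dmat > 0 & dmat <= distThreshold
  }
  diag(adj) <- FALSE
  adj <- adj | t(adj)
  nf <- max(length(freqsHz), 1L)
  if (nf == 1L) {
    chConFreq <- adj
  } else {
    tband <- abs(outer(seq_len(nf), seq_len(nf), "-")) == 1L
    ## node index = channel + (bin - 1) * N
    chConFreq <- kronecker(diag(nf) > 0, adj) |
      kronecker(tband, diag(n) > 0)
  }
  new("AdjacencyStructure", chCon = adj, chConFreq = chConFreq,
      freqs = as.numeric(freqsHz),
      params = list(rule = rule, distThreshold = distThreshold))
}

#' Cell adjacency for inter-brain connectivity matrices
#'
#' Two inter-brain cells (i, j) and (k, l) of an N1 x N2 block are adjacent
#' when both ends are neighbors (or identical) on their respective scalps:
#' \code{(chCon1[i,k] & chCon2[j,l]) | (i == k & chCon2[j,l]) |
#' (chCon1[i,k] & j == l)}. Cells are indexed column-major
#' (\code{cell = i + (j - 1) * N1}), matching \code{as.vector()} on the
#' block.
#'
#' @param chCon1 N1 x N1 logical channel adjacency of the row-end scalp.
#' @param chCon2 N2 x N2 logical adjacency of the column-end scalp; defaults
#'   to \code{chCon1} (same montage on both heads).
#' @return (N1*N2) x (N1*N2) logical cell adjacency.
#' @export
interCellAdjacency <- function(chCon1, chCon2 = chCon1) {
  stopifnot(is.matrix(chCon1), is.matrix(chCon2))
  a1 <- chCon1 | diag(nrow(chCon1)) > 0
  a2 <- chCon2 | diag(nrow(chCon2)) > 0
  out <- kronecker(a2, a1) > 0
  diag(out) <- FALSE
  out
}
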