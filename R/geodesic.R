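# Geodesic distances on the discrete RPE surface. Valid surface columns,
# lifted to their 3D mm positions, form the nodes of a graph whose edges
# connect each column to its 8- or 16-neighborhood (16 = the 8 adjacent
# cells plus the 8 knight moves) with Euclidean 3D chord weights; shortest
# paths are Dijkstra via igraph. The 16-neighborhood keeps the metrication
# overestimate of smooth-surface geodesics below about 2.8%.

.neighborOffsets <- function(neighborhood) {
  base <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  if (neighborhood == 8L) return(base)
  rbind(base, c(2, 1), c(1, 2), c(2, -1), c(1, -2))
}

# Build the surface graph once per surface; reused across queries.
.surfaceGraph <- function(surface, neighborhood = 16L) {
  g <- surface@geom
  nf <- g@nFast; ns <- g@nSlow
  P <- .surfacePoints3d(surface)
  validLin <- which(as.vector(surface@valid))
  comp <- integer(nf * ns)
  comp[validLin] <- seq_along(validLin)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in seq_len(nrow(.neighborOffsets(neighborhood)))) {
    off <- .neighborOffsets(neighborhood)[k, ]
    df <- off[1]; ds <- off[2]
    f0 <- max(0L, -df):(nf - 1L - max(0L, df))
    s0 <- max(0L, -ds):(ns - 1L - max(0L, ds))
    fa <- rep(f0, times = length(s0))
    sa <- rep(s0, each = length(f0))
    li0 <- fa + sa * nf + 1L
    li1 <- (fa + df) + (sa + ds) * nf + 1L
    ok <- comp[li0] > 0L & comp[li1] > 0L
    li0 <- li0[ok]; li1 <- li1[ok]
    from <- c(from, comp[li0]); to <- c(to, comp[li1])
    w <- c(w, sqrt(rowSums((P[li0, , drop = FALSE] - P[li1, , drop = FALSE])^2)))
  }
  list(from = from, to = to, weights = w, P = P, comp = comp,
       nValid = length(validLin), geom = g)
}

# valid columns (linear 1-based ids) near a 3D point's en face projection
.spliceNeighbors <- function(point3d, sg) {
  g <- sg$geom
  ef <- physicalToVoxel(point3d, g)[1, 1:2]
  f <- round(ef[1]); s <- round(ef[2])
  for (r in c(2L, 5L, 10L, 20L)) {
    fr <- max(0L, f - r):min(g@nFast - 1L, f + r)
    sr <- max(0L, s - r):min(g@nSlow - 1L, s + r)
    lin <- rep(fr, times = length(sr)) + rep(sr, each = length(fr)) * g@nFast + 1L
    lin <- lin[sg$comp[lin] > 0L]
    if (length(lin)) return(lin)
  }
  ropStop("measurement",
          sprintf("no valid surface column within 20 cells of point (%.2f, %.2f, %.2f) mm",
                  point3d[1], point3d[2], point3d[3]))
}

# Distances from one spliced source point to many spliced target points.
.geodesicMany <- function(surface, source3d, targets3d, neighborhood = 16L,
                          graph = NULL) {
  sg <- if (is.null(graph)) .surfaceGraph(surface, neighborhood) else graph
  targets3d <- if (is.matrix(targets3d)) targets3d else matrix(targets3d, ncol = 3)
  nT <- nrow(targets3d)
  srcV <- sg$nValid + 1L
  tgtV <- sg$nValid + 1L + seq_len(nT)
  exFrom <- integer(0); exTo <- integer(0); exW <- numeric(0)
  nb <- .spliceNeighbors(source3d, sg)
  exFrom <- c(exFrom, rep.int(srcV, length(nb)))
  exTo <- c(exTo, sg$comp[nb])
  exW <- c(exW, sqrt(colSums((t(sg$P[nb, , drop = FALSE]) - source3d)^2)))
  for (i in seq_len(nT)) {
    nb <- .spliceNeighbors(targets3d[i, ], sg)
    exFrom <- c(exFrom, rep.int(tgtV[i], length(nb)))
    exTo <- c(exTo, sg$comp[nb])
    exW <- c(exW, sqrt(colSums((t(sg$P[nb, , drop = FALSE]) - targets3d[i, ])^2)))
  }
  edges <- rbind(c(sg$from, exFrom), c(sg$to, exTo))
  ig <- igraph::make_graph(as.vector(edges), n = sg$nValid + 1L + nT,
                           directed = FALSE)
  d <- igraph::distances(ig, v = srcV, to = tgtV,
                         weights = c(sg$weights, exW), algorithm = "dijkstra")
  as.numeric(d)
}

#' Geodesic distance between two points on the RPE surface
#'
#' Length of the shortest path constrained to the discrete RPE surface:
#' Dijkstra over the graph of valid surface columns lifted to 3D, each
#' connected to its 16-neighborhood (optionally 8) with Euclidean chord
#' weights. Both endpoints are spliced into the graph at their exact 3D
#' positions, connected to the valid columns near their en face
#' projections. The result is always at least the straight-line 3D
#' distance between the endpoints.
#'
#' @param surface an \code{\linkS4class{RpeSurface}}.
#' @param geom the scan geometry (carried by the surface; accepted for
#'   interface symmetry and checked for consistency).
#' @param start,end 3D mm positions.
#' @param neighborhood 8 or 16 (default); the 16-neighborhood keeps the
#'   grid-direction overestimate below about 2.8%.
#' @return Distance in mm.
#' @export
geodesicDistance <- function(surface, geom = surface@geom, start, end,
                             neighborhood = 16L) {
  if (!identical(geom, surface@geom))
    ropStop("geometry", "geom does not match the surface's scan geometry")
  if (all(abs(start - end) < 1e-12)) return(0)
  d <- .geodesicMany(surface, start, matrix(end, 1), neighborhood)
  if (!is.finite(d))
    ropStop("measurement", "endpoints lie in disconnected surface components")
  d
}

#' Retinal arclengths to the sampled border
#'
#' One geodesic distance per border sample, from the optic-disc centroid to
#' that sample, in input order. Samples whose geodesic cannot be computed
#' (disconnected surface) are dropped with a warning and counted.
#'
#' @param surface an \code{\linkS4class{RpeSurface}}.
#' @param geom the scan geometry.
#' @param disc a \code{\linkS4class{DiscCentroid}}.
#' @param borderSamples m x 3 matrix of sampled border points (mm), e.g.
#'   from \code{\link{resampleBorder}}.
#' @param neighborhood 8 or 16.
#' @return A list with \code{ralMm} (retained arclengths, mm) and
#'   \code{nDropped}.
#' @export
computeRal <- function(surface, geom = surface@geom, disc, borderSamples,
                       neighborhood = 16L) {
  if (!nrow(borderSamples))
    ropStop("measurement", "no border samples to measure")
  d <- .geodesicMany(surface, disc@position3d, borderSamples, neighborhood)
  bad <- !is.finite(d)
  if (any(bad)) {
    warning(sprintf("%d of %d border samples unreachable on the surface; dropped",
                    sum(bad), length(d)))
    d <- d[!bad]
  }
  list(ralMm = d, nDropped = sum(bad))
}

#' Geodesic foveal distance
#'
#' Geodesic distance along the RPE from the disc centroid to the foveal RPE
#' point, consistent with how the retinal arclengths are measured. The
#' straight-line 3D chord is also returned for comparison.
#'
#' @param surface an \code{\linkS4class{RpeSurface}}.
#' @param geom the scan geometry.
#' @param disc a \code{\linkS4class{DiscCentroid}}.
#' @param fovea 0-based (fast, slow) foveal center.
#' @param neighborhood 8 or 16.
#' @return A list with \code{fdMm} (geodesic) and \code{chordMm}.
#' @export
fovealDistance <- function(surface, geom = surface@geom, disc, fovea,
                           neighborhood = 16L) {
  z <- .interpSurfaceDepth(surface, fovea[1], fovea[2])
  if (is.na(z))
    ropStop("measurement", "fovea falls on an invalid surface column")
  p <- voxelToPhysical(c(fovea[1], fovea[2], z), geom)[1, ]
  d <- .geodesicMany(surface, disc@position3d, matrix(p, 1), neighborhood)
  if (!is.finite(d))
    ropStop("measurement", "fovea unreachable from the disc centroid on the surface")
  list(fdMm = d, chordMm = sqrt(sum((p - disc@position3d)^2)))
}
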