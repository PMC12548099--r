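# Landmark handling: rasterizing annotated point sequences into contiguous
# chains, lifting them onto the RPE surface, locating the 3D disc centroid,
# and resampling the vascular-avascular border at a fixed bearing density.

# Classic driving-axis integer Bresenham (nearest-cell selection). Returns
# the cells from p0 to p1 inclusive, 0-based (fast, slow).
.bresenhamSegment <- function(p0, p1) {
  x0 <- p0[1]; y0 <- p0[2]; x1 <- p1[1]; y1 <- p1[2]
  steep <- abs(y1 - y0) > abs(x1 - x0)
  if (steep) { t <- x0; x0 <- y0; y0 <- t; t <- x1; x1 <- y1; y1 <- t }
  sx <- if (x1 >= x0) 1L else -1L
  sy <- if (y1 >= y0) 1L else -1L
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  err <- dx %/% 2L
  xs <- seq.int(x0, x1, by = sx)
  ys <- integer(length(xs))
  y <- y0
  for (i in seq_along(xs)) {
    ys[i] <- y
    err <- err - dy
    if (err < 0L) { y <- y + sy; err <- err + dx }
  }
  cells <- cbind(xs, ys, deparse.level = 0)
  if (steep) cells[, 2:1, drop = FALSE] else cells
}

#' Connect annotated points into a contiguous raster chain
#'
#' Rasterizes straight segments between consecutive annotated (fast, slow)
#' points with integer Bresenham line drawing (nearest-cell selection) and
#' concatenates them, dropping the duplicated junction cell between
#' segments. The result is 8-connected and visits every input point in
#' order.
#'
#' @param points n x 2 matrix (or list of length-2 vectors) of ordered
#'   0-based (fast, slow) points; fractional inputs are rounded to the
#'   nearest cell.
#' @return A \code{\linkS4class{BorderChain}} (not yet lifted to 3D).
#' @examples
#' bresenhamChain(rbind(c(0, 0), c(4, 2)))
#' @export
bresenhamChain <- function(points) {
  pts <- round(as.matrix(points))
  storage.mode(pts) <- "integer"
  if (nrow(pts) < 2L)
    ropStop("annotation", "need at least 2 points to form a chain")
  segs <- vector("list", nrow(pts) - 1L)
  for (i in seq_len(nrow(pts) - 1L)) {
    s <- .bresenhamSegment(pts[i, ], pts[i + 1L, ])
    if (i > 1L) s <- s[-1L, , drop = FALSE]
    segs[[i]] <- s
  }
  new("BorderChain", cells = do.call(rbind, segs),
      points3d = matrix(numeric(), 0, 3))
}

# RPE depth for arbitrary cells, interpolating from nearby valid columns
# where a cell itself is invalid; errors when no valid column lies within
# maxRadius cells.
.chainDepths <- function(cells, surface, maxRadius = 5L) {
  g <- surface@geom
  z <- numeric(nrow(cells))
  nInterp <- 0L
  for (i in seq_len(nrow(cells))) {
    f <- cells[i, 1]; s <- cells[i, 2]
    zi <- surface@zRpe[f + 1L, s + 1L]
    if (is.na(zi)) {
      zi <- NA_real_
      for (r in seq_len(maxRadius)) {
        fr <- max(0L, f - r):min(g@nFast - 1L, f + r)
        sr <- max(0L, s - r):min(g@nSlow - 1L, s + r)
        patch <- surface@zRpe[fr + 1L, sr + 1L, drop = FALSE]
        if (any(!is.na(patch))) { zi <- mean(patch, na.rm = TRUE); break }
      }
      if (is.na(zi))
        ropStop("measurement",
                sprintf("no valid RPE column within %d cells of chain cell (fast=%d, slow=%d)",
                        maxRadius, f, s))
      nInterp <- nInterp + 1L
    }
    z[i] <- zi
  }
  list(z = z, nInterpolated = nInterp)
}

#' Lift a chain onto the RPE surface
#'
#' Attaches 3D mm coordinates to each chain cell using the cell's RPE
#' depth; cells on invalid columns take the mean depth of the nearest valid
#' columns (within \code{maxRadius} cells).
#'
#' @param chain a \code{\linkS4class{BorderChain}}.
#' @param surface an \code{\linkS4class{RpeSurface}}.
#' @param maxRadius search radius (cells) for depth interpolation.
#' @return The chain with its \code{points3d} slot populated.
#' @export
liftChain <- function(chain, surface, maxRadius = 5L) {
  d <- .chainDepths(chain@cells, surface, maxRadius)
  idx <- cbind(chain@cells[, 1], chain@cells[, 2], d$z)
  new("BorderChain", cells = chain@cells,
      points3d = voxelToPhysical(idx, surface@geom))
}

#' 3D centroid of the optic-disc edge
#'
#' Connects the annotated disc-edge points into a closed raster chain,
#' lifts each chain cell to 3D using the RPE depth at the optic-nerve edge
#' (the disc interior itself carries no RPE), and returns the unweighted
#' mean of the 3D chain points together with its en face re-projection
#' (the angular position of the centroid on the index grid). Optionally the
#' centroid of the filled disc region (all grid cells inside the edge
#' polygon) can be used instead of the edge chain.
#'
#' @param discEdge k x 2 matrix of ordered 0-based disc-edge points
#'   (k >= 3); the loop is closed automatically.
#' @param surface an \code{\linkS4class{RpeSurface}}.
#' @param geom the scan geometry.
#' @param maxRadius interpolation radius (cells) for edge cells on invalid
#'   columns.
#' @param filled if TRUE, average over the filled disc region rather than
#'   the edge chain.
#' @return A \code{\linkS4class{DiscCentroid}}.
#' @export
discCentroid3d <- function(discEdge, surface, geom, maxRadius = 5L,
                           filled = FALSE) {
  pts <- round(as.matrix(discEdge))
  if (nrow(pts) < 3L)
    ropStop("annotation", "disc edge needs at least 3 points")
  chain <- bresenhamChain(rbind(pts, pts[1L, , drop = FALSE]))
  cells <- chain@cells
  # drop the duplicated closing cell if the loop closed exactly
  n <- nrow(cells)
  if (n > 1L && all(cells[n, ] == cells[1L, ]))
    cells <- cells[-n, , drop = FALSE]
  if (filled) cells <- .fillPolygonCells(cells)
  d <- .chainDepths(cells, surface, maxRadius)
  p3 <- voxelToPhysical(cbind(cells[, 1], cells[, 2], d$z), geom)
  centroid <- colMeans(p3)
  ef <- physicalToVoxel(centroid, geom)[1, 1:2]
  new("DiscCentroid", position3d = centroid, enfaceCenter = ef,
      nInterpolated = d$nInterpolated)
}

# Even-odd scanline fill: all grid cells inside (or on) the closed chain.
.fillPolygonCells <- function(cells) {
  poly <- rbind(cells, cells[1L, , drop = FALSE])
  fr <- range(cells[, 1]); sr <- range(cells[, 2])
  inside <- list(cells)
  k <- 2L
  for (s in sr[1]:sr[2]) {
    for (f in fr[1]:fr[2]) {
      # even-odd test against polygon edges
      cross <- 0L
      for (e in seq_len(nrow(poly) - 1L)) {
        y1 <- poly[e, 2]; y2 <- poly[e + 1L, 2]
        if ((y1 <= s) != (y2 <= s)) {
          xat <- poly[e, 1] + (s - y1) / (y2 - y1) * (poly[e + 1L, 1] - poly[e, 1])
          if (xat > f) cross <- cross + 1L
        }
      }
      if (cross %% 2L == 1L) { inside[[k]] <- cbind(f, s); k <- k + 1L }
    }
  }
  unique(do.call(rbind, inside))
}

# Signed bearing (degrees, in (-180, 180]) of en face points about a
# center, measured from the reference direction (disc -> fovea); positive
# clockwise in (fast, slow) index space, which matches the sign of the
# tangent-space bearing on the retinal sphere.
.bearingsAbout <- function(points, center, refDir) {
  v1 <- points[, 1] - center[1]
  v2 <- points[, 2] - center[2]
  .rad2deg(atan2(refDir[2] * v1 - refDir[1] * v2,
                 refDir[1] * v1 + refDir[2] * v2))
}

#' Resample the vascular-avascular border at a fixed angular density
#'
#' Computes the bearing of every chain cell about the disc's en face
#' center (reference direction disc -> fovea), restricts to the temporal
#' hemisphere (the half-plane containing the fovea, i.e. bearings within
#' +/-90 degrees), and lays out sample bearings every
#' \code{30 / density} degrees from the start of the covered interval,
#' half-open at its end (a candidate bearing is kept iff it is strictly
#' below the interval end). Each sample is the chain cell nearest that
#' bearing. With the default density of 10 points per clock hour the step
#' is 3 degrees, so a border covering 60 degrees yields 20 samples. A
#' border split into several contiguous chains is handled per chain, with
#' coverage taken as the union of the per-chain bearing intervals.
#'
#' @param chain a lifted \code{\linkS4class{BorderChain}} (see
#'   \code{\link{liftChain}}), or a list of lifted chains for a border with
#'   gaps.
#' @param disc a \code{\linkS4class{DiscCentroid}}.
#' @param fovea 0-based (fast, slow) foveal center.
#' @param density samples per clock hour (30 degrees); default 10.
#' @param laterality \code{"OD"} or \code{"OS"}; affects only the reported
#'   clock-hour labels, not the geometry.
#' @return A list with \code{points3d} (m x 3), \code{cells},
#'   \code{bearingsDeg}, \code{clockHours} and \code{coveredDeg} (total
#'   temporal bearing coverage, capped at 180).
#' @export
resampleBorder <- function(chain, disc, fovea, density = 10,
                           laterality = "OD") {
  chains <- if (is.list(chain)) chain else list(chain)
  refDir <- c(fovea[1] - disc@enfaceCenter[1],
              fovea[2] - disc@enfaceCenter[2])
  step <- 30 / density
  points3d <- matrix(numeric(), 0, 3)
  cells <- matrix(integer(), 0, 2)
  bearings <- numeric()
  intervals <- matrix(numeric(), 0, 2)
  for (ch in chains) {
    if (!nrow(ch@points3d))
      ropStop("annotation", "border chain must be lifted to 3D before resampling")
    b <- .bearingsAbout(ch@cells, disc@enfaceCenter, refDir)
    temporal <- abs(b) < 90
    if (!any(temporal)) next
    bt <- b[temporal]
    lo <- min(bt); hi <- max(bt)
    intervals <- rbind(intervals, c(lo, hi))
    sampleB <- seq(lo, hi, by = step)
    sampleB <- sampleB[sampleB < hi | hi == lo]   # half-open at the end
    if (hi == lo) sampleB <- lo
    idxT <- which(temporal)
    for (sb in sampleB) {
      j <- idxT[which.min(abs(bt - sb))]
      points3d <- rbind(points3d, ch@points3d[j, ])
      cells <- rbind(cells, ch@cells[j, ])
      bearings <- c(bearings, sb)
    }
  }
  if (!length(bearings)) {
    warning("border lies entirely in the nasal hemisphere; no samples taken")
    return(list(points3d = points3d, cells = cells, bearingsDeg = bearings,
                clockHours = numeric(), coveredDeg = 0))
  }
  covered <- min(.unionLength(intervals), 180)
  # clock hours about the disc: 9 o'clock is temporal in OD, 3 o'clock in OS
  ch0 <- if (laterality == "OD") 9 else 3
  sgn <- if (laterality == "OD") 1 else -1
  clock <- (ch0 + sgn * bearings / 30) %% 12
  list(points3d = unname(points3d), cells = unname(cells),
       bearingsDeg = bearings, clockHours = clock, coveredDeg = covered)
}

# total length of a union of 1D intervals given as rows (lo, hi)
.unionLength <- function(intervals) {
  if (!nrow(intervals)) return(0)
  o <- order(intervals[, 1])
  intervals <- intervals[o, , drop = FALSE]
  tot <- 0; curLo <- intervals[1, 1]; curHi <- intervals[1, 2]
  for (i in seq_len(nrow(intervals))[-1]) {
    if (intervals[i, 1] > curHi) {
      tot <- tot + (curHi - curLo)
      curLo <- intervals[i, 1]; curHi <- intervals[i, 2]
    } else curHi <- max(curHi, intervals[i, 2])
  }
  tot + (curHi - curLo)
}

#' Assessed angle of the vascular border
#'
#' The angular extent (degrees) of the temporal bearing interval covered by
#' the border about the disc center, capped at 180 degrees (the full
#' temporal hemisphere).
#'
#' @inheritParams resampleBorder
#' @return Angle in degrees.
#' @export
assessedAngle <- function(chain, disc, fovea, laterality = "OD") {
  chains <- if (is.list(chain)) chain else list(chain)
  refDir <- c(fovea[1] - disc@enfaceCenter[1],
              fovea[2] - disc@enfaceCenter[2])
  intervals <- matrix(numeric(), 0, 2)
  for (ch in chains) {
    b <- .bearingsAbout(ch@cells, disc@enfaceCenter, refDir)
    bt <- b[abs(b) < 90]
    if (length(bt)) intervals <- rbind(intervals, range(bt))
  }
  min(.unionLength(intervals), 180)
}

#' Read and write landmark annotations
#'
#' Landmarks are exchanged as a JSON document
#' \code{\{"disc_edge": [[fast, slow], ...], "fovea": [fast, slow],
#' "border": [[fast, slow], ...], "laterality": "OD"|"OS"\}} with 0-based
#' indices.
#'
#' @param path annotation file path.
#' @return \code{readLandmarks} returns a
#'   \code{\linkS4class{LandmarkSet}}; \code{writeLandmarks} returns
#'   \code{path} invisibly.
#' @export
readLandmarks <- function(path) {
  if (!file.exists(path)) ropStop("format", "landmark file not found: ", path)
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) ropStop("format", "cannot parse landmark JSON ",
                                            path, ": ", conditionMessage(e)))
  need <- c("disc_edge", "fovea", "border", "laterality")
  miss <- setdiff(need, names(x))
  if (length(miss))
    ropStop("format", "landmark file is missing fields: ",
            paste(miss, collapse = ", "))
  LandmarkSet(discEdge = matrix(unlist(x$disc_edge), ncol = 2, byrow = !is.matrix(x$disc_edge)),
              fovea = as.numeric(x$fovea),
              border = matrix(unlist(x$border), ncol = 2, byrow = !is.matrix(x$border)),
              laterality = x$laterality)
}

#' @param lms a \code{LandmarkSet} to serialize.
#' @rdname readLandmarks
#' @export
writeLandmarks <- function(lms, path) {
  x <- list(disc_edge = unname(apply(lms@discEdge, 1, as.numeric, simplify = FALSE)),
            fovea = as.numeric(lms@fovea),
            border = unname(apply(lms@border, 1, as.numeric, simplify = FALSE)),
            laterality = lms@laterality)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Check that landmarks fall inside the scan grid
#'
#' @param lms a \code{\linkS4class{LandmarkSet}}.
#' @param geom the scan geometry.
#' @return \code{lms} invisibly; raises an annotation error naming the
#'   first offending point otherwise.
#' @export
validateLandmarks <- function(lms, geom) {
  lim <- c(geom@nFast, geom@nSlow) - 1L
  checkSet <- function(pts, what) {
    pts <- if (is.matrix(pts)) pts else matrix(pts, ncol = 2)
    for (i in seq_len(nrow(pts))) {
      if (any(pts[i, ] < 0) || any(pts[i, ] > lim))
        ropStop("annotation",
                sprintf("%s point %d = (%g, %g) is outside the %d x %d grid",
                        what, i, pts[i, 1], pts[i, 2], geom@nFast, geom@nSlow))
    }
  }
  checkSet(lms@discEdge, "disc-edge")
  checkSet(matrix(lms@fovea, ncol = 2), "fovea")
  checkSet(lms@border, "border")
  invisible(lms)
}
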