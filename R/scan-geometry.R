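# Coordinate model: every A-scan is a ray from a single pivot. A voxel
# (fast, slow, depth) maps to direction(alpha, beta) scaled by the radial
# distance pivotOffsetMm + depth * depthStepMm, where
#   alpha = (fast/(nFast-1) - 1/2) * fovFastDeg   (rotation about slow axis)
#   beta  = (slow/(nSlow-1) - 1/2) * fovSlowDeg   (rotation about fast axis)
# and direction = Rx(beta) %*% Ry(alpha) %*% c(0,0,1)
#               = (sin a, -sin b * cos a, cos b * cos a).
# The origin is at the pivot; the central axis is +z.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.rayAngles <- function(fast, slow, geom) {
  list(alpha = .deg2rad((fast / (geom@nFast - 1) - 0.5) * geom@fovFastDeg),
       beta  = .deg2rad((slow / (geom@nSlow - 1) - 0.5) * geom@fovSlowDeg))
}

.rayDirection <- function(fast, slow, geom) {
  a <- .rayAngles(fast, slow, geom)
  cbind(sin(a$alpha), -sin(a$beta) * cos(a$alpha), cos(a$beta) * cos(a$alpha))
}

.checkBounds <- function(idx, geom) {
  lim <- c(geom@nFast, geom@nSlow, geom@nDepth) - 1L
  axes <- c("fast", "slow", "depth")
  for (j in 1:3) {
    bad <- idx[, j] < 0 | idx[, j] > lim[j]
    if (any(bad))
      stop(sprintf("index out of range on the %s axis: %g not in [0, %d]",
                   axes[j], idx[which(bad)[1], j], lim[j]), call. = FALSE)
  }
}

#' Convert voxel indices to physical 3D coordinates
#'
#' Maps 0-based \code{(fast, slow, depth)} indices (fractional values
#' permitted, e.g. for interpolated surfaces) to mm positions under the
#' single-pivot equiangular fan model. The origin sits at the scan pivot and
#' the central axis is +z.
#'
#' @param index length-3 numeric vector or n x 3 matrix of 0-based indices.
#' @param geom a \code{\linkS4class{ScanGeometry}}.
#' @return n x 3 matrix of mm coordinates (a 1 x 3 matrix for a single
#'   index).
#' @seealso \code{\link{physicalToVoxel}} for the inverse.
#' @export
voxelToPhysical <- function(index, geom) {
  idx <- if (is.matrix(index)) index else matrix(index, ncol = 3)
  .checkBounds(idx, geom)
  d <- .rayDirection(idx[, 1], idx[, 2], geom)
  r <- geom@pivotOffsetMm + idx[, 3] * geom@depthStepMm
  unname(d * r)
}

#' Invert the voxel-to-physical mapping
#'
#' Recovers fractional 0-based \code{(fast, slow, depth)} indices from mm
#' coordinates by solving for the ray angles and the radial distance.
#' Points outside the scanned angular range or depth range yield indices
#' outside the grid bounds; no bounds check is applied.
#'
#' @param points length-3 numeric vector or n x 3 matrix of mm coordinates.
#' @param geom a \code{\linkS4class{ScanGeometry}}.
#' @return n x 3 matrix of fractional indices.
#' @export
physicalToVoxel <- function(points, geom) {
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  r <- sqrt(rowSums(p^2))
  alpha <- asin(pmin(1, pmax(-1, p[, 1] / r)))
  beta <- atan2(-p[, 2], p[, 3])
  cbind((.rad2deg(alpha) / geom@fovFastDeg + 0.5) * (geom@nFast - 1),
        (.rad2deg(beta) / geom@fovSlowDeg + 0.5) * (geom@nSlow - 1),
        (r - geom@pivotOffsetMm) / geom@depthStepMm)
}

#' Estimate axial length from the foveal RPE depth
#'
#' Axial length is calibrated from the radial distance of the RPE at the
#' fovea: \code{AL = alScale * (pivotOffsetMm + z_rpe(fovea) * depthStepMm)
#' + alOffsetMm}. With the phantom geometry profile (pivot at the globe
#' center, \code{alScale = 2}) this is exactly twice the RPE sphere radius.
#' A measured axial length supplied with the eye's metadata takes precedence
#' and is returned unchanged.
#'
#' @param surface an \code{\linkS4class{RpeSurface}}.
#' @param fovea 0-based (fast, slow) foveal position (fractional allowed).
#' @param geom a \code{\linkS4class{ScanGeometry}}.
#' @param measuredAl optional axial length (mm) from biometry metadata;
#'   returned as-is when supplied.
#' @return axial length in mm.
#' @export
estimateAxialLength <- function(surface, fovea, geom, measuredAl = NULL) {
  if (!is.null(measuredAl) && !is.na(measuredAl)) return(as.numeric(measuredAl))
  z <- .interpSurfaceDepth(surface, fovea[1], fovea[2])
  if (is.na(z))
    stop("cannot estimate axial length: fovea falls on an invalid surface column",
         call. = FALSE)
  geom@alScale * (geom@pivotOffsetMm + z * geom@depthStepMm) + geom@alOffsetMm
}

# Bilinear interpolation of the RPE depth at a fractional (fast, slow)
# position; falls back to the nearest valid corner when some corners are
# invalid, NA when none is.
.interpSurfaceDepth <- function(surface, fast, slow) {
  z <- surface@zRpe
  nf <- nrow(z); ns <- ncol(z)
  f0 <- floor(fast); s0 <- floor(slow)
  f0 <- min(max(f0, 0), nf - 2); s0 <- min(max(s0, 0), ns - 2)
  wf <- fast - f0; ws <- slow - s0
  corners <- rbind(c(f0, s0), c(f0 + 1, s0), c(f0, s0 + 1), c(f0 + 1, s0 + 1))
  vals <- z[cbind(corners[, 1] + 1, corners[, 2] + 1)]
  w <- c((1 - wf) * (1 - ws), wf * (1 - ws), (1 - wf) * ws, wf * ws)
  ok <- !is.na(vals)
  if (all(ok)) return(sum(vals * w))
  if (!any(ok)) return(NA_real_)
  vals[ok][which.max(w[ok])]
}

#' Read or write a scan-geometry sidecar
#'
#' Scan geometry travels with a volume as a small JSON or YAML sidecar with
#' fields \code{n_fast, n_slow, n_depth, fov_fast_deg, fov_slow_deg,
#' depth_step_mm, pivot_offset_mm, al_scale, al_offset_mm} (lengths mm,
#' angles degrees). The format is chosen by file extension
#' (\code{.json} vs \code{.yaml}/\code{.yml}).
#'
#' @param path file path.
#' @return \code{readScanGeometry} returns a
#'   \code{\linkS4class{ScanGeometry}}; \code{writeScanGeometry} returns
#'   \code{path} invisibly.
#' @export
readScanGeometry <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  need <- c("n_fast", "n_slow", "n_depth", "fov_fast_deg", "fov_slow_deg",
            "depth_step_mm", "pivot_offset_mm", "al_scale", "al_offset_mm")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("geometry sidecar is missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ScanGeometry(x$n_fast, x$n_slow, x$n_depth, x$fov_fast_deg, x$fov_slow_deg,
               x$depth_step_mm, x$pivot_offset_mm, x$al_scale, x$al_offset_mm)
}

#' @param geom a \code{\linkS4class{ScanGeometry}} to serialize.
#' @rdname readScanGeometry
#' @export
writeScanGeometry <- function(geom, path) {
  x <- list(n_fast = geom@nFast, n_slow = geom@nSlow, n_depth = geom@nDepth,
            fov_fast_deg = geom@fovFastDeg, fov_slow_deg = geom@fovSlowDeg,
            depth_step_mm = geom@depthStepMm,
            pivot_offset_mm = geom@pivotOffsetMm,
            al_scale = geom@alScale, al_offset_mm = geom@alOffsetMm)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(x, path)
  invisible(path)
}
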