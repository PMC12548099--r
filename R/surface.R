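# Surface extraction from retina/choroid label volumes. All per-column
# passes are vectorized over the en face grid with a single loop over the
# (short) depth axis.

.asDepthMatrix <- function(voxels) {
  d <- dim(voxels)
  matrix(voxels, nrow = d[1] * d[2], ncol = d[3])
}

#' Extract the RPE surface from a label volume
#'
#' The retinal pigment epithelium is taken as the half-voxel interface
#' between the last retina voxel and the first choroid voxel along each
#' A-scan (the segmentation carries no explicit RPE class; its boundary is
#' the RPE by construction). Columns lacking either label are invalid.
#' Columns where stray retina voxels occur after the first choroid voxel
#' (segmentation noise) use the last retina-to-choroid transition and are
#' counted in the \code{nMultiRun} QC slot; columns whose choroid lies
#' entirely above the retina violate the label-order invariant and raise an
#' error naming the column.
#'
#' @param vol a \code{\linkS4class{LabelVolume}}.
#' @return An \code{\linkS4class{RpeSurface}} whose \code{zRpe} holds
#'   0-based fractional depth indices (e.g. labels 0,0,1,1,1,2,2 along a
#'   column give 4.5).
#' @export
extractRpeSurface <- function(vol) {
  g <- vol@geom
  m <- .asDepthMatrix(vol@voxels)
  n <- nrow(m); nd <- ncol(m)
  lastRet <- integer(n)          # 1-based depth of last retina voxel, 0 if none
  firstCho <- rep.int(nd + 1L, n)
  for (d in seq_len(nd)) {
    sel <- m[, d] == 1L
    lastRet[sel] <- d
    selc <- m[, d] == 2L & firstCho > nd
    firstCho[selc] <- d
  }
  # first choroid strictly after the last retina voxel
  choAfter <- rep.int(0L, n)
  for (d in rev(seq_len(nd))) {
    sel <- m[, d] == 2L & d > lastRet
    choAfter[sel] <- d
  }
  hasRet <- lastRet > 0L
  hasCho <- firstCho <= nd
  bad <- hasRet & hasCho & choAfter == 0L
  if (any(bad)) {
    i <- which(bad)[1]
    fs <- .linearToEnface(i, g)
    ropStop("measurement",
            sprintf("label-order invariant violated: retina occurs after choroid in column (fast=%d, slow=%d)",
                    fs[1], fs[2]))
  }
  valid <- hasRet & hasCho
  multiRun <- sum(valid & firstCho < lastRet)
  z <- rep(NA_real_, n)
  z[valid] <- (choAfter[valid] - 1) - 0.5   # 0-based half-voxel boundary
  new("RpeSurface",
      zRpe = matrix(z, g@nFast, g@nSlow),
      valid = matrix(valid, g@nFast, g@nSlow),
      geom = g, nMultiRun = as.integer(multiRun))
}

.linearToEnface <- function(i, geom) {
  c((i - 1L) %% geom@nFast, (i - 1L) %/% geom@nFast)   # 0-based
}

#' Retinal thickness map
#'
#' Thickness per en face column, measured along the A-scan ray as the count
#' of retina voxels times the depth step. Measuring along the ray (rather
#' than perpendicular to the surface) matches per-A-scan depth maps; for
#' near-normal incidence the difference is negligible and it is documented
#' as an approximation.
#'
#' @param vol a \code{\linkS4class{LabelVolume}}.
#' @return A \code{\linkS4class{ThicknessMap}}; columns without retina are
#'   invalid.
#' @export
thicknessMap <- function(vol) {
  g <- vol@geom
  m <- .asDepthMatrix(vol@voxels)
  cnt <- integer(nrow(m))
  for (d in seq_len(ncol(m))) cnt <- cnt + (m[, d] == 1L)
  new("ThicknessMap",
      thicknessMm = matrix(cnt * g@depthStepMm, g@nFast, g@nSlow),
      valid = matrix(cnt > 0L, g@nFast, g@nSlow),
      geom = g)
}

#' En face maximum intensity projection
#'
#' Per-column maximum along the depth axis, for either a raw intensity
#' array or a \code{\linkS4class{LabelVolume}}.
#'
#' @param vol a 3D array or a \code{LabelVolume}.
#' @return A numeric matrix over (fast, slow).
#' @export
enfaceProjection <- function(vol) {
  voxels <- if (is(vol, "LabelVolume")) vol@voxels else vol
  d <- dim(voxels)
  m <- matrix(voxels, nrow = d[1] * d[2], ncol = d[3])
  out <- m[, 1]
  for (k in seq_len(d[3])[-1]) out <- pmax(out, m[, k])
  matrix(out, d[1], d[2])
}

# 3D mm coordinates of every valid surface column (rows in en face linear
# order, NA rows where invalid).
.surfacePoints3d <- function(surface) {
  g <- surface@geom
  fast <- rep(seq_len(g@nFast) - 1L, times = g@nSlow)
  slow <- rep(seq_len(g@nSlow) - 1L, each = g@nFast)
  z <- as.vector(surface@zRpe)
  p <- matrix(NA_real_, length(z), 3)
  ok <- !is.na(z)
  d <- .rayDirection(fast[ok], slow[ok], g)
  p[ok, ] <- d * (g@pivotOffsetMm + z[ok] * g@depthStepMm)
  p
}

#' Read and write segmented label volumes
#'
#' Label volumes are exchanged as unsigned 8-bit NIfTI (\code{.nii} /
#' \code{.nii.gz}) or multi-page TIFF (one page per depth sample, each page
#' a fast x slow matrix). The scan geometry travels in a separate sidecar
#' (\code{\link{readScanGeometry}}).
#'
#' @param path volume file; format chosen by extension.
#' @param geom the matching \code{\linkS4class{ScanGeometry}}.
#' @return \code{readLabelVolume} returns a
#'   \code{\linkS4class{LabelVolume}}; \code{writeLabelVolume} returns
#'   \code{path} invisibly.
#' @export
readLabelVolume <- function(path, geom) {
  if (!file.exists(path)) ropStop("format", "volume file not found: ", path)
  arr <- tryCatch({
    if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
      a <- RNifti::readNifti(path)
      array(as.integer(round(a)), dim = dim(a))
    } else {
      pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      array(as.integer(round(unlist(pages))),
            dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
    }
  }, error = function(e) ropStop("format", "cannot parse volume file ", path,
                                 ": ", conditionMessage(e)))
  d <- dim(arr)
  if (!all(d == c(geom@nFast, geom@nSlow, geom@nDepth)))
    ropStop("geometry",
            sprintf("volume grid %dx%dx%d does not match geometry %dx%dx%d",
                    d[1], d[2], d[3], geom@nFast, geom@nSlow, geom@nDepth))
  LabelVolume(arr, geom)
}

#' @param vol a \code{LabelVolume} to serialize.
#' @rdname readLabelVolume
#' @export
writeLabelVolume <- function(vol, path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    RNifti::writeNifti(RNifti::asNifti(vol@voxels, datatype = "uint8"), path)
  } else {
    d <- dim(vol@voxels)
    pages <- lapply(seq_len(d[3]), function(k) vol@voxels[, , k] / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L, reduce = FALSE)
  }
  invisible(path)
}

#' Write an en face map as TIFF and CSV
#'
#' Utility for thickness maps and projections: the TIFF carries the map
#' rescaled to [0, 1] (display normalization is configurable through
#' \code{zlim}), the CSV the raw values.
#'
#' @param map numeric matrix over (fast, slow).
#' @param pathTiff,pathCsv output paths (either may be NULL to skip).
#' @param zlim display range for the TIFF; defaults to the finite data
#'   range.
#' @return invisible NULL.
#' @export
writeEnfaceMap <- function(map, pathTiff = NULL, pathCsv = NULL,
                           zlim = range(map, finite = TRUE)) {
  if (!is.null(pathTiff)) {
    m <- (map - zlim[1]) / max(zlim[2] - zlim[1], .Machine$double.eps)
    m[!is.finite(m)] <- 0
    tiff::writeTIFF(pmin(pmax(m, 0), 1), pathTiff, bits.per.sample = 16L)
  }
  if (!is.null(pathCsv))
    utils::write.csv(map, pathCsv, row.names = FALSE)
  invisible(NULL)
}
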