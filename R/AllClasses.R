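#' @import methods
NULL

# Index convention used throughout the package API and all on-disk formats:
# grid indices are 0-based triples (fast, slow, depth); fractional indices
# are permitted where a quantity lives between voxels. Lengths are mm,
# angles are degrees at every interface (radians only inside computations).

#' Scan geometry of a fan-beam OCT scanner
#'
#' Parameterizes the mapping from voxel indices \code{(fast, slow, depth)} to
#' physical 3D positions in mm. The model is a single-pivot equiangular fan:
#' every A-scan is a ray from a common pivot point, with the ray direction
#' obtained by rotating the central axis (+z) by the fast-axis angle about
#' the slow axis, then by the slow-axis angle about the fast axis. Sample
#' \code{depth} along a ray lies at radial distance
#' \code{pivotOffsetMm + depth * depthStepMm} from the pivot.
#'
#' @slot nFast number of A-scans per B-scan.
#' @slot nSlow number of B-scans.
#' @slot nDepth samples per A-scan.
#' @slot fovFastDeg,fovSlowDeg angular field of view (degrees), in (0, 180].
#' @slot depthStepMm axial sample spacing (mm).
#' @slot pivotOffsetMm radial distance from the pivot to depth sample 0 (mm).
#' @slot alScale,alOffsetMm calibration mapping the radial distance of the
#'   foveal RPE to axial length: \code{AL = alScale * r_fovea + alOffsetMm}.
#'   The phantom profile places the pivot at the globe center, so
#'   \code{alScale = 2}, \code{alOffsetMm = 0}.
#' @export
setClass("ScanGeometry", representation(
  nFast = "integer", nSlow = "integer", nDepth = "integer",
  fovFastDeg = "numeric", fovSlowDeg = "numeric",
  depthStepMm = "numeric", pivotOffsetMm = "numeric",
  alScale = "numeric", alOffsetMm = "numeric"
))

setValidity("ScanGeometry", function(object) {
  msg <- character()
  if (any(c(object@nFast, object@nSlow, object@nDepth) < 2L))
    msg <- c(msg, "all grid counts must be >= 2")
  if (any(c(object@fovFastDeg, object@fovSlowDeg) <= 0) ||
      any(c(object@fovFastDeg, object@fovSlowDeg) > 180))
    msg <- c(msg, "field-of-view angles must lie in (0, 180] degrees")
  if (object@depthStepMm <= 0) msg <- c(msg, "depthStepMm must be > 0")
  if (object@pivotOffsetMm < 0) msg <- c(msg, "pivotOffsetMm must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a ScanGeometry
#'
#' @param nFast,nSlow,nDepth grid dimensions (A-scans per B-scan, B-scans,
#'   depth samples).
#' @param fovFastDeg,fovSlowDeg angular field of view in degrees.
#' @param depthStepMm axial sample spacing in mm.
#' @param pivotOffsetMm radial distance from pivot to depth sample 0, mm.
#' @param alScale,alOffsetMm axial-length calibration (see
#'   \code{\linkS4class{ScanGeometry}}).
#' @return A \code{ScanGeometry} object.
#' @examples
#' g <- ScanGeometry(200, 200, 80, fovFastDeg = 140, fovSlowDeg = 140,
#'                   depthStepMm = 0.02, pivotOffsetMm = 7)
#' voxelToPhysical(c(99.5, 99.5, 10), g)
#' @export
ScanGeometry <- function(nFast, nSlow, nDepth, fovFastDeg = 140,
                         fovSlowDeg = 140, depthStepMm = 0.02,
                         pivotOffsetMm = 0, alScale = 2, alOffsetMm = 0) {
  new("ScanGeometry", nFast = as.integer(nFast), nSlow = as.integer(nSlow),
      nDepth = as.integer(nDepth), fovFastDeg = as.numeric(fovFastDeg),
      fovSlowDeg = as.numeric(fovSlowDeg),
      depthStepMm = as.numeric(depthStepMm),
      pivotOffsetMm = as.numeric(pivotOffsetMm),
      alScale = as.numeric(alScale), alOffsetMm = as.numeric(alOffsetMm))
}

setMethod("show", "ScanGeometry", function(object) {
  cat(sprintf("ScanGeometry: %d x %d A-scans, %d depth samples\n",
              object@nFast, object@nSlow, object@nDepth))
  cat(sprintf("  FOV %g x %g deg, depth step %g mm, pivot offset %g mm\n",
              object@fovFastDeg, object@fovSlowDeg, object@depthStepMm,
              object@pivotOffsetMm))
  cat(sprintf("  AL calibration: AL = %g * r_fovea + %g mm\n",
              object@alScale, object@alOffsetMm))
})

#' Segmented OCT label volume
#'
#' A 3D voxel grid of tissue labels (0 = background, 1 = retina,
#' 2 = choroid) with its scan geometry. Along each A-scan ray, retina voxels
#' must precede choroid voxels.
#'
#' @slot voxels integer array of dim \code{c(nFast, nSlow, nDepth)} with
#'   values in \{0, 1, 2\}.
#' @slot geom the \code{\linkS4class{ScanGeometry}}.
#' @export
setClass("LabelVolume", representation(voxels = "array",
                                       geom = "ScanGeometry"))

setValidity("LabelVolume", function(object) {
  g <- object@geom
  d <- dim(object@voxels)
  if (length(d) != 3L || !all(d == c(g@nFast, g@nSlow, g@nDepth)))
    return("voxel array dimensions must match the scan geometry grid")
  vals <- unique(as.vector(object@voxels))
  if (!all(vals %in% c(0L, 1L, 2L)))
    return("labels must be 0 (background), 1 (retina) or 2 (choroid)")
  TRUE
})

#' @param voxels,geom see slots.
#' @rdname LabelVolume-class
#' @export
LabelVolume <- function(voxels, geom) {
  storage.mode(voxels) <- "integer"
  new("LabelVolume", voxels = voxels, geom = geom)
}

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("LabelVolume: %d x %d x %d voxels (%.1f%% retina, %.1f%% choroid)\n",
              d[1], d[2], d[3], 100 * mean(object@voxels == 1L),
              100 * mean(object@voxels == 2L)))
})

#' RPE surface height field
#'
#' Per-column fractional depth index of the retina--choroid boundary (the
#' retinal pigment epithelium), extracted from a \code{LabelVolume}. Columns
#' lacking either tissue label are invalid (\code{NA} depth).
#'
#' @slot zRpe numeric matrix (nFast x nSlow) of 0-based fractional depth
#'   indices; \code{NA} where invalid.
#' @slot valid logical matrix marking columns with a usable boundary.
#' @slot geom the scan geometry.
#' @slot nMultiRun number of columns where the retina/choroid ordering was
#'   noisy and the last retina-to-choroid transition was used (QC counter).
#' @export
setClass("RpeSurface", representation(zRpe = "matrix", valid = "matrix",
                                      geom = "ScanGeometry",
                                      nMultiRun = "integer"))

setValidity("RpeSurface", function(object) {
  g <- object@geom
  if (!all(dim(object@zRpe) == c(g@nFast, g@nSlow)))
    return("zRpe dimensions must match the en face grid")
  if (!all(dim(object@valid) == dim(object@zRpe)))
    return("valid mask must match zRpe dimensions")
  z <- object@zRpe[object@valid]
  if (length(z) && (any(z < -0.5) || any(z > g@nDepth - 0.5)))
    return("zRpe values fall outside the depth range")
  TRUE
})

setMethod("show", "RpeSurface", function(object) {
  cat(sprintf("RpeSurface: %d x %d columns, %.1f%% valid\n",
              nrow(object@zRpe), ncol(object@zRpe), 100 * mean(object@valid)))
})

#' Retinal thickness map
#'
#' Per-column retinal thickness in mm, measured along each A-scan ray.
#'
#' @slot thicknessMm numeric matrix (nFast x nSlow).
#' @slot valid logical matrix; invalid where the column has no retina label.
#' @slot geom the scan geometry.
#' @export
setClass("ThicknessMap", representation(thicknessMm = "matrix",
                                        valid = "matrix",
                                        geom = "ScanGeometry"))

setValidity("ThicknessMap", function(object) {
  t <- object@thicknessMm[object@valid]
  if (length(t) && any(t < 0)) return("thickness must be >= 0")
  TRUE
})

#' Landmark annotations for one eye
#'
#' Manually annotated optic-disc edge points, foveal center, and
#' vascular--avascular border points, all as 0-based (fast, slow) en face
#' coordinates.
#'
#' @slot discEdge k x 2 matrix of ordered disc-edge points (k >= 3).
#' @slot fovea length-2 numeric, foveal center.
#' @slot border m x 2 matrix of ordered border points (m >= 2).
#' @slot laterality \code{"OD"} (right) or \code{"OS"} (left).
#' @export
setClass("LandmarkSet", representation(discEdge = "matrix", fovea = "numeric",
                                       border = "matrix",
                                       laterality = "character"))

setValidity("LandmarkSet", function(object) {
  msg <- character()
  if (nrow(object@discEdge) < 3L) msg <- c(msg, "need >= 3 disc-edge points")
  if (nrow(object@border) < 2L) msg <- c(msg, "need >= 2 border points")
  if (length(object@fovea) != 2L) msg <- c(msg, "fovea must be (fast, slow)")
  if (!object@laterality %in% c("OD", "OS"))
    msg <- c(msg, "laterality must be 'OD' or 'OS'")
  if (length(msg)) msg else TRUE
})

#' @param discEdge,fovea,border,laterality see slots.
#' @rdname LandmarkSet-class
#' @export
LandmarkSet <- function(discEdge, fovea, border, laterality = "OD") {
  new("LandmarkSet", discEdge = as.matrix(discEdge),
      fovea = as.numeric(fovea), border = as.matrix(border),
      laterality = laterality)
}

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet (%s): %d disc-edge points, %d border points, fovea (%.1f, %.1f)\n",
              object@laterality, nrow(object@discEdge), nrow(object@border),
              object@fovea[1], object@fovea[2]))
})

#' Rasterized contiguous border chain
#'
#' Ordered 8-connected grid cells connecting annotated points, with their 3D
#' positions on the RPE surface once lifted.
#'
#' @slot cells n x 2 integer matrix of 0-based (fast, slow) cells.
#' @slot points3d n x 3 matrix of mm coordinates (may have 0 rows before
#'   lifting onto a surface).
#' @export
setClass("BorderChain", representation(cells = "matrix", points3d = "matrix"))

setValidity("BorderChain", function(object) {
  cells <- object@cells
  if (nrow(cells) > 1L) {
    step <- abs(diff(cells))
    if (any(pmax(step[, 1], step[, 2]) > 1L))
      return("consecutive chain cells must be 8-connected")
  }
  if (nrow(object@points3d) && nrow(object@points3d) != nrow(cells))
    return("points3d must have one row per cell")
  TRUE
})

setMethod("show", "BorderChain", function(object) {
  cat(sprintf("BorderChain: %d cells%s\n", nrow(object@cells),
              if (nrow(object@points3d)) ", lifted to 3D" else ""))
})

#' Optic-disc centroid
#'
#' The 3D centroid of the rasterized disc-edge chain lifted to the RPE, and
#' its en face re-projection.
#'
#' @slot position3d mm coordinates of the centroid.
#' @slot enfaceCenter 0-based fractional (fast, slow) of the centroid's
#'   angular position.
#' @slot nInterpolated number of chain cells whose RPE depth had to be
#'   interpolated from neighbors (QC counter).
#' @export
setClass("DiscCentroid", representation(position3d = "numeric",
                                        enfaceCenter = "numeric",
                                        nInterpolated = "integer"))

setMethod("show", "DiscCentroid", function(object) {
  cat(sprintf("DiscCentroid: (%.3f, %.3f, %.3f) mm, en face (%.1f, %.1f)\n",
              object@position3d[1], object@position3d[2],
              object@position3d[3], object@enfaceCenter[1],
              object@enfaceCenter[2]))
})

#' Per-eye biomarkers
#'
#' Holds all quantitative zone measurements for one eye: axial length (AL),
#' foveal distance (FD), the array of retinal arclengths (RAL) to the
#' sampled vascular--avascular border, their mean and minimum, the
#' min-RAL:FD ratio, the spherical-cap area of vascularized retina (AVR),
#' the cap angle mean-RAL/AL, the assessed angle of the border, and the
#' mathematical zone classification.
#'
#' @slot axialLengthMm,fovealDistanceMm,meanRalMm,minRalMm,zoneRatio,avrMm2,capAngleRad,assessedAngleDeg scalars.
#' @slot ralMm per-sample arclengths (mm).
#' @slot fdChordMm straight-line 3D disc-to-fovea distance, retained for
#'   comparison with the geodesic FD.
#' @slot zoneMath one of \code{"I"}, \code{"PII"}, \code{"II+"}.
#' @slot nBorderSamples,nDroppedSamples sample counts (QC).
#' @export
setClass("EyeMetrics", representation(
  axialLengthMm = "numeric", fovealDistanceMm = "numeric",
  fdChordMm = "numeric", ralMm = "numeric", meanRalMm = "numeric",
  minRalMm = "numeric", zoneRatio = "numeric", avrMm2 = "numeric",
  capAngleRad = "numeric", assessedAngleDeg = "numeric",
  zoneMath = "character", nBorderSamples = "integer",
  nDroppedSamples = "integer"
))

setValidity("EyeMetrics", function(object) {
  msg <- character()
  if (length(object@ralMm)) {
    if (object@minRalMm > object@meanRalMm + 1e-9 ||
        object@meanRalMm > max(object@ralMm) + 1e-9)
      msg <- c(msg, "must satisfy min-RAL <= mean-RAL <= max(RAL)")
  }
  if (any(c(object@axialLengthMm, object@fovealDistanceMm,
            object@meanRalMm, object@minRalMm) <= 0))
    msg <- c(msg, "lengths must be positive")
  if (object@avrMm2 <= 0 ||
      object@avrMm2 > pi * object@axialLengthMm^2 + 1e-9)
    msg <- c(msg, "AVR must lie in (0, pi*AL^2]")
  if (!object@zoneMath %in% c("I", "PII", "II+"))
    msg <- c(msg, "zoneMath must be 'I', 'PII' or 'II+'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EyeMetrics", function(object) {
  cat("EyeMetrics:\n")
  cat(sprintf("  AL %.2f mm, FD %.2f mm (chord %.2f mm)\n",
              object@axialLengthMm, object@fovealDistanceMm,
              object@fdChordMm))
  cat(sprintf("  RAL: n = %d, mean %.2f mm, min %.2f mm\n",
              object@nBorderSamples, object@meanRalMm, object@minRalMm))
  cat(sprintf("  min-RAL:FD ratio %.2f, AVR %.1f mm^2, assessed angle %.1f deg\n",
              object@zoneRatio, object@avrMm2, object@assessedAngleDeg))
  cat(sprintf("  mathematical zone: %s\n", object@zoneMath))
})

#' Synthetic eye-phantom specification
#'
#' Describes an idealized spherical infant eye imaged by the fan-beam
#' scanner: a globe of radius R (axial length 2R), a uniform retinal shell
#' ending at the RPE sphere, a choroid shell beyond it, an optic disc and
#' fovea at known angular positions, and a vascular--avascular border at a
#' configurable angular radius about the disc (optionally with a notch).
#'
#' @slot sphereRadiusMm globe (RPE) radius R; axial length is 2R.
#' @slot retinaThicknessMm,choroidThicknessMm shell thicknesses (mm).
#' @slot discColatitudeDeg angular distance of the disc center from the scan
#'   axis (the fovea sits on the scan axis).
#' @slot discAngularRadiusDeg angular radius of the disc-edge circle.
#' @slot foveaOffsetDeg angular distance disc -> fovea (theta_f).
#' @slot borderBaseDeg base angular radius theta_b of the border about the
#'   disc.
#' @slot notchCenterDeg,notchWidthDeg,notchDepthDeg optional rectangular
#'   notch in the border profile: bearings within width/2 of the center
#'   bearing have angular radius theta_b - depth.
#' @slot borderSpanDeg half-span of annotated border bearings about the
#'   temporal meridian (clipped to the field of view at generation).
#' @slot ridgeThickeningMm extra retinal thickness in a band at the border.
#' @slot noise probability of flipping a label within one voxel of a tissue
#'   interface.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec", representation(
  sphereRadiusMm = "numeric", retinaThicknessMm = "numeric",
  choroidThicknessMm = "numeric", discColatitudeDeg = "numeric",
  discAngularRadiusDeg = "numeric", foveaOffsetDeg = "numeric",
  borderBaseDeg = "numeric", notchCenterDeg = "numeric",
  notchWidthDeg = "numeric", notchDepthDeg = "numeric",
  borderSpanDeg = "numeric", ridgeThickeningMm = "numeric",
  noise = "numeric", seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@sphereRadiusMm < 7 || object@sphereRadiusMm > 9)
    msg <- c(msg, "sphereRadiusMm must lie in [7, 9] (infant eye)")
  if (object@retinaThicknessMm <= 0 || object@choroidThicknessMm <= 0)
    msg <- c(msg, "shell thicknesses must be > 0")
  if (object@foveaOffsetDeg <= 0)
    msg <- c(msg, "foveaOffsetDeg must be > 0")
  prof <- c(object@borderBaseDeg, object@borderBaseDeg - object@notchDepthDeg)
  if (any(prof <= 0) || any(prof >= 180))
    msg <- c(msg, "border angular radii must lie in (0, 180) degrees")
  if (object@noise < 0 || object@noise > 1)
    msg <- c(msg, "noise must be a probability")
  if (length(msg)) msg else TRUE
})

#' @param sphereRadiusMm,retinaThicknessMm,choroidThicknessMm,discColatitudeDeg,discAngularRadiusDeg,foveaOffsetDeg,borderBaseDeg,notchCenterDeg,notchWidthDeg,notchDepthDeg,borderSpanDeg,ridgeThickeningMm,noise,seed see slots.
#' @rdname PhantomSpec-class
#' @export
PhantomSpec <- function(sphereRadiusMm = 7.7, retinaThicknessMm = 0.2,
                        choroidThicknessMm = 0.2, discColatitudeDeg = 28.3,
                        discAngularRadiusDeg = 3, foveaOffsetDeg = 28.3,
                        borderBaseDeg = 75, notchCenterDeg = 0,
                        notchWidthDeg = 0, notchDepthDeg = 0,
                        borderSpanDeg = 85, ridgeThickeningMm = 0.1,
                        noise = 0, seed = 1L) {
  new("PhantomSpec", sphereRadiusMm = sphereRadiusMm,
      retinaThicknessMm = retinaThicknessMm,
      choroidThicknessMm = choroidThicknessMm,
      discColatitudeDeg = discColatitudeDeg,
      discAngularRadiusDeg = discAngularRadiusDeg,
      foveaOffsetDeg = foveaOffsetDeg, borderBaseDeg = borderBaseDeg,
      notchCenterDeg = notchCenterDeg, notchWidthDeg = notchWidthDeg,
      notchDepthDeg = notchDepthDeg, borderSpanDeg = borderSpanDeg,
      ridgeThickeningMm = ridgeThickeningMm, noise = noise,
      seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: R = %g mm (AL %g mm), disc at %g deg, fovea offset %g deg\n",
              object@sphereRadiusMm, 2 * object@sphereRadiusMm,
              object@discColatitudeDeg, object@foveaOffsetDeg))
  cat(sprintf("  border at %g deg about the disc", object@borderBaseDeg))
  if (object@notchWidthDeg > 0)
    cat(sprintf(" with a %g deg notch (width %g deg) at bearing %g deg",
                object@notchDepthDeg, object@notchWidthDeg,
                object@notchCenterDeg))
  cat(sprintf("; noise %g, seed %d\n", object@noise, object@seed))
})

#' Analytic ground truth for a phantom
#'
#' Closed-form values implied by a \code{\linkS4class{PhantomSpec}}: the
#' geodesic foveal distance R*theta_f, the retinal arclength R*theta_b at
#' each sampled bearing, their mean and minimum, the printed spherical-cap
#' AVR at (mean-RAL, 2R), the true spherical-cap area on the R-sphere, the
#' assessed angle, and the expected mathematical zone.
#'
#' @slot fdMm,meanRalMm,minRalMm,avrMm2,trueCapAreaMm2,assessedAngleDeg scalars.
#' @slot bearingsDeg,ralMm the sampled bearings about the temporal meridian
#'   and the per-bearing true arclengths.
#' @slot zone expected zone label.
#' @export
setClass("PhantomTruth", representation(
  fdMm = "numeric", bearingsDeg = "numeric", ralMm = "numeric",
  meanRalMm = "numeric", minRalMm = "numeric", avrMm2 = "numeric",
  trueCapAreaMm2 = "numeric", assessedAngleDeg = "numeric",
  zone = "character"
))

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: FD %.3f mm, mean-RAL %.3f mm, min-RAL %.3f mm\n",
              object@fdMm, object@meanRalMm, object@minRalMm))
  cat(sprintf("  AVR %.1f mm^2 (true cap %.1f mm^2), assessed angle %.1f deg, zone %s\n",
              object@avrMm2, object@trueCapAreaMm2, object@assessedAngleDeg,
              object@zone))
})

#' Cluster-bootstrap result
#'
#' @slot estimate point estimate on the full table.
#' @slot ciLow,ciHigh percentile 2.5/97.5 bootstrap confidence limits.
#' @slot nReplicates,nClusters,nRedraws,seed bookkeeping.
#' @slot replicates the replicate statistics.
#' @slot ciFlag TRUE if the point estimate falls outside the percentile
#'   interval (possible for strongly skewed replicate distributions; flagged
#'   rather than treated as an error).
#' @export
setClass("BootstrapResult", representation(
  estimate = "numeric", ciLow = "numeric", ciHigh = "numeric",
  nReplicates = "integer", nClusters = "integer", nRedraws = "integer",
  seed = "integer", replicates = "numeric", ciFlag = "logical"
))

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf("BootstrapResult: %.4f (95%% CI %.4f-%.4f), %d replicates over %d clusters (seed %d)\n",
              object@estimate, object@ciLow, object@ciHigh,
              object@nReplicates, object@nClusters, object@seed))
  if (object@nRedraws > 0L)
    cat(sprintf("  %d replicates redrawn (undefined statistic)\n",
                object@nRedraws))
  if (object@ciFlag)
    cat("  note: point estimate outside the percentile interval\n")
})
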