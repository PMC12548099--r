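# Synthetic infant-eye phantom: a spherical globe imaged by the fan-beam
# scanner with the pivot at the globe center, so every geodesic truth is an
# exact great-circle arc R * theta. The fovea sits in the x-z plane near
# the scan axis, the disc nasal to it, and the vascular-avascular border is
# a small circle of (optionally notched) angular radius about the disc.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# unit vectors and tangent frame of the phantom anatomy
.phantomFrame <- function(spec) {
  thD <- .deg2rad(spec@discColatitudeDeg)
  ud <- c(-sin(thD), 0, cos(thD))                    # disc center direction
  phF <- -thD + .deg2rad(spec@foveaOffsetDeg)        # fovea in the x-z plane
  uf <- c(sin(phF), 0, cos(phF))
  e1 <- uf - sum(uf * ud) * ud                       # toward the fovea
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(ud[2] * e1[3] - ud[3] * e1[2],
          ud[3] * e1[1] - ud[1] * e1[3],
          ud[1] * e1[2] - ud[2] * e1[1])
  list(ud = ud, uf = uf, e1 = e1, e2 = e2)
}

# border angular radius (deg) as a function of bearing (deg) about the disc
.borderProfileDeg <- function(spec, bearingDeg) {
  th <- rep(spec@borderBaseDeg, length(bearingDeg))
  if (spec@notchWidthDeg > 0 && spec@notchDepthDeg > 0) {
    inNotch <- abs(bearingDeg - spec@notchCenterDeg) < spec@notchWidthDeg / 2
    th[inNotch] <- th[inNotch] - spec@notchDepthDeg
  }
  th
}

# point on the unit sphere at angular radius theta (rad) and bearing phi
# (rad) about the disc; bearing 0 points toward the fovea
.diskOffsetPoint <- function(frame, theta, phi) {
  ct <- cos(theta); st <- sin(theta)
  cbind(ct * frame$ud[1] + st * (cos(phi) * frame$e1[1] + sin(phi) * frame$e2[1]),
        ct * frame$ud[2] + st * (cos(phi) * frame$e1[2] + sin(phi) * frame$e2[2]),
        ct * frame$ud[3] + st * (cos(phi) * frame$e1[3] + sin(phi) * frame$e2[3]))
}

#' Default scan geometry for a phantom
#'
#' The central-pivot profile: the scan pivot sits at the globe center
#' (\code{alScale = 2}), the depth window brackets the retina and choroid
#' shells, and the en face grid defaults to 400 x 400 over a 140-degree
#' field of view.
#'
#' @param spec a \code{\linkS4class{PhantomSpec}}.
#' @param nEnface en face grid size (used for both axes).
#' @param depthStepMm axial sample spacing, mm.
#' @param marginMm padding beyond the tissue shells at both depth ends.
#' @return A \code{\linkS4class{ScanGeometry}}.
#' @export
phantomGeometry <- function(spec, nEnface = 400L, depthStepMm = 0.02,
                            marginMm = 0.15) {
  inner <- spec@sphereRadiusMm - spec@retinaThicknessMm -
    spec@ridgeThickeningMm - marginMm
  span <- spec@retinaThicknessMm + spec@ridgeThickeningMm +
    spec@choroidThicknessMm + 2 * marginMm
  ScanGeometry(nEnface, nEnface, ceiling(span / depthStepMm) + 1L,
               fovFastDeg = 140, fovSlowDeg = 140,
               depthStepMm = depthStepMm, pivotOffsetMm = inner,
               alScale = 2, alOffsetMm = 0)
}

#' Generate a synthetic eye phantom
#'
#' Builds a segmented label volume, matching landmark annotations, and
#' closed-form ground truth for a spherical infant eye. Each A-scan is
#' labeled retina over the radial interval \code{[R - t, R]} (with t
#' locally increased by the ridge thickening in a band at the border) and
#' choroid over \code{(R, R + choroidThickness]}. Landmarks are emitted at
#' the grid projections of the configured disc-edge circle, fovea, and
#' border locus; border bearings whose points fall outside the field of
#' view are clipped. Ground truth (FD = R * theta_f, RAL(bearing) =
#' R * theta_b(bearing), the printed-formula AVR at (mean-RAL, 2R), the
#' exact cap area, and the expected zone) follows in closed form. The
#' result is deterministic given the spec's seed.
#'
#' @param spec a \code{\linkS4class{PhantomSpec}}.
#' @param geom optional \code{\linkS4class{ScanGeometry}}; defaults to
#'   \code{phantomGeometry(spec, nEnface)}.
#' @param nEnface en face grid size when \code{geom} is not supplied.
#' @param discDiameterMm disc diameter used for the expected zone label.
#' @return A list with \code{volume} (\code{LabelVolume}),
#'   \code{landmarks} (\code{LandmarkSet}), \code{truth}
#'   (\code{PhantomTruth}) and \code{geom}.
#' @export
generatePhantom <- function(spec, geom = NULL, nEnface = 400L,
                            discDiameterMm = 1.1) {
  validObject(spec)
  if (is.null(geom)) geom <- phantomGeometry(spec, nEnface)
  R <- spec@sphereRadiusMm
  maxDepthMm <- geom@pivotOffsetMm + (geom@nDepth - 1L) * geom@depthStepMm
  if (R + spec@choroidThicknessMm > maxDepthMm ||
      R - spec@retinaThicknessMm - spec@ridgeThickeningMm < geom@pivotOffsetMm)
    ropStop("config",
            sprintf("globe (R = %g mm) does not fit the depth window [%g, %g] mm",
                    R, geom@pivotOffsetMm, maxDepthMm))
  frame <- .phantomFrame(spec)

  # per-column direction, disc-relative colatitude and bearing
  nf <- geom@nFast; ns <- geom@nSlow
  fast <- rep(seq_len(nf) - 1L, times = ns)
  slow <- rep(seq_len(ns) - 1L, each = nf)
  dirs <- .rayDirection(fast, slow, geom)
  cosTh <- pmin(1, pmax(-1, dirs %*% frame$ud))
  bearing <- atan2(dirs %*% frame$e2, dirs %*% frame$e1)
  thetaCol <- acos(cosTh)

  # retinal thickness per column: base shell plus a ridge band straddling
  # the border locus
  tcol <- rep(spec@retinaThicknessMm, nf * ns)
  if (spec@ridgeThickeningMm > 0) {
    thB <- .deg2rad(.borderProfileDeg(spec, .rad2deg(as.vector(bearing))))
    band <- abs(as.vector(thetaCol) - thB) < .deg2rad(1.5)
    tcol[band] <- tcol[band] + spec@ridgeThickeningMm
  }

  m <- matrix(0L, nf * ns, geom@nDepth)
  radii <- geom@pivotOffsetMm + (seq_len(geom@nDepth) - 1L) * geom@depthStepMm
  for (k in seq_len(geom@nDepth)) {
    r <- radii[k]
    if (r <= R) m[r >= R - tcol, k] <- 1L
    else if (r <= R + spec@choroidThicknessMm) m[, k] <- 2L
  }
  if (spec@noise > 0) m <- .withSeed(spec@seed, .flipInterfaceLabels(m, spec@noise))
  vol <- LabelVolume(array(m, dim = c(nf, ns, geom@nDepth)), geom)

  # landmarks at the exact grid projections of the configured anatomy
  toIndex <- function(unitDirs) {
    idx <- physicalToVoxel(unitDirs * R, geom)
    round(idx[, 1:2, drop = FALSE])
  }
  inGrid <- function(idx)
    idx[, 1] >= 1 & idx[, 1] <= nf - 2 & idx[, 2] >= 1 & idx[, 2] <= ns - 2
  discPts <- .diskOffsetPoint(frame, .deg2rad(spec@discAngularRadiusDeg),
                              .deg2rad(seq(0, 330, by = 30)))
  discIdx <- toIndex(discPts)
  foveaIdx <- toIndex(matrix(frame$uf, 1))
  if (!all(inGrid(discIdx)) || !inGrid(foveaIdx))
    ropStop("config", "disc or fovea falls outside the field of view")

  bearGrid <- seq(-spec@borderSpanDeg, spec@borderSpanDeg, by = 1)
  borderPts <- .diskOffsetPoint(frame, .deg2rad(.borderProfileDeg(spec, bearGrid)),
                                .deg2rad(bearGrid))
  borderIdx <- toIndex(borderPts)
  keep <- inGrid(borderIdx)
  if (!any(keep))
    ropStop("config", "border lies entirely outside the field of view")
  borderIdx <- borderIdx[keep, , drop = FALSE]
  bearKept <- bearGrid[keep]
  landmarks <- LandmarkSet(discEdge = discIdx, fovea = as.numeric(foveaIdx),
                           border = borderIdx, laterality = "OD")

  truth <- .phantomTruth(spec, range(bearKept), discDiameterMm)
  list(volume = vol, landmarks = landmarks, truth = truth, geom = geom)
}

# closed-form truth over the emitted bearing range
.phantomTruth <- function(spec, bearRange, discDiameterMm = 1.1) {
  R <- spec@sphereRadiusMm
  bg <- seq(bearRange[1], bearRange[2], by = 0.5)
  ral <- R * .deg2rad(.borderProfileDeg(spec, bg))
  fd <- R * .deg2rad(spec@foveaOffsetDeg)
  meanRal <- mean(ral); minRal <- min(ral)
  z <- classifyZoneMath(minRal, fd, discDiameterMm)
  new("PhantomTruth", fdMm = fd, bearingsDeg = bg, ralMm = ral,
      meanRalMm = meanRal, minRalMm = minRal,
      avrMm2 = sphericalCapAvr(meanRal, 2 * R),
      trueCapAreaMm2 = trueCapArea(R, meanRal),
      assessedAngleDeg = diff(bearRange), zone = z$zone)
}

# boundary-uncertainty noise: a voxel adjacent (along depth) to a voxel
# with a different label takes its neighbor's label with probability p
.flipInterfaceLabels <- function(m, p) {
  nd <- ncol(m)
  nextDiff <- cbind(m[, -1] != m[, -nd], FALSE)
  prevDiff <- cbind(FALSE, m[, -nd] != m[, -1])
  atInterface <- which(nextDiff | prevDiff)
  flip <- atInterface[stats::runif(length(atInterface)) < p]
  for (i in flip) {
    row <- (i - 1L) %% nrow(m) + 1L
    col <- (i - 1L) %/% nrow(m) + 1L
    src <- if (col < nd && m[row, col + 1L] != m[row, col]) col + 1L else col - 1L
    if (src >= 1L) m[row, col] <- m[row, src]
  }
  m
}

#' Read and write phantom specifications
#'
#' Phantom specs travel as JSON or YAML with snake_case field names
#' (\code{sphere_radius_mm}, \code{retina_thickness_mm},
#' \code{choroid_thickness_mm}, \code{disc_colatitude_deg},
#' \code{disc_angular_radius_deg}, \code{fovea_offset_deg},
#' \code{border_base_deg}, \code{notch_center_deg}, \code{notch_width_deg},
#' \code{notch_depth_deg}, \code{border_span_deg},
#' \code{ridge_thickening_mm}, \code{noise}, \code{seed}); missing fields
#' take the \code{\link{PhantomSpec}} defaults.
#'
#' @param path spec file path.
#' @return \code{readPhantomSpec} returns a
#'   \code{\linkS4class{PhantomSpec}}; \code{writePhantomSpec} returns
#'   \code{path} invisibly.
#' @export
readPhantomSpec <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  args <- list(sphereRadiusMm = x$sphere_radius_mm,
               retinaThicknessMm = x$retina_thickness_mm,
               choroidThicknessMm = x$choroid_thickness_mm,
               discColatitudeDeg = x$disc_colatitude_deg,
               discAngularRadiusDeg = x$disc_angular_radius_deg,
               foveaOffsetDeg = x$fovea_offset_deg,
               borderBaseDeg = x$border_base_deg,
               notchCenterDeg = x$notch_center_deg,
               notchWidthDeg = x$notch_width_deg,
               notchDepthDeg = x$notch_depth_deg,
               borderSpanDeg = x$border_span_deg,
               ridgeThickeningMm = x$ridge_thickening_mm,
               noise = x$noise, seed = x$seed)
  do.call(PhantomSpec, args[!vapply(args, is.null, logical(1))])
}

#' @param spec a \code{PhantomSpec} to serialize.
#' @rdname readPhantomSpec
#' @export
writePhantomSpec <- function(spec, path) {
  x <- list(sphere_radius_mm = spec@sphereRadiusMm,
            retina_thickness_mm = spec@retinaThicknessMm,
            choroid_thickness_mm = spec@choroidThicknessMm,
            disc_colatitude_deg = spec@discColatitudeDeg,
            disc_angular_radius_deg = spec@discAngularRadiusDeg,
            fovea_offset_deg = spec@foveaOffsetDeg,
            border_base_deg = spec@borderBaseDeg,
            notch_center_deg = spec@notchCenterDeg,
            notch_width_deg = spec@notchWidthDeg,
            notch_depth_deg = spec@notchDepthDeg,
            border_span_deg = spec@borderSpanDeg,
            ridge_thickening_mm = spec@ridgeThickeningMm,
            noise = spec@noise, seed = spec@seed)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(x, path)
  invisible(path)
}
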