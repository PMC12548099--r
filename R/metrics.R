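#' Spherical-cap area of vascularized retina
#'
#' Evaluates the cap formula \code{(pi * AL^2 / 2) * (1 - cos(meanRAL /
#' AL))} with the axial length AL as the size parameter and mean-RAL / AL
#' as the cap angle. The formula is implemented verbatim in this
#' parameterization (AL enters the angle as a radius but the prefactor as
#' half of \code{pi * AL^2}); no geometric correction is applied, since the
#' published group-mean AVR values arise from exactly this form.
#' \code{\link{trueCapArea}} gives the geometrically exact cap area on a
#' sphere of known radius for phantom reference.
#'
#' @param meanRal mean retinal arclength, mm; must lie in
#'   \code{[0, pi * al]}.
#' @param al axial length, mm.
#' @return Area in mm^2.
#' @examples
#' sphericalCapAvr(10.3, 15.4)   # about 80.3 mm^2
#' @export
sphericalCapAvr <- function(meanRal, al) {
  if (al <= 0) ropStop("measurement", "axial length must be positive")
  if (meanRal < 0) ropStop("measurement", "mean-RAL must be non-negative")
  if (meanRal > pi * al)
    ropStop("measurement",
            sprintf("mean-RAL %.3f exceeds pi * AL = %.3f (beyond the full sphere)",
                    meanRal, pi * al))
  (pi * al^2 / 2) * (1 - cos(meanRal / al))
}

#' Exact spherical-cap area
#'
#' Reference cap area \code{2 * pi * r^2 * (1 - cos(s / r))} for a cap of
#' geodesic radius \code{s} on a sphere of radius \code{r}; used as the
#' geometric ground truth on phantoms.
#'
#' @param r sphere radius, mm.
#' @param s geodesic cap radius (arclength from the cap pole), mm.
#' @return Area in mm^2.
#' @export
trueCapArea <- function(r, s) 2 * pi * r^2 * (1 - cos(s / r))

#' Mathematical zone classification
#'
#' Zone I is the circle of radius twice the foveal distance about the optic
#' disc, so an eye is mathematically zone I iff its most posterior border
#' point satisfies \code{minRal < 2 * fd} (strictly; a border exactly on
#' the circle is not inside it). Posterior zone II extends a further two
#' disc diameters: \code{minRal < 2 * fd + 2 * discDiameter}. Anything
#' beyond is reported as \code{"II+"}. The continuous counterpart
#' \code{zoneRatio = minRal / fd} is returned alongside.
#'
#' @param minRal minimum retinal arclength, mm.
#' @param fd foveal distance, mm.
#' @param discDiameter optic-disc diameter, mm; the classification needs it
#'   for the posterior zone II band and no consensus infant value exists,
#'   so it is a required, config-exposed parameter (default 1.1).
#' @return A list with \code{zone} (\code{"I"}, \code{"PII"} or
#'   \code{"II+"}) and \code{zoneRatio}.
#' @examples
#' classifyZoneMath(8.8, 4.5)    # ratio 1.96, zone I
#' classifyZoneMath(13.6, 4.7)   # ratio 2.89, zone II+
#' @export
classifyZoneMath <- function(minRal, fd, discDiameter = 1.1) {
  if (any(c(minRal, fd, discDiameter) <= 0))
    ropStop("measurement", "zone classification needs positive inputs")
  zone <- if (minRal < 2 * fd) "I"
          else if (minRal < 2 * fd + 2 * discDiameter) "PII"
          else "II+"
  list(zone = zone, zoneRatio = minRal / fd)
}

#' Assemble all per-eye biomarkers
#'
#' Summarizes a retinal-arclength array into the full biomarker set: mean-
#' and min-RAL, the spherical-cap AVR at (mean-RAL, AL), the min-RAL:FD
#' ratio and mathematical zone, and the cap angle mean-RAL / AL. The mean
#' is the unweighted arithmetic mean of all retained samples.
#'
#' @param ral numeric vector of retinal arclengths, mm (non-empty).
#' @param fd foveal distance, mm.
#' @param al axial length, mm.
#' @param assessedAngleDeg assessed angle of the border, degrees.
#' @param discDiameter optic-disc diameter for the PII band, mm.
#' @param fdChordMm optional straight-line disc-to-fovea distance, mm.
#' @param nDropped number of border samples dropped during measurement.
#' @return An \code{\linkS4class{EyeMetrics}} object.
#' @export
summarizeMetrics <- function(ral, fd, al, assessedAngleDeg,
                             discDiameter = 1.1, fdChordMm = NA_real_,
                             nDropped = 0L) {
  if (!length(ral))
    ropStop("measurement", "cannot summarize an empty arclength array")
  meanRal <- mean(ral)
  minRal <- min(ral)
  z <- classifyZoneMath(minRal, fd, discDiameter)
  new("EyeMetrics",
      axialLengthMm = al, fovealDistanceMm = fd, fdChordMm = fdChordMm,
      ralMm = ral, meanRalMm = meanRal, minRalMm = minRal,
      zoneRatio = z$zoneRatio, avrMm2 = sphericalCapAvr(meanRal, al),
      capAngleRad = meanRal / al, assessedAngleDeg = assessedAngleDeg,
      zoneMath = z$zone, nBorderSamples = length(ral),
      nDroppedSamples = as.integer(nDropped))
}

#' One-row data frame of eye metrics
#'
#' Columns carry the row labels used in clinical summary tables
#' (\code{AL}, \code{FD}, \code{mean-RAL}, \code{min-RAL},
#' \code{min-RAL:FD ratio}, \code{AVR}) plus \code{assessed_angle},
#' \code{zone_math} and QC counters.
#'
#' @param x an \code{\linkS4class{EyeMetrics}}.
#' @param row.names,optional,... passed for generic compatibility; unused.
#' @return A one-row \code{data.frame}.
#' @export
as.data.frame.EyeMetrics <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(check.names = FALSE,
             `AL` = x@axialLengthMm, `FD` = x@fovealDistanceMm,
             `mean-RAL` = x@meanRalMm, `min-RAL` = x@minRalMm,
             `min-RAL:FD ratio` = x@zoneRatio, `AVR` = x@avrMm2,
             assessed_angle = x@assessedAngleDeg, zone_math = x@zoneMath,
             fd_chord = x@fdChordMm, cap_angle_rad = x@capAngleRad,
             n_border_samples = x@nBorderSamples,
             n_dropped_samples = x@nDroppedSamples)
}

#' Write eye metrics to CSV
#'
#' @param metrics an \code{\linkS4class{EyeMetrics}} or list of them.
#' @param path output CSV path.
#' @return \code{path} invisibly.
#' @export
writeEyeMetrics <- function(metrics, path) {
  if (is(metrics, "EyeMetrics")) metrics <- list(metrics)
  df <- do.call(rbind, lapply(metrics, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
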