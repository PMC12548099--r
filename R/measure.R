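# End-to-end measurement pipeline: label volume + landmarks -> surface ->
# disc centroid and border chain -> geodesic arclengths -> biomarkers.

#' Measure all zone biomarkers for one eye
#'
#' Runs the full pipeline on in-memory objects: extracts the RPE surface,
#' locates the 3D disc centroid from the annotated disc edge, rasterizes
#' and lifts the vascular-avascular border, resamples it at
#' \code{density} points per clock hour over the temporal hemisphere,
#' measures geodesic arclengths from the disc centroid to every border
#' sample and to the fovea (one surface graph, one shortest-path pass),
#' estimates axial length from the foveal RPE depth (unless a measured
#' value is supplied), and assembles the \code{\linkS4class{EyeMetrics}}.
#'
#' @param vol a \code{\linkS4class{LabelVolume}}.
#' @param landmarks a \code{\linkS4class{LandmarkSet}}.
#' @param density border samples per clock hour (default 10).
#' @param discDiameter optic-disc diameter (mm) for the posterior zone II
#'   band (default 1.1).
#' @param neighborhood geodesic graph neighborhood, 8 or 16 (default 16).
#' @param measuredAl optional measured axial length (mm); takes precedence
#'   over the OCT-derived estimate.
#' @return A list with \code{metrics} (\code{EyeMetrics}), \code{surface},
#'   \code{disc}, \code{samples} (the resampled border) and
#'   \code{thickness} (a \code{ThicknessMap}).
#' @export
measureEye <- function(vol, landmarks, density = 10, discDiameter = 1.1,
                       neighborhood = 16L, measuredAl = NULL) {
  geom <- vol@geom
  validateLandmarks(landmarks, geom)
  surface <- extractRpeSurface(vol)
  disc <- discCentroid3d(landmarks@discEdge, surface, geom)
  chain <- liftChain(bresenhamChain(landmarks@border), surface)
  samples <- resampleBorder(chain, disc, landmarks@fovea, density,
                            landmarks@laterality)
  if (!nrow(samples$points3d))
    ropStop("measurement", "no temporal border samples available")
  angle <- assessedAngle(chain, disc, landmarks@fovea, landmarks@laterality)
  zF <- .interpSurfaceDepth(surface, landmarks@fovea[1], landmarks@fovea[2])
  if (is.na(zF))
    ropStop("measurement", "fovea falls on an invalid surface column")
  foveaP <- voxelToPhysical(c(landmarks@fovea[1], landmarks@fovea[2], zF),
                            geom)[1, ]
  sg <- .surfaceGraph(surface, neighborhood)
  d <- .geodesicMany(surface, disc@position3d,
                     rbind(samples$points3d, foveaP), graph = sg)
  ral <- d[seq_len(nrow(samples$points3d))]
  fd <- d[length(d)]
  bad <- !is.finite(ral)
  if (any(bad)) {
    warning(sprintf("%d border samples unreachable on the surface; dropped",
                    sum(bad)))
    ral <- ral[!bad]
  }
  if (!length(ral) || !is.finite(fd))
    ropStop("measurement", "geodesic measurement failed: surface disconnected")
  al <- estimateAxialLength(surface, landmarks@fovea, geom, measuredAl)
  metrics <- summarizeMetrics(ral, fd, al, angle, discDiameter,
                              fdChordMm = sqrt(sum((foveaP - disc@position3d)^2)),
                              nDropped = sum(bad))
  list(metrics = metrics, surface = surface, disc = disc, samples = samples,
       thickness = thicknessMap(vol))
}

.provenance <- function(config, seed = NA_integer_) {
  cfgJson <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfgJson, tmp)
  on.exit(unlink(tmp))
  list(software = "ropzone",
       version = as.character(utils::packageVersion("ropzone")),
       config = config, config_md5 = unname(tools::md5sum(tmp)),
       seed = seed)
}

#' Measure one eye from files
#'
#' File-level front end of \code{\link{measureEye}}: reads the volume,
#' geometry sidecar and landmark annotations, runs the pipeline, and
#' writes \code{metrics.csv} (with QC counters), a thickness-map TIFF, an
#' en face projection TIFF with the sampled border and disc center burned
#' in, and a \code{provenance.json} recording the configuration, its MD5
#' hash and the package version.
#'
#' @param volumePath label volume (NIfTI or multi-page TIFF).
#' @param landmarksPath landmark JSON.
#' @param geometryPath geometry sidecar (JSON or YAML).
#' @param outDir output directory (created if needed).
#' @param density,discDiameter,neighborhood,measuredAl see
#'   \code{\link{measureEye}}.
#' @return The \code{measureEye} result, invisibly.
#' @export
cmdMeasure <- function(volumePath, landmarksPath, geometryPath, outDir,
                       density = 10, discDiameter = 1.1, neighborhood = 16L,
                       measuredAl = NULL) {
  geom <- readScanGeometry(geometryPath)
  vol <- readLabelVolume(volumePath, geom)
  lms <- readLandmarks(landmarksPath)
  res <- measureEye(vol, lms, density = density, discDiameter = discDiameter,
                    neighborhood = neighborhood, measuredAl = measuredAl)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeEyeMetrics(res$metrics, file.path(outDir, "metrics.csv"))
  writeEnfaceMap(res$thickness@thicknessMm,
                 file.path(outDir, "thickness.tiff"),
                 file.path(outDir, "thickness.csv"))
  ef <- enfaceProjection(vol)
  ov <- ef / max(ef, 1)
  cells <- res$samples$cells
  ov[cbind(cells[, 1] + 1L, cells[, 2] + 1L)] <- 1
  ctr <- round(res$disc@enfaceCenter)
  ov[ctr[1] + 1L, ctr[2] + 1L] <- 1
  tiff::writeTIFF(ov, file.path(outDir, "enface_border.tiff"),
                  bits.per.sample = 8L)
  prov <- .provenance(list(density = density, disc_diameter = discDiameter,
                           neighborhood = neighborhood,
                           measured_al = measuredAl,
                           volume = basename(volumePath),
                           landmarks = basename(landmarksPath)))
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Generate a phantom bundle on disk
#'
#' Writes everything the measurement pipeline consumes for a synthetic
#' eye: the label volume (NIfTI), the landmark JSON, the geometry sidecar,
#' the closed-form truth table (CSV) and a provenance record. Byte-for-
#' byte deterministic given the spec's seed.
#'
#' @param spec a \code{\linkS4class{PhantomSpec}} or a path to a spec file
#'   (see \code{\link{readPhantomSpec}}).
#' @param outDir output directory.
#' @param nEnface en face grid size.
#' @return File paths, invisibly.
#' @export
cmdPhantom <- function(spec, outDir, nEnface = 400L) {
  if (is.character(spec)) spec <- readPhantomSpec(spec)
  ph <- generatePhantom(spec, nEnface = nEnface)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(volume = file.path(outDir, "volume.nii.gz"),
                landmarks = file.path(outDir, "landmarks.json"),
                geometry = file.path(outDir, "geometry.json"),
                truth = file.path(outDir, "truth.csv"),
                spec = file.path(outDir, "phantom_spec.json"))
  writeLabelVolume(ph$volume, paths$volume)
  writeLandmarks(ph$landmarks, paths$landmarks)
  writeScanGeometry(ph$geom, paths$geometry)
  writePhantomSpec(spec, paths$spec)
  tr <- ph$truth
  utils::write.csv(data.frame(
    quantity = c("fd_mm", "mean_ral_mm", "min_ral_mm", "avr_mm2",
                 "true_cap_area_mm2", "assessed_angle_deg", "axial_length_mm"),
    value = c(tr@fdMm, tr@meanRalMm, tr@minRalMm, tr@avrMm2,
              tr@trueCapAreaMm2, tr@assessedAngleDeg,
              2 * spec@sphereRadiusMm),
    zone = tr@zone), paths$truth, row.names = FALSE)
  invisible(paths)
}

#' Read and write eye-level cohort tables
#'
#' CSV round trip for the cohort schema (see
#' \code{\link{validateCohortTable}}).
#'
#' @param path CSV path.
#' @return \code{readCohortTable} returns a validated \code{data.frame}.
#' @export
readCohortTable <- function(path) {
  if (!file.exists(path)) ropStop("format", "cohort table not found: ", path)
  validateCohortTable(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @param table cohort table to serialize.
#' @rdname readCohortTable
#' @export
writeCohortTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Run a cohort analysis from a table file
#'
#' Analyses: \code{"auroc"} (cluster-bootstrap AUROC of \code{predictor}
#' for \code{outcome}), \code{"compare"} (paired AUROC difference of
#' \code{predictor} vs \code{predictor2}), \code{"group_diff"} (mean of
#' \code{metric} in \code{groupB} minus \code{groupA}, with bootstrap CI),
#' and \code{"pearson"} (correlation of \code{predictor} and
#' \code{predictor2} on one randomly selected eye per patient). Results,
#' the seed and the replicate count are written as JSON when \code{outPath}
#' is given.
#'
#' @param table cohort \code{data.frame} or CSV path.
#' @param analysis one of \code{"auroc"}, \code{"compare"},
#'   \code{"group_diff"}, \code{"pearson"}.
#' @param predictor,predictor2,outcome,metric,groupA,groupB column names /
#'   group labels as required by the analysis.
#' @param nReps,seed bootstrap settings.
#' @param outPath optional JSON output path.
#' @return A named list with the analysis results.
#' @export
cmdCohort <- function(table, analysis = c("auroc", "compare", "group_diff",
                                          "pearson"),
                      predictor = "mean_ral_mm", predictor2 = "min_ral_mm",
                      outcome = "treated", metric = "mean_ral_mm",
                      groupA = "I", groupB = "II", nReps = 2000L, seed = 1L,
                      outPath = NULL) {
  analysis <- match.arg(analysis)
  if (is.character(table)) table <- readCohortTable(table)
  validateCohortTable(table)
  out <- switch(analysis,
    auroc = {
      validateCohortTable(table, usedCols = c(predictor, outcome))
      br <- clusterBootstrap(table, aurocStat(predictor, outcome),
                             nReps = nReps, seed = seed)
      list(analysis = "auroc", predictor = predictor, outcome = outcome,
           estimate = br@estimate, ci_low = br@ciLow, ci_high = br@ciHigh,
           n_reps = br@nReplicates, seed = br@seed,
           n_clusters = br@nClusters, n_redraws = br@nRedraws)
    },
    compare = {
      cp <- comparePredictors(table, predictor, predictor2, outcome,
                              nReps = nReps, seed = seed)
      list(analysis = "compare", predictor_a = predictor,
           predictor_b = predictor2, outcome = outcome,
           estimate = cp$estimate, mean_diff = cp$meanDiff,
           ci_low = cp$ciLow, ci_high = cp$ciHigh,
           significant = cp$significant, n_reps = nReps, seed = seed)
    },
    group_diff = {
      gd <- groupDifference(table, metric, groupA, groupB, bootstrap = TRUE,
                            nReps = nReps, seed = seed)
      list(analysis = "group_diff", metric = metric, group_a = groupA,
           group_b = groupB, estimate = gd$estimate, ci_low = gd$ciLow,
           ci_high = gd$ciHigh, n_reps = nReps, seed = seed)
    },
    pearson = {
      one <- oneEyePerPatient(table, seed = seed)
      list(analysis = "pearson", x = predictor, y = predictor2,
           estimate = pearsonCorrelation(one[[predictor]],
                                         one[[predictor2]]),
           n = nrow(one), seed = seed)
    })
  if (!is.null(outPath))
    jsonlite::write_json(c(out, list(provenance = .provenance(
      list(analysis = analysis), seed = seed))), outPath,
      auto_unbox = TRUE, digits = NA)
  out
}
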