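# Eye-level cohort simulation for the statistics module. Produces metric
# values directly (not volumes): each patient carries a zone category and
# demographics drawn from per-zone normals, and two eyes whose mean-RAL
# shares a patient-level random effect to induce inter-eye correlation.

#' Default per-zone cohort parameters
#'
#' Per-zone (I, PII, II) means and standard deviations of the demographic
#' and biometric distributions used by \code{\link{generateCohort}}:
#' gestational age (weeks), birthweight (g), postmenstrual age (weeks),
#' axial length (mm), foveal distance (mm), mean retinal arclength (mm),
#' and the positive mean-to-min arclength offset (mm). The treatment
#' outcome is Bernoulli with log-odds \code{treatA + treatB * meanRal}
#' (\code{treatB < 0}: shorter arclength, higher risk).
#'
#' @return A named list of parameter vectors.
#' @export
cohortDefaults <- function() {
  list(zones = c("I", "PII", "II"),
       gaMean = c(24.1, 24.2, 27.8), gaSd = c(1.2, 1.0, 2.1),
       bwMean = c(557.9, 605.0, 964.6), bwSd = c(116.8, 84.4, 414.7),
       pmaMean = c(33.3, 32.6, 35.9), pmaSd = c(1.5, 1.5, 3.1),
       alMean = c(15.4, 15.2, 16.0), alSd = c(0.5, 0.6, 0.6),
       fdMean = c(4.5, 4.8, 4.7), fdSd = c(0.5, 0.6, 0.6),
       ralMean = c(10.3, 11.9, 14.8), ralSd = c(1.2, 1.4, 1.1),
       minOffsetMean = c(1.5, 1.5, 1.2), minOffsetSd = 0.4,
       treatA = 12.84, treatB = -1.2)
}

#' Simulate an eye-level cohort
#'
#' Per patient: a latent severity (standard normal) is thresholded to a
#' zone category matching \code{zoneMix}; gestational age, birthweight and
#' postmenstrual age are drawn from per-zone normals; both eyes share a
#' patient-level random effect so that \code{cor(eye1, eye2) =
#' interEyeCor} for mean-RAL within a zone; min-RAL subtracts a positive
#' (gamma-distributed) offset; AVR applies the spherical-cap formula to
#' each eye's mean-RAL and axial length; treatment is Bernoulli with
#' log-odds linear (decreasing) in mean-RAL. Deterministic given
#' \code{seed}.
#'
#' @param nPatients number of patients (>= 2); each contributes 2 eyes.
#' @param zoneMix probabilities of zones I, PII, II (sum to 1).
#' @param seed RNG seed.
#' @param interEyeCor within-patient correlation of eye-level mean-RAL.
#' @param params parameter list as from \code{\link{cohortDefaults}}.
#' @return A \code{data.frame} with columns \code{patient_id, eye, zone,
#'   ga_weeks, bw_g, pma_weeks, mean_ral_mm, min_ral_mm, fd_mm,
#'   zone_ratio, avr_mm2, treated}.
#' @export
generateCohort <- function(nPatients, zoneMix = c(0.346, 0.096, 0.558),
                           seed = 1L, interEyeCor = 0.8,
                           params = cohortDefaults()) {
  if (nPatients < 2) ropStop("config", "need at least 2 patients")
  if (abs(sum(zoneMix) - 1) > 1e-8 || any(zoneMix < 0))
    ropStop("config", "zoneMix must be non-negative probabilities summing to 1")
  if (interEyeCor < 0 || interEyeCor > 1)
    ropStop("config", "interEyeCor must lie in [0, 1]")
  .withSeed(seed, {
    latent <- stats::rnorm(nPatients)
    zi <- findInterval(stats::pnorm(latent), cumsum(zoneMix)[-3]) + 1L
    ga <- stats::rnorm(nPatients, params$gaMean[zi], params$gaSd[zi])
    bw <- stats::rnorm(nPatients, params$bwMean[zi], params$bwSd[zi])
    pma <- stats::rnorm(nPatients, params$pmaMean[zi], params$pmaSd[zi])
    sdz <- params$ralSd[zi]
    bpat <- stats::rnorm(nPatients, 0, sqrt(interEyeCor) * sdz)
    rows <- vector("list", 2L)
    for (e in 1:2) {
      ral <- params$ralMean[zi] + bpat +
        stats::rnorm(nPatients, 0, sqrt(1 - interEyeCor) * sdz)
      mo <- params$minOffsetMean[zi]
      shape <- (mo / params$minOffsetSd)^2
      off <- stats::rgamma(nPatients, shape = shape, rate = shape / mo)
      al <- stats::rnorm(nPatients, params$alMean[zi], params$alSd[zi])
      fd <- stats::rnorm(nPatients, params$fdMean[zi], params$fdSd[zi])
      minRal <- pmax(ral - off, 0.5)
      avr <- (pi * al^2 / 2) * (1 - cos(pmin(ral, pi * al) / al))
      treated <- stats::rbinom(nPatients, 1,
                               stats::plogis(params$treatA + params$treatB * ral))
      rows[[e]] <- data.frame(
        patient_id = sprintf("P%04d", seq_len(nPatients)),
        eye = c("OD", "OS")[e], zone = params$zones[zi],
        ga_weeks = ga, bw_g = bw, pma_weeks = pma,
        mean_ral_mm = ral, min_ral_mm = minRal, fd_mm = fd,
        zone_ratio = minRal / fd, avr_mm2 = avr, treated = treated)
    }
    out <- rbind(rows[[1]], rows[[2]])
    out[order(out$patient_id, out$eye), , drop = FALSE]
  })
}

#' Validate a cohort table
#'
#' Checks the eye-level table schema: required columns present, at most
#' two eyes per patient, and no missing values in the columns an analysis
#' will use.
#'
#' @param table a \code{data.frame}.
#' @param usedCols columns that must be complete (no NA).
#' @return \code{table} invisibly; raises a format error otherwise.
#' @export
validateCohortTable <- function(table, usedCols = character()) {
  need <- c("patient_id", "eye", "zone", "mean_ral_mm", "min_ral_mm",
            "avr_mm2", "treated")
  miss <- setdiff(need, names(table))
  if (length(miss))
    ropStop("format", "cohort table is missing columns: ",
            paste(miss, collapse = ", "))
  eyeCount <- table(table$patient_id)
  if (any(eyeCount > 2L))
    ropStop("format", "patient ", names(eyeCount)[which(eyeCount > 2L)[1]],
            " has more than 2 eyes")
  for (cn in usedCols) {
    if (!cn %in% names(table))
      ropStop("format", "cohort table is missing column: ", cn)
    if (anyNA(table[[cn]]))
      ropStop("format", "missing values in column ", cn)
  }
  invisible(table)
}

#' Keep one randomly selected eye per patient
#'
#' Patient-level analyses (demographic predictors, Pearson correlation of
#' the arclength summaries) use a single randomly chosen eye per patient.
#'
#' @param table cohort table.
#' @param seed RNG seed for the per-patient choice.
#' @return Subset of \code{table} with one row per patient.
#' @export
oneEyePerPatient <- function(table, seed = 1L) {
  .withSeed(seed, {
    keep <- unlist(lapply(split(seq_len(nrow(table)), table$patient_id),
                          function(i) if (length(i) == 1L) i else sample(i, 1L)))
    table[sort(unname(keep)), , drop = FALSE]
  })
}
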