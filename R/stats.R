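# Cohort statistics: AUROC by pair counting, patient-cluster bootstrap
# percentile confidence intervals, paired predictor comparisons, group mean
# differences, and Pearson correlation.

#' Area under the ROC curve
#'
#' Probability-of-concordance (Mann-Whitney) estimator: the fraction of
#' positive-negative pairs in which the positive scores higher, ties
#' counted one half. Computed from midranks, which is algebraically
#' identical to explicit pair counting and equals trapezoidal ROC
#' integration with tie handling.
#'
#' @param scores numeric predictor values.
#' @param labels binary outcomes (0/1 or logical).
#' @return AUROC in [0, 1].
#' @examples
#' auroc(c(0.9, 0.4, 0.5, 0.3), c(1, 1, 0, 0))   # 0.75
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels))
    ropStop("analysis", "scores and labels differ in length")
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L)
    ropStop("analysis", "AUROC undefined: only one class present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

# NA-returning variant for use inside bootstrap replicates, where a
# resample may lose one class and is redrawn rather than treated as fatal
.aurocOrNA <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Bootstrap statistic factories
#'
#' Convenience constructors for the statistics most often fed to
#' \code{\link{clusterBootstrap}}: the AUROC of one predictor for a binary
#' outcome, the paired AUROC difference of two predictors, and the mean of
#' a column. Each returns a function of a (resampled) cohort table that
#' yields the statistic, or \code{NA} when it is undefined on that
#' resample.
#'
#' @param predictor,predictorA,predictorB,outcome,column column names.
#' @return A function \code{table -> numeric}.
#' @export
aurocStat <- function(predictor, outcome) {
  function(table) .aurocOrNA(table[[predictor]], table[[outcome]])
}

#' @rdname aurocStat
#' @export
aurocDiffStat <- function(predictorA, predictorB, outcome) {
  function(table) {
    a <- .aurocOrNA(table[[predictorA]], table[[outcome]])
    if (is.na(a)) return(NA_real_)
    a - .aurocOrNA(table[[predictorB]], table[[outcome]])
  }
}

#' @rdname aurocStat
#' @export
meanStat <- function(column) function(table) mean(table[[column]])

# fast row subset of a plain data.frame (avoids `[.data.frame` overhead in
# tight bootstrap loops)
.subRows <- function(cols, rows) {
  out <- lapply(cols, `[`, rows)
  attr(out, "class") <- "data.frame"
  attr(out, "row.names") <- c(NA_integer_, -length(rows))
  out
}

#' Patient-cluster bootstrap
#'
#' Resamples whole patients (clusters of correlated eyes) with
#' replacement: each replicate draws \code{nClusters} patient ids,
#' concatenates all their eyes, and recomputes the statistic; the 95%
#' confidence interval is the percentile (2.5/97.5) interval over
#' replicates. Replicates on which the statistic is undefined (e.g. a
#' single-class resample for an AUROC) are redrawn and counted; more than
#' 50% undefined is an analysis error. The cluster index draws for all
#' replicates come from one seeded stream laid out replicate-by-replicate,
#' so a given (seed, nReps) pair is bit-reproducible.
#'
#' @param table cohort table with a \code{patient_id} column.
#' @param statistic function of a table returning a scalar (NA when
#'   undefined on that resample); see \code{\link{aurocStat}}.
#' @param nReps number of bootstrap replicates (the reference analysis
#'   uses 2000).
#' @param seed RNG seed.
#' @return A \code{\linkS4class{BootstrapResult}}.
#' @export
clusterBootstrap <- function(table, statistic, nReps = 2000L, seed = 1L) {
  ids <- unique(table$patient_id)
  nC <- length(ids)
  if (nC < 2L) ropStop("analysis", "need at least 2 clusters")
  idxList <- split(seq_len(nrow(table)),
                   factor(table$patient_id, levels = ids))
  cols <- as.list(table)
  est <- statistic(table)
  .withSeed(seed, {
    draws <- matrix(sample.int(nC, nReps * nC, replace = TRUE),
                    nrow = nReps, byrow = TRUE)
    reps <- numeric(nReps)
    nRedraws <- 0L
    for (r in seq_len(nReps)) {
      cl <- draws[r, ]
      val <- statistic(.subRows(cols, unlist(idxList[cl], use.names = FALSE)))
      while (is.na(val)) {
        nRedraws <- nRedraws + 1L
        if (nRedraws > nReps)
          ropStop("analysis",
                  "statistic undefined in more than 50% of bootstrap replicates")
        cl <- sample.int(nC, nC, replace = TRUE)
        val <- statistic(.subRows(cols, unlist(idxList[cl], use.names = FALSE)))
      }
      reps[r] <- val
    }
    ci <- unname(stats::quantile(reps, c(0.025, 0.975)))
    new("BootstrapResult", estimate = est, ciLow = ci[1], ciHigh = ci[2],
        nReplicates = as.integer(nReps), nClusters = as.integer(nC),
        nRedraws = nRedraws, seed = as.integer(seed), replicates = reps,
        ciFlag = est < ci[1] || est > ci[2])
  })
}

#' Compare two predictors of the same outcome
#'
#' Bootstraps the paired AUROC difference: on each cluster resample both
#' AUROCs are computed on the same eyes and differenced (a - b). Reports
#' the full-table difference, the mean replicate difference, the
#' percentile CI, and a significance flag (CI excludes zero).
#'
#' @param table cohort table.
#' @param predictorA,predictorB,outcome column names.
#' @param nReps,seed bootstrap settings.
#' @return A list with \code{estimate}, \code{meanDiff}, \code{ciLow},
#'   \code{ciHigh}, \code{significant} and the underlying
#'   \code{\linkS4class{BootstrapResult}}.
#' @export
comparePredictors <- function(table, predictorA, predictorB, outcome,
                              nReps = 2000L, seed = 1L) {
  validateCohortTable(table, usedCols = c(predictorA, predictorB, outcome))
  br <- clusterBootstrap(table, aurocDiffStat(predictorA, predictorB, outcome),
                         nReps = nReps, seed = seed)
  list(estimate = br@estimate, meanDiff = mean(br@replicates),
       ciLow = br@ciLow, ciHigh = br@ciHigh,
       significant = br@ciLow > 0 || br@ciHigh < 0, bootstrap = br)
}

#' Group mean difference
#'
#' \code{mean(metric | groupB) - mean(metric | groupA)}; e.g. with zone
#' groups I and II and the arclength column this is the zone II minus
#' zone I mean difference. Optionally a cluster-bootstrap CI.
#'
#' @param table cohort table.
#' @param metric metric column name.
#' @param groupA,groupB group labels in \code{groupCol}.
#' @param groupCol grouping column (default \code{"zone"}).
#' @param bootstrap if TRUE, attach a cluster-bootstrap percentile CI.
#' @param nReps,seed bootstrap settings.
#' @return The difference, or a list with \code{estimate}, \code{ciLow},
#'   \code{ciHigh} when \code{bootstrap} is TRUE.
#' @export
groupDifference <- function(table, metric, groupA, groupB,
                            groupCol = "zone", bootstrap = FALSE,
                            nReps = 2000L, seed = 1L) {
  ga <- table[[groupCol]] == groupA
  gb <- table[[groupCol]] == groupB
  if (!any(ga) || !any(gb))
    ropStop("analysis", "empty group in group difference")
  diffStat <- function(t) {
    a <- t[[metric]][t[[groupCol]] == groupA]
    b <- t[[metric]][t[[groupCol]] == groupB]
    if (!length(a) || !length(b)) return(NA_real_)
    mean(b) - mean(a)
  }
  if (!bootstrap) return(mean(table[[metric]][gb]) - mean(table[[metric]][ga]))
  br <- clusterBootstrap(table, diffStat, nReps = nReps, seed = seed)
  list(estimate = br@estimate, ciLow = br@ciLow, ciHigh = br@ciHigh,
       bootstrap = br)
}

#' Pearson correlation
#'
#' Standard product-moment correlation with the preconditions made
#' explicit: at least two pairs, both with nonzero variance.
#'
#' @param x,y paired numeric vectors.
#' @return Correlation in [-1, 1].
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    ropStop("analysis", "need >= 2 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    ropStop("analysis", "correlation undefined: zero variance")
  stats::cor(x, y)
}
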