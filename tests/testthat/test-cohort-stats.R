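test_that("AUROC equals explicit pair counting", {
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.6, 0.4), c(1, 1, 1, 0, 0)), 1)
  expect_equal(auroc(c(0.9, 0.4, 0.5, 0.3), c(1, 1, 0, 0)), 0.75)
  expect_equal(auroc(c(0.5, 0.5), c(1, 0)), 0.5)
  bruteAuroc <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    tot <- 0
    for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(pos) * length(neg))
  }
  set.seed(31)
  for (i in 1:40) {
    n <- sample(4:15, 1)
    s <- round(rnorm(n), 1)           # coarse values force ties
    l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(auroc(s, l), bruteAuroc(s, l), tolerance = 1e-12)
  }
  err <- tryCatch(auroc(1:3, c(1, 1, 1)), error = identity)
  expect_s3_class(err, "ropzone_analysis")
})

test_that("AUROC agrees with an independent ROC implementation", {
  set.seed(47)
  for (i in 1:10) {
    s <- round(rnorm(40), 1)
    l <- rbinom(40, 1, 0.5)
    if (length(unique(l)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auroc(s, l), ref, tolerance = 1e-12)
  }
})

test_that("AUROC is rank-invariant and complement-symmetric", {
  set.seed(33)
  for (i in 1:10) {
    s <- rnorm(30); l <- rbinom(30, 1, 0.4)
    if (length(unique(l)) < 2) next
    a <- auroc(s, l)
    expect_identical(auroc(exp(2 * s) + 5, l), a)
    expect_equal(a + auroc(s, 1 - l), 1, tolerance = 1e-12)
  }
})

test_that("cluster bootstrap collapses on constants and is seed-stable", {
  tab <- generateCohort(40, seed = 2L)
  tab$const <- 5.5
  br <- clusterBootstrap(tab, meanStat("const"), nReps = 200, seed = 9L)
  expect_equal(c(br@estimate, br@ciLow, br@ciHigh), rep(5.5, 3))
  b1 <- clusterBootstrap(tab, aurocStat("mean_ral_mm", "treated"),
                         nReps = 300, seed = 17L)
  b2 <- clusterBootstrap(tab, aurocStat("mean_ral_mm", "treated"),
                         nReps = 300, seed = 17L)
  expect_identical(b1@replicates, b2@replicates)
  expect_identical(c(b1@ciLow, b1@ciHigh), c(b2@ciLow, b2@ciHigh))
  expect_lte(b1@ciLow, b1@estimate)
  expect_gte(b1@ciHigh, b1@estimate)
})

test_that("with one eye per patient the cluster bootstrap is the iid bootstrap", {
  tab <- generateCohort(60, seed = 4L)
  one <- oneEyePerPatient(tab, seed = 1L)
  br <- clusterBootstrap(one, meanStat("mean_ral_mm"), nReps = 250, seed = 23L)
  # independent re-implementation with the same draw layout
  x <- one$mean_ral_mm
  n <- length(x)
  set.seed(23)
  draws <- matrix(sample.int(n, 250 * n, replace = TRUE), nrow = 250,
                  byrow = TRUE)
  reps <- apply(draws, 1, function(i) mean(x[i]))
  expect_equal(br@replicates, reps, tolerance = 1e-12)
})

test_that("a mostly-undefined statistic is an analysis error", {
  tab <- generateCohort(30, seed = 6L)
  badStat <- function(t) NA_real_
  err <- tryCatch(clusterBootstrap(tab, function(t) NA_real_,
                                   nReps = 50, seed = 1L),
                  error = identity)
  expect_s3_class(err, "ropzone_analysis")
})

test_that("predictor comparison is null for equivalent predictors", {
  tab <- generateCohort(50, seed = 8L)
  cp <- comparePredictors(tab, "mean_ral_mm", "mean_ral_mm", "treated",
                          nReps = 200, seed = 3L)
  expect_equal(c(cp$estimate, cp$ciLow, cp$ciHigh), rep(0, 3))
  expect_false(cp$significant)
  # monotone transforms leave the AUROC difference at zero
  tab$ral_rescaled <- exp(tab$mean_ral_mm / 3)
  cp2 <- comparePredictors(tab, "mean_ral_mm", "ral_rescaled", "treated",
                           nReps = 200, seed = 3L)
  expect_equal(c(cp2$estimate, cp2$ciLow, cp2$ciHigh), rep(0, 3))
})

test_that("a separating predictor beats noise with a CI excluding zero", {
  set.seed(41)
  n <- 120
  tab <- data.frame(patient_id = sprintf("P%03d", rep(1:n, each = 2)),
                    eye = rep(c("OD", "OS"), n), zone = "I",
                    mean_ral_mm = 0, min_ral_mm = 0, avr_mm2 = 0,
                    treated = rep(rbinom(n, 1, 0.5), each = 2))
  tab$good <- tab$treated * 2 + rnorm(2 * n, 0, 0.1)
  tab$noise <- rnorm(2 * n)
  cp <- comparePredictors(tab, "good", "noise", "treated",
                          nReps = 300, seed = 5L)
  expect_true(cp$significant)
  expect_gt(cp$ciLow, 0)
})

test_that("group differences subtract means and are antisymmetric", {
  tab <- data.frame(patient_id = sprintf("P%02d", 1:6),
                    eye = "OD", zone = rep(c("I", "II"), each = 3),
                    mean_ral_mm = c(10.3, 10.3, 10.3, 14.8, 14.8, 14.8),
                    min_ral_mm = 1, avr_mm2 = rep(c(80.7, 161.6), each = 3),
                    treated = rep(c(1, 0), 3))
  expect_equal(groupDifference(tab, "mean_ral_mm", "I", "II"), 4.5)
  expect_equal(groupDifference(tab, "avr_mm2", "I", "II"), 80.9)
  expect_equal(groupDifference(tab, "mean_ral_mm", "II", "I"), -4.5)
  expect_equal(groupDifference(tab, "mean_ral_mm", "I", "I"), 0)
  err <- tryCatch(groupDifference(tab, "mean_ral_mm", "I", "III"),
                  error = identity)
  expect_s3_class(err, "ropzone_analysis")
})

test_that("Pearson correlation applies its preconditions", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(pearsonCorrelation(x, 2 * x + 1), 1)
  expect_equal(pearsonCorrelation(x, -x), -1)
  y <- c(2, 1, 5, 4, 8)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearsonCorrelation(x, y), hand, tolerance = 1e-12)
  expect_s3_class(tryCatch(pearsonCorrelation(x, rep(1, 5)),
                           error = identity), "ropzone_analysis")
  expect_s3_class(tryCatch(pearsonCorrelation(1, 2), error = identity),
                  "ropzone_analysis")
})
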