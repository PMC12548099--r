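test_that("phantom generation is deterministic given the seed", {
  spec <- PhantomSpec(noise = 0.3, seed = 42L)
  a <- generatePhantom(spec, nEnface = 80L)
  b <- generatePhantom(spec, nEnface = 80L)
  expect_identical(a$volume@voxels, b$volume@voxels)
  expect_identical(a$landmarks@border, b$landmarks@border)
  c2 <- generatePhantom(PhantomSpec(noise = 0.3, seed = 43L), nEnface = 80L)
  expect_false(identical(a$volume@voxels, c2$volume@voxels))
})

test_that("closed-form truth matches its defining arithmetic", {
  spec <- PhantomSpec(sphereRadiusMm = 7.7, borderBaseDeg = 60,
                      borderSpanDeg = 40)
  ph <- generatePhantom(spec, nEnface = 80L)
  tr <- ph$truth
  expect_equal(unique(round(tr@ralMm, 9)), round(7.7 * pi / 3, 9))
  expect_equal(tr@meanRalMm, 7.7 * pi / 3, tolerance = 1e-12)
  expect_equal(tr@fdMm, 7.7 * 28.3 * pi / 180, tolerance = 1e-12)
  expect_equal(tr@avrMm2, sphericalCapAvr(tr@meanRalMm, 15.4))
  expect_equal(tr@trueCapAreaMm2, trueCapArea(7.7, tr@meanRalMm))
})

test_that("noise-free phantoms reconstruct the configured sphere", {
  ph <- cachedPhantom(PhantomSpec(sphereRadiusMm = 8.0), nEnface = 120L)
  g <- ph$geom
  surf <- extractRpeSurface(ph$volume)
  r <- g@pivotOffsetMm + surf@zRpe[surf@valid] * g@depthStepMm
  expect_gt(mean(abs(r - 8.0) <= g@depthStepMm / 2 + 1e-9), 0.99)
})

test_that("interface noise only perturbs voxels at tissue boundaries", {
  clean <- generatePhantom(PhantomSpec(seed = 7L), nEnface = 80L)
  noisy <- generatePhantom(PhantomSpec(noise = 0.5, seed = 7L), nEnface = 80L)
  changed <- which(clean$volume@voxels != noisy$volume@voxels,
                   arr.ind = TRUE)
  expect_gt(nrow(changed), 0)
  v <- clean$volume@voxels
  nd <- dim(v)[3]
  for (i in seq_len(min(nrow(changed), 200))) {
    f <- changed[i, 1]; s <- changed[i, 2]; d <- changed[i, 3]
    nbr <- v[f, s, max(1, d - 1):min(nd, d + 1)]
    expect_gt(length(unique(nbr)), 1)   # sat at an interface
  }
})

test_that("the expected zone flips across the closed-form notch threshold", {
  # zone I threshold: R*(theta_b - depth) < 2 * R * theta_f
  # with theta_b = 75 and theta_f = 28.3 the critical depth is 18.4 deg
  dCrit <- 75 - 2 * 28.3
  below <- generatePhantom(PhantomSpec(borderBaseDeg = 75, borderSpanDeg = 50,
                                       notchWidthDeg = 16,
                                       notchDepthDeg = dCrit - 2),
                           nEnface = 80L)
  above <- generatePhantom(PhantomSpec(borderBaseDeg = 75, borderSpanDeg = 50,
                                       notchWidthDeg = 16,
                                       notchDepthDeg = dCrit + 2),
                           nEnface = 80L)
  expect_false(below$truth@zone == "I")
  expect_identical(above$truth@zone, "I")
})

test_that("a globe that overflows the depth window is a configuration error", {
  spec <- PhantomSpec()
  geom <- ScanGeometry(80, 80, 10, depthStepMm = 0.02, pivotOffsetMm = 7.4)
  err <- tryCatch(generatePhantom(spec, geom = geom), error = identity)
  expect_s3_class(err, "ropzone_config")
})

test_that("phantom spec files round-trip in YAML and JSON", {
  spec <- PhantomSpec(sphereRadiusMm = 8.0, borderBaseDeg = 66,
                      notchDepthDeg = 5, notchWidthDeg = 10, seed = 9L)
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    writePhantomSpec(spec, path)
    back <- readPhantomSpec(path)
    expect_equal(back@sphereRadiusMm, 8.0)
    expect_equal(back@borderBaseDeg, 66)
    expect_identical(back@seed, 9L)
  }
})

test_that("simulated cohorts recover the configured per-zone means", {
  tab <- generateCohort(5000, seed = 11L)
  expect_identical(tab, generateCohort(5000, seed = 11L))
  defs <- cohortDefaults()
  for (zi in 1:3) {
    z <- defs$zones[zi]
    x <- tab$mean_ral_mm[tab$zone == z]
    se <- sd(x) / sqrt(length(x) / 2)   # eyes correlate within patient
    expect_lt(abs(mean(x) - defs$ralMean[zi]), 2 * se + 0.02)
    g <- tab$ga_weeks[tab$zone == z]
    expect_lt(abs(mean(g) - defs$gaMean[zi]), 3 * sd(g) / sqrt(length(g) / 2))
  }
  # inter-eye correlation near its configured value
  od <- tab[tab$eye == "OD", ]; os <- tab[tab$eye == "OS", ]
  resid <- function(t) t$mean_ral_mm - defs$ralMean[match(t$zone, defs$zones)]
  expect_lt(abs(cor(resid(od), resid(os)) - 0.8), 0.05)
  # min-RAL is always below mean-RAL
  expect_true(all(tab$min_ral_mm < tab$mean_ral_mm))
})

test_that("degenerate mixes and steep outcomes behave as limits", {
  tab <- generateCohort(200, zoneMix = c(1, 0, 0), seed = 3L)
  expect_true(all(tab$zone == "I"))
  # near-step outcome: treatment iff arclength below a threshold
  p <- cohortDefaults()
  p$treatA <- 1e6 * 11.5; p$treatB <- -1e6
  tabStep <- generateCohort(400, seed = 5L, params = p)
  expect_identical(auroc(-tabStep$mean_ral_mm, tabStep$treated), 1)
})

test_that("invalid cohort configurations are rejected", {
  err <- tryCatch(generateCohort(100, zoneMix = c(0.5, 0.2, 0.2)),
                  error = identity)
  expect_s3_class(err, "ropzone_config")
  expect_s3_class(tryCatch(generateCohort(1), error = identity),
                  "ropzone_config")
})
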