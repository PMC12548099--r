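test_that("geodesics reproduce great-circle arcs on the phantom sphere", {
  ph <- cachedPhantom(PhantomSpec(), nEnface = 160L)
  surf <- extractRpeSurface(ph$volume)
  R <- 7.7
  # identical endpoints
  p <- c(0, 0, R)
  expect_identical(geodesicDistance(surf, start = p, end = p), 0)
  # 60 degrees apart: R * pi / 3, within the 16-neighbor metrication bound
  th <- pi / 3
  q <- c(R * sin(th) * cos(0.4), R * sin(th) * sin(0.4), R * cos(th))
  d <- geodesicDistance(surf, start = p, end = q)
  expect_lt(abs(d - R * th) / (R * th), 0.03)
  # random pairs against the spherical law of cosines
  set.seed(21)
  for (i in 1:8) {
    ang <- runif(2, -0.9, 0.9); ang2 <- runif(2, -0.9, 0.9)
    u <- c(sin(ang[1]), cos(ang[1]) * sin(ang[2]),
           cos(ang[1]) * cos(ang[2]))
    v <- c(sin(ang2[1]), cos(ang2[1]) * sin(ang2[2]),
           cos(ang2[1]) * cos(ang2[2]))
    truth <- R * acos(pmin(1, sum(u * v)))
    if (truth < 0.5) next
    d <- geodesicDistance(surf, start = R * u, end = R * v)
    expect_lt(abs(d - truth) / truth, 0.03)
    # never shorter than the 3D chord
    expect_gte(d, sqrt(sum((R * u - R * v)^2)) - 1e-9)
  }
})

test_that("geodesic distance is symmetric in its endpoints", {
  ph <- cachedPhantom(PhantomSpec(), nEnface = 160L)
  surf <- extractRpeSurface(ph$volume)
  R <- 7.7
  p <- c(0.3, -0.6, sqrt(R^2 - 0.45))
  q <- c(-3, 2, sqrt(R^2 - 13))
  expect_equal(geodesicDistance(surf, start = p, end = q),
               geodesicDistance(surf, start = q, end = p), tolerance = 1e-9)
})

test_that("arclength arrays are constant for constant borders, notched at notches", {
  ph <- cachedPhantom(PhantomSpec(borderBaseDeg = 60, borderSpanDeg = 50),
                      nEnface = 160L)
  surf <- extractRpeSurface(ph$volume)
  dc <- discCentroid3d(ph$landmarks@discEdge, surf, ph$geom)
  chain <- liftChain(bresenhamChain(ph$landmarks@border), surf)
  smp <- resampleBorder(chain, dc, ph$landmarks@fovea)
  ral <- computeRal(surf, disc = dc, borderSamples = smp$points3d)
  expect_identical(ral$nDropped, 0L)
  expect_lt(sd(ral$ralMm) / mean(ral$ralMm), 0.02)
  # a sample at the disc centroid's own position measures about zero
  near <- computeRal(surf, disc = dc,
                     borderSamples = matrix(dc@position3d, 1))
  expect_lt(near$ralMm, 0.2)
  # notch: the arclength minimum falls inside the notch bearing window
  phN <- cachedPhantom(PhantomSpec(borderBaseDeg = 60, borderSpanDeg = 50,
                                   notchCenterDeg = -15, notchWidthDeg = 14,
                                   notchDepthDeg = 12), nEnface = 160L)
  surfN <- extractRpeSurface(phN$volume)
  dcN <- discCentroid3d(phN$landmarks@discEdge, surfN, phN$geom)
  chainN <- liftChain(bresenhamChain(phN$landmarks@border), surfN)
  smpN <- resampleBorder(chainN, dcN, phN$landmarks@fovea)
  ralN <- computeRal(surfN, disc = dcN, borderSamples = smpN$points3d)
  bmin <- smpN$bearingsDeg[which.min(ralN$ralMm)]
  expect_gt(bmin, -15 - 7 - 5)
  expect_lt(bmin, -15 + 7 + 5)
})

test_that("foveal distance is geodesic, with the chord retained", {
  ph <- cachedPhantom(PhantomSpec(), nEnface = 160L)
  surf <- extractRpeSurface(ph$volume)
  dc <- discCentroid3d(ph$landmarks@discEdge, surf, ph$geom)
  fd <- fovealDistance(surf, disc = dc, fovea = ph$landmarks@fovea)
  expect_lt(abs(fd$fdMm - ph$truth@fdMm) / ph$truth@fdMm, 0.03)
  expect_lte(fd$chordMm, fd$fdMm + 1e-9)
  # on this phantom the border lies beyond the fovea, so FD <= every RAL
  chain <- liftChain(bresenhamChain(ph$landmarks@border), surf)
  smp <- resampleBorder(chain, dc, ph$landmarks@fovea)
  ral <- computeRal(surf, disc = dc, borderSamples = smp$points3d)
  expect_true(all(fd$fdMm <= ral$ralMm))
})

test_that("disconnected surface components raise a no-path error", {
  surf <- flatSurface(n = 41, depthIndex = 16)
  # cut the grid into two islands with an invalid band
  surf@valid[19:23, ] <- FALSE
  surf@zRpe[19:23, ] <- NA_real_
  g <- surf@geom
  p <- voxelToPhysical(c(5, 20, 16), g)[1, ]
  q <- voxelToPhysical(c(36, 20, 16), g)[1, ]
  err <- tryCatch(geodesicDistance(surf, start = p, end = q),
                  error = identity)
  expect_s3_class(err, "ropzone_measurement")
})
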