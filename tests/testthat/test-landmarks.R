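test_that("Bresenham chains match hand-traced rasterizations", {
  # axis-aligned segment
  ch <- bresenhamChain(rbind(c(0, 0), c(0, 5)))
  expect_equal(ch@cells, cbind(rep(0L, 6), 0:5))
  # frozen hand trace of the classic integer algorithm for delta = (4, 2)
  ch <- bresenhamChain(rbind(c(0, 0), c(4, 2)))
  expect_equal(ch@cells,
               rbind(c(0L, 0L), c(1L, 0L), c(2L, 1L), c(3L, 1L), c(4L, 2L)))
  expect_error(bresenhamChain(rbind(c(0, 0))), "at least 2 points")
})

test_that("chains are 8-connected, nearest-line, length-bounded and close loops", {
  set.seed(5)
  for (i in 1:40) {
    p0 <- sample(-30:30, 2); p1 <- sample(-30:30, 2)
    if (all(p0 == p1)) next
    cells <- bresenhamChain(rbind(p0, p1))@cells
    step <- abs(diff(cells))
    expect_true(all(pmax(step[, 1], step[, 2]) == 1))      # 8-connected
    d <- abs(p1 - p0)
    expect_gte(nrow(cells), max(d) + 1)
    expect_lte(nrow(cells), sum(d) + 1)
    # nearest-cell property: each cell within half a cell of the line
    # (in the minor coordinate, parameterized by the driving axis)
    if (d[1] >= d[2]) {
      yline <- p0[2] + (cells[, 1] - p0[1]) * (p1[2] - p0[2]) / (p1[1] - p0[1])
      expect_true(all(abs(cells[, 2] - yline) <= 0.5 + 1e-9))
    } else {
      xline <- p0[1] + (cells[, 2] - p0[2]) * (p1[1] - p0[1]) / (p1[2] - p0[2])
      expect_true(all(abs(cells[, 1] - xline) <= 0.5 + 1e-9))
    }
  }
  # a closed disc-edge loop ends 8-adjacent to its start
  loop <- rbind(c(10, 0), c(0, 10), c(-10, 0), c(0, -10), c(10, 0))
  cells <- bresenhamChain(loop)@cells
  n <- nrow(cells)
  expect_true(all(abs(cells[n, ] - cells[1, ]) <= 1))
})

test_that("Bresenham agrees with a rounding rasterizer off tie points", {
  set.seed(9)
  for (i in 1:30) {
    p0 <- sample(0:40, 2); p1 <- sample(0:40, 2)
    if (all(p0 == p1)) next
    cells <- bresenhamChain(rbind(p0, p1))@cells
    d <- abs(p1 - p0)
    if (d[1] < d[2]) { p0 <- rev(p0); p1 <- rev(p1); cells <- cells[, 2:1] }
    yline <- p0[2] + (cells[, 1] - p0[1]) * (p1[2] - p0[2]) / (p1[1] - p0[1])
    noTie <- abs(yline - round(yline) ) < 0.5 - 1e-9
    expect_equal(cells[noTie, 2], round(yline[noTie]))
  }
})

test_that("disc centroid is the mean of the lifted edge chain", {
  surf <- flatSurface(n = 61, depthIndex = 20)
  g <- surf@geom
  edge <- rbind(c(20, 30), c(30, 40), c(40, 30), c(30, 20))
  dc <- discCentroid3d(edge, surf, g)
  # independent recomputation: rasterize, lift, average
  cells <- bresenhamChain(rbind(edge, edge[1, ]))@cells
  cells <- cells[-nrow(cells), ]
  pts <- voxelToPhysical(cbind(cells, 20), g)
  expect_equal(dc@position3d, colMeans(pts), tolerance = 1e-12)
  # symmetric edge about the central axis -> centroid on the axis
  edgeSym <- rbind(c(30 - 7, 30), c(30, 30 + 7), c(30 + 7, 30), c(30, 30 - 7))
  dcSym <- discCentroid3d(edgeSym, surf, g)
  expect_lt(max(abs(dcSym@position3d[1:2])), 1e-9)
  expect_equal(dcSym@enfaceCenter, c(30, 30), tolerance = 1e-6)
  # invariant under cyclic rotation of the input point order
  dcRot <- discCentroid3d(edge[c(3, 4, 1, 2), ], surf, g)
  expect_equal(dcRot@position3d, dc@position3d, tolerance = 1e-12)
})

test_that("phantom disc centroid lands near the configured pole", {
  ph <- cachedPhantom(PhantomSpec(), nEnface = 160L)
  surf <- extractRpeSurface(ph$volume)
  dc <- discCentroid3d(ph$landmarks@discEdge, surf, ph$geom)
  thD <- 28.3 * pi / 180
  pole <- c(-sin(thD), 0, cos(thD)) * 7.7 * cos(3 * pi / 180)
  expect_lt(sqrt(sum((dc@position3d - pole)^2)), 0.05)
})

test_that("border resampling lays out one point per 3 degrees, half-open", {
  ph <- cachedPhantom(PhantomSpec(borderBaseDeg = 60, borderSpanDeg = 50),
                      nEnface = 160L)
  surf <- extractRpeSurface(ph$volume)
  g <- ph$geom
  dc <- discCentroid3d(ph$landmarks@discEdge, surf, g)
  chain <- liftChain(bresenhamChain(ph$landmarks@border), surf)
  smp <- resampleBorder(chain, dc, ph$landmarks@fovea, density = 10)
  expect_lte(abs(nrow(smp$points3d) - floor(smp$coveredDeg / 3)), 1)
  # constant angular border: all sampled points equidistant from the disc
  # pole up to grid quantization
  thD <- 28.3 * pi / 180
  pole <- c(-sin(thD), 0, cos(thD)) * 7.7
  dpole <- sqrt(colSums((t(smp$points3d) - pole)^2))
  cellMm <- 7.7 * sin(pi / 3) * (140 / 160) * pi / 180   # one cell at the border
  expect_lt(max(dpole) - min(dpole), 3 * cellMm)
  # denser sampling doubles the count
  smp20 <- resampleBorder(chain, dc, ph$landmarks@fovea, density = 20)
  expect_lte(abs(nrow(smp20$points3d) - floor(smp20$coveredDeg / 1.5)), 1)
})

test_that("nasal-only borders resample to nothing, with a warning", {
  surf <- flatSurface(n = 61, depthIndex = 20)
  dc <- discCentroid3d(rbind(c(28, 30), c(30, 32), c(32, 30), c(30, 28)),
                       surf, surf@geom)
  # fovea temporal (larger fast); border on the nasal side of the disc
  chain <- liftChain(bresenhamChain(rbind(c(10, 20), c(10, 40))), surf)
  expect_warning(smp <- resampleBorder(chain, dc, fovea = c(50, 30)),
                 "nasal")
  expect_equal(nrow(smp$points3d), 0L)
})

test_that("assessed angle equals the brute-force temporal bearing extent", {
  surf <- flatSurface(n = 61, depthIndex = 20)
  g <- surf@geom
  dc <- discCentroid3d(rbind(c(28, 30), c(30, 32), c(32, 30), c(30, 28)),
                       surf, g)
  fovea <- c(50, 30)
  set.seed(13)
  for (i in 1:5) {
    pts <- cbind(sample(35:58, 4), sample(5:55, 4))
    chain <- liftChain(bresenhamChain(pts), surf)
    a <- assessedAngle(chain, dc, fovea)
    # direct scan over chain cells
    v <- sweep(chain@cells, 2, dc@enfaceCenter)
    u <- fovea - dc@enfaceCenter
    b <- atan2(u[1] * v[, 2] - u[2] * v[, 1],
               u[1] * v[, 1] + u[2] * v[, 2]) * 180 / pi
    b <- b[abs(b) < 90]
    expect_equal(a, max(b) - min(b), tolerance = 1e-9)
    expect_lte(a, 180)
  }
})

test_that("landmark JSON round-trips and bounds are enforced", {
  lms <- LandmarkSet(discEdge = rbind(c(10, 12), c(14, 16), c(12, 8)),
                     fovea = c(30, 31), border = rbind(c(5, 6), c(40, 41)),
                     laterality = "OS")
  path <- tempfile(fileext = ".json")
  writeLandmarks(lms, path)
  back <- readLandmarks(path)
  expect_equal(back@discEdge, lms@discEdge)
  expect_equal(back@fovea, lms@fovea)
  expect_equal(back@border, lms@border)
  expect_identical(back@laterality, "OS")
  g <- ScanGeometry(32, 32, 16)
  err <- tryCatch(validateLandmarks(lms, g), error = identity)
  expect_s3_class(err, "ropzone_annotation")
  expect_match(conditionMessage(err), "border point 2")
})
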