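# Shared fixture builders. Phantoms are generated in code at test time;
# a small cache avoids regenerating identical phantoms across tests in a
# file.

.phantomCache <- new.env(parent = emptyenv())

cachedPhantom <- function(spec = PhantomSpec(), nEnface = 160L) {
  key <- paste(c(nEnface, spec@sphereRadiusMm, spec@borderBaseDeg,
                 spec@notchDepthDeg, spec@notchWidthDeg, spec@notchCenterDeg,
                 spec@borderSpanDeg, spec@noise, spec@seed,
                 spec@foveaOffsetDeg), collapse = "_")
  if (is.null(.phantomCache[[key]]))
    .phantomCache[[key]] <- generatePhantom(spec, nEnface = nEnface)
  .phantomCache[[key]]
}

# a tiny label volume from a list of per-column depth label vectors laid
# out on a 2 x nSlow grid
tinyVolume <- function(columns, depthStepMm = 0.05, pivotOffsetMm = 0) {
  nd <- length(columns[[1]])
  ns <- max(2L, ceiling(length(columns) / 2))
  arr <- array(0L, dim = c(2L, ns, nd))
  for (i in seq_along(columns)) {
    f <- (i - 1L) %% 2L + 1L
    s <- (i - 1L) %/% 2L + 1L
    arr[f, s, ] <- columns[[i]]
  }
  LabelVolume(arr, ScanGeometry(2L, ns, nd, fovFastDeg = 20, fovSlowDeg = 20,
                                depthStepMm = depthStepMm,
                                pivotOffsetMm = pivotOffsetMm))
}

# synthetic constant-depth surface on an n x n grid (all columns valid)
flatSurface <- function(n = 41L, depthIndex = 10, geom = NULL) {
  if (is.null(geom))
    geom <- ScanGeometry(n, n, 32L, fovFastDeg = 120, fovSlowDeg = 120,
                         depthStepMm = 0.05, pivotOffsetMm = 7)
  new("RpeSurface", zRpe = matrix(depthIndex, geom@nFast, geom@nSlow),
      valid = matrix(TRUE, geom@nFast, geom@nSlow), geom = geom,
      nMultiRun = 0L)
}
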