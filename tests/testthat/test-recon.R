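## a minimal hand-built RawScan with one A-line per channel
rawFromSignal <- function(sig, config) {
  nS <- length(sig)
  arr <- array(sig, c(1, 1, nS))
  new("RawScan", ch1 = arr, ch2 = arr, config = config,
      omegaDeg = matrix(30, 1, 2), fastPosLocalMm = matrix(0.35, 1, 2),
      channelOffsetMm = c(0, config@channelRangeMm - config@overlapMm),
      facetOfBscan = 0L, yPosMm = 0, truth = list())
}

gaussPulse <- function(nS, center0, sigma = 2.335, f0 = 0.12) {
  t <- (seq_len(nS) - 1) - center0
  exp(-t^2 / (2 * sigma^2)) * cos(2 * pi * f0 * t)
}

test_that("envelope extraction behaves like an amplitude detector", {
  expect_equal(envelope(numeric(64)), numeric(64))
  x <- 2.5 * sin(2 * pi * 0.1 * (0:499))
  e <- envelope(x)
  expect_lt(max(abs(e[50:450] - 2.5)) / 2.5, 0.01)
  g <- gaussPulse(512, 200)
  expect_lt(abs(which.max(envelope(g)) - 1 - 200), 1.5)
})

test_that("time gating separates the two wavelength pulses", {
  cfg <- deskConfig(pulseDelayNs = 448, depthRangeMm = 1.7)
  nS <- 520
  sig <- gaussPulse(nS, 250) + 0.8 * gaussPulse(nS, 362)  # shift 112
  raw <- rawFromSignal(sig, cfg)
  pair <- demultiplexWavelengths(raw, 1)
  expect_false(pair@emptyFlag[1, 1])
  w1 <- pair@a532[1, 1, ]
  w2 <- pair@a558[1, 1, ]
  ## window length respects the invariant W <= round(delay * fs)
  expect_lte(pair@windowSamples, round(448 * 0.25))
  ## each window captures its own peak only, at the same in-window offset
  off1 <- which.max(w1); off2 <- which.max(w2)
  expect_lt(abs(off1 - off2), 1.5)
  expect_equal(max(w2) / max(w1), 0.8, tolerance = 1e-3)
  ## peak 1 only in window 1: away from the peak the window is quiet
  quiet1 <- w1[-(max(1, off1 - 10):min(length(w1), off1 + 10))]
  expect_lt(max(quiet1), 0.05 * max(w1))

  ## all-zero A-line: flagged empty with all-zero windows
  raw0 <- rawFromSignal(numeric(nS), cfg)
  pair0 <- demultiplexWavelengths(raw0, 1)
  expect_true(pair0@emptyFlag[1, 1])
  expect_true(all(pair0@a532 == 0) && all(pair0@a558 == 0))
})

test_that("demultiplexed windows match separate single-wavelength records", {
  tab <- defaultExtinctionTable()
  cfg <- deskConfig(fovSlowMm = 0.02)
  spec <- PhantomSpec(extentMm = c(1.2, 0.06, 0.4), voxelUm = 10,
                      nVessels = 2L, radiusRangeUm = c(30, 50), seed = 8)
  ph <- generateVesselPhantom(spec)
  raw <- simulateScan(ph, cfg, seed = 1)
  pair <- demultiplexWavelengths(raw, 1)

  ## oracle: rebuild chosen A-lines with one wavelength silenced and gate
  ## the clean record at the same anchor
  vols <- dcpam:::aperturedVolumes(ph, cfg, tab)
  zMm <- (seq_len(dim(ph@cHbO2)[3]) - 0.5) * ph@voxelUm / 1000
  nS <- dim(rawChannel(raw, 1))[3]
  checked <- 0
  for (b in seq_len(dim(pair@a532)[1])) {
    for (a in seq(1, dim(pair@a532)[2], by = 5)) {
      if (pair@emptyFlag[b, a] || checked >= 8) next
      x <- raw@fastPosLocalMm[a, 1]
      p532 <- dcpam:::volumeColumn(vols$a532, x, raw@yPosMm[b], ph@voxelUm)
      delta <- pathOffsetMm(raw@omegaDeg[a, 1], cfg@geometry, cfg, 1)
      only532 <- dcpam:::alineSignal(p532, numeric(length(zMm)), zMm,
                                     delta, cfg, nS)
      t0 <- pair@tSurf[b, a] + 1L
      w <- envelope(only532[t0:(t0 + pair@windowSamples - 1L)])
      expect_equal(max(pair@a532[b, a, ]), max(w), tolerance = 1e-9)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 4)
})

test_that("depth correction flattens the rotary-arc distortion", {
  cfg <- deskConfig(fovSlowMm = 0.005, arcSagMm = 0.3, depthRangeMm = 0.6,
                    prfKHz = 30.3, latticeUm = 5)
  ph <- flatTargetPhantom(0.3, extentMm = c(1.2, 0.05, 0.6), voxelUm = 10)
  raw <- simulateScan(ph, cfg, seed = 1)
  pair <- demultiplexWavelengths(raw, 1)
  volRawD <- assembleVolume(pair, cfg)
  pairC <- depthCorrect(pair, cfg@geometry, cfg)
  volCorr <- assembleVolume(pairC, cfg)

  zRaw <- surfaceDepthUm(volRawD)
  zCorr <- surfaceDepthUm(volCorr)
  ok <- is.finite(zRaw) & is.finite(zCorr)
  spreadRaw <- diff(range(zRaw[ok]))
  spreadCorr <- diff(range(zCorr[ok]))
  expect_gt(spreadRaw, 100)            # the injected sagitta is ~300 um
  expect_lt(spreadCorr, cfg@axialResUm)
  expect_lt(spreadCorr, spreadRaw)

  ## center-of-facet A-line is untouched; re-application is a no-op
  fp <- dcpam:::facetPass(cfg@geometry, 1)
  centerA <- which.min(abs((raw@omegaDeg[, 1] - fp["start"]) -
                           fp["width"] / 2))
  expect_equal(pairC@a532[1, centerA, ], pair@a532[1, centerA, ],
               tolerance = 1e-9)
  pairC2 <- depthCorrect(pairC, cfg@geometry, cfg)
  expect_identical(pairC2@a532, pairC@a532)
  expect_identical(pairC2@tSurf, pairC@tSurf)
})

test_that("volume assembly scatters, averages and tracks occupancy", {
  cfg <- deskConfig(latticeUm = 10)
  W <- 4L
  mk <- function(vals, positions) {
    nA <- length(positions)
    a <- array(0, c(1, nA, W))
    for (i in seq_len(nA)) a[1, i, ] <- vals[i]
    new("WavelengthPair", a532 = a, a558 = a / 2,
        tSurf = matrix(0L, 1, nA), emptyFlag = matrix(FALSE, 1, nA),
        windowSamples = W, channel = 1L,
        omegaDeg = rep(30, nA), fastPosLocalMm = positions,
        facetOfBscan = 0L, yPosMm = 0, depthCorrected = TRUE)
  }
  ## exact bin centers: lossless placement
  pos <- c(0.005, 0.015, 0.025)
  vol <- assembleVolume(mk(c(1, 2, 3), pos), cfg)
  expect_equal(vol@a532[1, 1:3, 1], c(1, 2, 3))
  ## two A-lines in one bin hold their mean
  vol2 <- assembleVolume(mk(c(1, 3), c(0.012, 0.014)), cfg)
  expect_equal(vol2@a532[1, 2, 1], 2)
  ## dropped positions are counted
  vol3 <- assembleVolume(mk(c(1, 1), c(0.005, 5)), cfg)
  expect_identical(vol3@provenance$droppedAlines, 1L)

  ## occupancy of a nonuniform raster matches the counting expectation
  cfgO <- deskConfig(latticeUm = 5, fovSlowMm = 0.005)
  ph <- flatTargetPhantom(0.2, extentMm = c(1.2, 0.05, 0.5), voxelUm = 10)
  rawO <- simulateScan(ph, cfgO, seed = 1)
  pairO <- demultiplexWavelengths(rawO, 1)
  volO <- assembleVolume(pairO, cfgO)
  nA <- dim(rawChannel(rawO, 1))[2]
  nx <- round(cfgO@channelRangeMm * 1e3 / cfgO@latticeUm)
  expected <- length(unique(round(rawO@fastPosLocalMm[, 1] * 1e3 /
                                  cfgO@latticeUm + 0.5))) / nx
  expect_lt(abs(volO@provenance$occupancy - expected) / expected, 0.02)
})

test_that("MIP takes per-pixel maxima and is stable", {
  v <- array(0, c(4, 5, 6))
  v[, , 3] <- matrix(runif(20), 4, 5)
  expect_equal(projectMip(v), v[, , 3])
  expect_equal(projectMip(array(0, c(3, 3, 3))), matrix(0, 3, 3))
  set.seed(2)
  r <- array(runif(4 * 5 * 6), c(4, 5, 6))
  m <- projectMip(r)
  expect_true(all(m >= apply(r, c(1, 2), function(z) max(z))))
  ## permutation-invariant along z, idempotent as an image op
  expect_equal(projectMip(r[, , sample(6)]), m)
})

test_that("stitching blends the overlap and conserves the rest", {
  cfg <- deskConfig(latticeUm = 10)     # 70-px channels, 20-px overlap
  n1 <- 70
  c1 <- matrix(5, 8, n1); c2 <- matrix(5, 8, n1)
  out <- stitchChannels(c1, c2, cfg)
  expect_equal(ncol(out),
               round(effectiveRangeMm(0.7, 0.7, 0.2) * 1e3 / cfg@latticeUm))
  expect_true(all(out == 5))            # ramp preserves constants
  ## zero overlap: plain concatenation
  cfg0 <- deskConfig(overlapMm = 0, latticeUm = 10)
  out0 <- stitchChannels(c1, c2, cfg0)
  expect_equal(ncol(out0), 140)
  ## pixel mass outside the band is copied verbatim
  set.seed(3)
  a <- matrix(runif(8 * n1), 8); b <- matrix(runif(8 * n1), 8)
  s <- stitchChannels(a, b, cfg)
  expect_identical(s[, 1:50], a[, 1:50])
  expect_identical(s[, 71:120], b[, 21:70])
  expect_error(stitchChannels(a, b[1:4, ], cfg), "slow-axis")
})
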