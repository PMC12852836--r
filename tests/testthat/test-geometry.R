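test_that("initial angle follows arccos(d/R) with domain checks", {
  expect_equal(initialAngle(ScannerGeometry(radiusMm = 7, beamOffsetMm = 7)), 0)
  expect_equal(initialAngle(ScannerGeometry(radiusMm = 7, beamOffsetMm = 0)), 90)
  expect_equal(initialAngle(ScannerGeometry(radiusMm = 7, beamOffsetMm = 3.5)), 60)
  expect_error(initialAngle(new("ScannerGeometry", radiusMm = 7,
                                beamOffsetMm = 8, nFacets = 6L,
                                facetWidthMm = 7, facetHeightMm = 10)),
               "beamOffsetMm")
  expect_error(ScannerGeometry(radiusMm = 7, beamOffsetMm = -1),
               "beamOffsetMm")
})

test_that("steering-angle sums are 60 deg (central) and 120 deg (outer)", {
  geom <- ScannerGeometry(radiusMm = 7, beamOffsetMm = 5)
  theta0 <- initialAngle(geom)
  omCentral <- seq(60 - theta0 + 0.2, theta0 - 0.2, length.out = 40)
  omOuter <- seq(theta0, 59.9, length.out = 40)
  ca <- channelAngles(c(omCentral, omOuter), geom)
  expect_true(all(ca$regime[1:40] == "central"))
  expect_true(all(ca$regime[41:80] == "outer"))
  expect_equal(ca$theta1[1:40] + ca$theta2[1:40], rep(60, 40),
               tolerance = 1e-12)
  expect_equal(ca$theta1[41:80] + ca$theta2[41:80], rep(120, 40),
               tolerance = 1e-12)
  ## boundary omega = theta0 belongs to the 120-deg case
  atBoundary <- channelAngles(theta0, geom)
  expect_identical(atBoundary$regime, "outer")
  expect_equal(atBoundary$theta1 + atBoundary$theta2, 120, tolerance = 1e-9)
  ## below the central regime: flagged facet-transition, not an error
  low <- channelAngles(seq(0.5, 60 - theta0 - 0.5, length.out = 7), geom)
  expect_true(all(low$regime == "facet-transition"))
})

test_that("channel angles agree with the brute-force ray-trace oracle", {
  geom <- ScannerGeometry(radiusMm = 7, beamOffsetMm = 5)
  om <- seq(0.05, 59.95, length.out = 101)
  ca <- channelAngles(om, geom)
  orc <- rayTraceOracle(om, R = 7, d = 5)
  expect_equal(ca$theta1, orc$theta1, tolerance = 1e-9)
  expect_equal(ca$theta2, orc$theta2, tolerance = 1e-9)

  ## randomized geometries: angles match the oracle over the full domain
  set.seed(101)
  for (k in 1:25) {
    R <- runif(1, 4, 10)
    d <- runif(1, 0.05, 0.95) * R
    g <- ScannerGeometry(radiusMm = R, beamOffsetMm = d)
    omk <- runif(5, 0.01, 59.99)
    cak <- channelAngles(omk, g)
    ok <- rayTraceOracle(omk, R = R, d = d)
    expect_equal(cak$theta1, ok$theta1, tolerance = 1e-9)
    expect_equal(cak$theta2, ok$theta2, tolerance = 1e-9)
  }
  ## within the operating band (theta0 in [30, 60] deg) the regime sums
  ## reduce exactly to 60 / 120
  for (k in 1:25) {
    R <- runif(1, 4, 10)
    d <- runif(1, 0.51, 0.86) * R
    g <- ScannerGeometry(radiusMm = R, beamOffsetMm = d)
    cak <- channelAngles(runif(8, 0.01, 59.99), g)
    sums <- cak$theta1 + cak$theta2
    expect_equal(sums[cak$regime == "central"],
                 rep(60, sum(cak$regime == "central")), tolerance = 1e-9)
    expect_equal(sums[cak$regime == "outer"],
                 rep(120, sum(cak$regime == "outer")), tolerance = 1e-9)
  }
})

test_that("focus trajectory spans the channel range monotonically", {
  geom <- ScannerGeometry()
  cfg <- deskConfig()
  for (chn in 1:2) {
    fp <- dcpam:::facetPass(geom, chn)
    omClosed <- seq(fp["start"], fp["start"] + fp["width"], length.out = 201)
    pos <- focusTrajectory(omClosed, geom, cfg, chn)
    expect_equal(max(pos) - min(pos), cfg@channelRangeMm, tolerance = 1e-6)
    dd <- diff(pos)
    expect_true(all(dd > 0) || all(dd < 0))
    ## pass center maps to the range midpoint
    expect_equal(focusTrajectory(fp["start"] + fp["width"] / 2, geom, cfg, chn),
                 cfg@channelRangeMm / 2, tolerance = 1e-9)
  }
  ## positions are affine in the oracle's reflected-ray angle within a pass
  fp <- dcpam:::facetPass(geom, 1)
  om <- seq(fp["start"] + 0.1, fp["start"] + fp["width"] - 0.1,
            length.out = 50)
  pos <- focusTrajectory(om, geom, cfg, 1)
  beta <- rayTraceOracle(om, geom@radiusMm, geom@beamOffsetMm)$beta1
  betaU <- beta + cumsum(c(0, ifelse(abs(diff(beta)) > 180,
                                     -sign(diff(beta)) * 360, 0)))
  fit <- stats::lm(pos ~ betaU)
  expect_lt(max(abs(stats::residuals(fit))), 1e-9)
  expect_error(focusTrajectory(numeric(0), geom, cfg, 1), "empty")
})

test_that("pulse separation is delay times sound speed", {
  expect_equal(pulseSeparationMm(450, 1500), 0.675)
  expect_equal(pulseSeparationMm(0, 1500), 0)
  expect_equal(pulseSeparationMm(1000, 1500), 1.5)
  expect_error(pulseSeparationMm(-1, 1500), ">= 0")
  ## bilinearity
  set.seed(7)
  d <- runif(20, 0, 2000); c0 <- runif(20, 1000, 2000)
  expect_equal(pulseSeparationMm(2 * d, c0), 2 * pulseSeparationMm(d, c0))
  expect_equal(pulseSeparationMm(d, 3 * c0), 3 * pulseSeparationMm(d, c0))
})

test_that("effective range adds channels minus overlap", {
  expect_equal(effectiveRangeMm(14, 14, 4), 24)
  expect_equal(effectiveRangeMm(14, 14, 0), 28)
  expect_equal(effectiveRangeMm(14, 14, 14), 14)
  expect_error(effectiveRangeMm(14, 14, 15), "exceeds")
})

test_that("timing summary identities hold on randomized configurations", {
  set.seed(11)
  for (k in 1:10) {
    cfg <- ScanConfig(prfKHz = runif(1, 100, 2000),
                      bscanRateHz = runif(1, 100, 1000),
                      slowStepUm = runif(1, 2, 20),
                      fovSlowMm = runif(1, 5, 30),
                      channelRangeMm = runif(1, 8, 20),
                      overlapMm = runif(1, 0, 6),
                      rpm = runif(1, 1000, 12000))
    ts <- timingSummary(cfg)
    expect_equal(ts$scan_time_s,
                 (cfg@fovSlowMm * 1e3 / cfg@slowStepUm) / cfg@bscanRateHz)
    expect_equal(ts$avg_fast_step_um,
                 cfg@channelRangeMm * 1e3 * cfg@bscanRateHz /
                   (cfg@prfKHz * 1e3))
    expect_equal(ts$bscan_rate_from_rpm_Hz, cfg@rpm / 60 * 6)
    expect_equal(ts$alines_per_bscan, cfg@prfKHz * 1e3 / cfg@bscanRateHz)
    expect_equal(ts$overlap_fraction_pct,
                 100 * cfg@overlapMm / cfg@channelRangeMm)
  }
})

test_that("config validity enforces the design constraints", {
  expect_error(ScanConfig(pulseDelayNs = 100),
               "must exceed depthOfFocusMm")
  expect_error(ScanConfig(overlapMm = 15), "smaller than channelRangeMm")
  expect_error(ScanConfig(digitizerRateMHz = -1), "strictly positive")
})
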