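## Shared test fixtures and independent oracles. The ray-trace oracle is
## deliberately a different implementation from the package's steering
## model: it intersects each fixed incident beam with all facet segments
## of the rotated polygon and reflects about the winning facet's normal.

rayTraceOracle <- function(omegaDeg, R, d, nFacets = 6L) {
  period <- 360 / nFacets
  a <- R * cos(pi / nFacets)
  traceOne <- function(origin, dir, om) {
    best <- NULL
    for (k in 0:(nFacets - 1)) {
      psi <- (om + k * period) * pi / 180
      n <- c(cos(psi), sin(psi))
      denom <- sum(dir * n)
      if (denom >= -1e-14) next                  # must hit the outward side
      t <- (a - sum(origin * n)) / denom
      if (t <= 0) next
      p <- origin + t * dir
      v1 <- R * c(cos(psi - pi / nFacets), sin(psi - pi / nFacets))
      v2 <- R * c(cos(psi + pi / nFacets), sin(psi + pi / nFacets))
      e <- v2 - v1
      s <- sum((p - v1) * e) / sum(e * e)
      if (s < -1e-12 || s > 1 + 1e-12) next
      if (is.null(best) || t < best$t)
        best <- list(t = t, n = n, k = k)
    }
    if (is.null(best)) return(c(theta = NA_real_, beta = NA_real_))
    refl <- dir - 2 * sum(dir * best$n) * best$n
    c(theta = acos(min(abs(sum(dir * best$n)), 1)) * 180 / pi,
      beta = atan2(refl[2], refl[1]) * 180 / pi)
  }
  L <- 100 * R
  out <- t(vapply(omegaDeg, function(om) {
    b1 <- traceOne(c(L, d), c(-1, 0), om)
    b2 <- traceOne(c(-L, d), c(1, 0), om)
    c(theta1 = b1[["theta"]], theta2 = b2[["theta"]],
      beta1 = b1[["beta"]], beta2 = b2[["beta"]])
  }, numeric(4)))
  as.data.frame(out)
}

## desk-scale acquisition settings: same physics constants as the full
## system, scan extents shrunk so a simulation runs in seconds
deskConfig <- function(channelRangeMm = 0.7, overlapMm = 0.2,
                       fovSlowMm = 0.12, prfKHz = 19.2,
                       depthRangeMm = 0.5, arcSagMm = 0.1,
                       latticeUm = 10, ...) {
  ScanConfig(channelRangeMm = channelRangeMm, overlapMm = overlapMm,
             fovFastMm = channelRangeMm * 2 - overlapMm,
             fovSlowMm = fovSlowMm, prfKHz = prfKHz,
             depthRangeMm = depthRangeMm, arcSagMm = arcSagMm,
             latticeUm = latticeUm, ...)
}

## demultiplex -> depth-correct -> assemble -> MIP for one channel
reconChannelMip <- function(raw, channel) {
  cfg <- raw@config
  pair <- demultiplexWavelengths(raw, channel = channel)
  pair <- depthCorrect(pair, cfg@geometry, cfg)
  projectMip(assembleVolume(pair, cfg))
}

## full dual-channel reconstruction to stitched per-wavelength MIPs
reconStitched <- function(raw) {
  cfg <- raw@config
  m1 <- reconChannelMip(raw, 1)
  m2 <- reconChannelMip(raw, 2)
  list(a532 = stitchChannels(m1$a532, m2$a532, cfg),
       a558 = stitchChannels(m1$a558, m2$a558, cfg))
}

## facet-registration trial fixtures at the stated slow pitch (5 um
## rows): a wide vessel field split into facet stacks, then per-trial
## injected fast-axis shifts plus noise
vesselFacetStacks <- function(phantomSeed,
                              extentMm = c(0.96, 1.92, 0.15),
                              nVessels = 24) {
  spec <- PhantomSpec(extentMm = extentMm, voxelUm = 5,
                      nVessels = nVessels, radiusRangeUm = c(30, 60),
                      seed = phantomSeed)
  ph <- generateVesselPhantom(spec)
  img <- projectMip(ph@cHbO2 + ph@cHbR)
  splitByFacet(img, rep(0:5, length.out = nrow(img)))
}

facetTrial <- function(stacks, trialSeed, snrDb = 20, maxOffsetPx = 10) {
  offs <- withr_seed(trialSeed, stats::runif(6, -maxOffsetPx, maxOffsetPx))
  offs[1] <- 0
  shifted <- lapply(1:6, function(f) {
    m <- dcpam:::translateImage(stacks[[f]], 0, offs[f])
    if (is.finite(snrDb))
      m <- addNoise(m, snrDb, seed = trialSeed * 101 + f)
    attr(m, "rows") <- attr(stacks[[f]], "rows")
    m
  })
  list(stacks = shifted, offsetsPx = offs)
}

withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

## simple global SSIM (standard constants, full-image statistics)
ssim <- function(a, b) {
  L <- max(a, b) - min(a, b)
  if (L == 0) return(1)
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(as.vector(a)); vb <- stats::var(as.vector(b))
  cab <- stats::cov(as.vector(a), as.vector(b))
  ((2 * ma * mb + c1) * (2 * cab + c2)) /
    ((ma^2 + mb^2 + c1) * (va + vb + c2))
}

## per-column surface depth (um) of a volume's 532-nm grid, parabolic
## sub-sample refinement of the envelope peak
surfaceDepthUm <- function(vol, row = 1) {
  d <- dim(vol@a532)
  vapply(seq_len(d[2]), function(j) {
    p <- vol@a532[row, j, ]
    if (max(p) <= 0) return(NA_real_)
    i <- which.max(p)
    refine <- 0
    if (i > 1 && i < length(p)) {
      denom <- p[i - 1] - 2 * p[i] + p[i + 1]
      if (denom != 0) refine <- 0.5 * (p[i - 1] - p[i + 1]) / denom
    }
    vol@originMm[3] * 1e3 + (i - 1 + refine) * vol@zPitchUm
  }, numeric(1))
}
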