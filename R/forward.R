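## Forward acquisition model. Fluence is uniform at the focal plane and
## the Grueneisen coefficient is a global constant absorbed into the
## amplitude units, so simulated amplitudes are relative -- which is all
## the sO2 ratio needs. Acoustic travel is one-way (t = z / c): the
## photoacoustic source sits at the absorber.

## unit helpers
cMmPerNs <- function(config) config@soundSpeedMs * 1e-6   # mm per ns
dtNs <- function(config) 1e3 / config@digitizerRateMHz    # ns per sample

## transducer axial impulse response: Gaussian-modulated sinusoid at the
## transducer center frequency; the Gaussian sigma is chosen so the
## envelope FWHM maps to the configured axial resolution (bandwidth is
## otherwise unconstrained by the system description)
irSigmaNs <- function(config) {
  fwhmNs <- (config@axialResUm * 1e-3) / cMmPerNs(config)
  fwhmNs / (2 * sqrt(2 * log(2)))
}

## number of samples in one A-line record: depth range + arc sagitta +
## the wavelength separation + impulse-response tails
alineSamples <- function(config) {
  tMaxNs <- (config@depthRangeMm + config@arcSagMm) / cMmPerNs(config) +
    config@pulseDelayNs + 8 * irSigmaNs(config)
  as.integer(ceiling(tMaxNs / dtNs(config)))
}

## accumulate both wavelengths' echoes into one A-line signal.
## a532/a558: amplitude per occupied depth; zMm: matching depths (mm);
## extraPathMm: arc-induced additional acoustic path for this A-line.
alineSignal <- function(a532, a558, zMm, extraPathMm, config, nS) {
  sig <- numeric(nS)
  if (!length(zMm)) return(sig)
  dt <- dtNs(config)
  sigma <- irSigmaNs(config)
  f0 <- config@transducerMHz * 1e-3            # cycles per ns
  halfWin <- ceiling(6 * sigma / dt)
  for (lam in 1:2) {
    amp <- if (lam == 1) a532 else a558
    lagNs <- if (lam == 1) 0 else config@pulseDelayNs
    keep <- which(amp != 0)
    for (i in keep) {
      tc <- (zMm[i] + extraPathMm) / cMmPerNs(config) + lagNs
      ## sample with 0-based index k sits at t = k * dt
      n0 <- max(1L, floor(tc / dt) + 1L - halfWin)
      n1 <- min(nS, ceiling(tc / dt) + 1L + halfWin)
      if (n0 > n1) next
      t <- (n0:n1 - 1) * dt - tc
      sig[n0:n1] <- sig[n0:n1] +
        amp[i] * exp(-t^2 / (2 * sigma^2)) * sin(2 * pi * f0 * t)
    }
  }
  sig
}

## lateral-aperture weighted mu_a volumes (Gaussian of FWHM lateralResUm),
## returned as list(a532, a558) arrays [y, x, z]
aperturedVolumes <- function(phantom, config, table) {
  sigmaVox <- (config@lateralResUm / (2 * sqrt(2 * log(2)))) / phantom@voxelUm
  list(a532 = gaussBlurLateral(absorptionVolume(phantom, 532, table),
                               sigmaVox, sigmaVox),
       a558 = gaussBlurLateral(absorptionVolume(phantom, 558, table),
                               sigmaVox, sigmaVox))
}

## bilinear (x, y) sample of a volume's depth column; xMm/yMm scalar,
## returns the z profile; positions are clamped to the grid edge
volumeColumn <- function(vol, xMm, yMm, voxelUm) {
  d <- dim(vol)
  cx <- xMm * 1000 / voxelUm + 0.5
  cy <- yMm * 1000 / voxelUm + 0.5
  cx <- min(max(cx, 1), d[2]); cy <- min(max(cy, 1), d[1])
  x0 <- floor(cx); wx <- cx - x0; x1 <- min(x0 + 1, d[2])
  y0 <- floor(cy); wy <- cy - y0; y1 <- min(y0 + 1, d[1])
  (1 - wy) * ((1 - wx) * vol[y0, x0, ] + wx * vol[y0, x1, ]) +
    wy * ((1 - wx) * vol[y1, x0, ] + wx * vol[y1, x1, ])
}

#' Simulate a single time-resolved A-line
#'
#' Depth profile of the absorption coefficient along the beam column
#' (weighted by the Gaussian lateral aperture), convolved with the
#' transducer impulse response and placed at one-way travel times
#' `t = z / c`; the 558-nm echo is additionally delayed by the configured
#' pulse lag. Both wavelengths are summed into one record, exactly as the
#' digitizer sees them.
#'
#' @param phantom a [ChromophoreVolume].
#' @param beamXYMm beam position (x, y), mm; must lie inside the
#'   phantom's lateral extent.
#' @param config a [ScanConfig].
#' @param table an [ExtinctionTable].
#' @param extraPathMm additional acoustic path (rotary-arc offset), mm.
#' @param channel,facetIndex,bscanIndex metadata for the record.
#' @return an [ALineRecord].
#' @export
simulateAline <- function(phantom, beamXYMm, config, table,
                          extraPathMm = 0, channel = 1L, facetIndex = 0L,
                          bscanIndex = 0L) {
  d <- dim(phantom@cHbO2)
  extMm <- c(d[2], d[1]) * phantom@voxelUm / 1000
  if (beamXYMm[1] < 0 || beamXYMm[1] > extMm[1] ||
      beamXYMm[2] < 0 || beamXYMm[2] > extMm[2])
    stop(sprintf("beam (%.3f, %.3f) mm outside phantom lateral extent %.3f x %.3f mm",
                 beamXYMm[1], beamXYMm[2], extMm[1], extMm[2]))
  vols <- aperturedVolumes(phantom, config, table)
  p532 <- volumeColumn(vols$a532, beamXYMm[1], beamXYMm[2], phantom@voxelUm)
  p558 <- volumeColumn(vols$a558, beamXYMm[1], beamXYMm[2], phantom@voxelUm)
  zMm <- (seq_len(d[3]) - 0.5) * phantom@voxelUm / 1000
  nS <- alineSamples(config)
  new("ALineRecord",
      samples = alineSignal(p532, p558, zMm, extraPathMm, config, nS),
      channel = as.integer(channel), facetIndex = as.integer(facetIndex),
      bscanIndex = as.integer(bscanIndex),
      fastPositionMm = beamXYMm[1], triggerS = 0)
}

#' Additive white Gaussian noise at a target SNR
#'
#' Scales zero-mean Gaussian noise so `10 log10(P_signal / P_noise)`
#' equals `snrDb`, with `P_signal = mean(x^2)`. `snrDb = Inf` is the
#' noise-free sentinel and returns `x` unchanged; deterministic per seed.
#'
#' @param x numeric vector/array.
#' @param snrDb target signal-to-noise ratio (dB), or `Inf`.
#' @param seed RNG seed.
#' @return `x` plus noise, same shape.
#' @export
addNoise <- function(x, snrDb, seed = 1L) {
  if (is.infinite(snrDb) && snrDb > 0) return(x)
  if (!is.finite(snrDb)) stop("snrDb must be finite or +Inf")
  p <- mean(x^2)
  if (p == 0) stop("zero-power signal: finite SNR is undefined")
  sdn <- sqrt(p / 10^(snrDb / 10))
  withSeed(seed, x + array(stats::rnorm(length(x), 0, sdn),
                           dim = if (is.null(dim(x))) length(x) else dim(x)))
}

#' Simulate a full dual-channel volumetric scan
#'
#' Rasters both channels concurrently: each B-scan is one facet pass per
#' channel (A-lines on a uniform scan-angle grid spanning the pass, so
#' one pass covers `channelRangeMm`), the slow axis steps by
#' `slowStepUm`, and channel 2's range is offset so the two ranges
#' overlap by `overlapMm`. Injected per-facet offsets/gains and the
#' in-B-scan wobble perturb the *actual* sampling positions; the rotary
#' arc adds its depth offset; white Gaussian noise is added at `snrDb`.
#' The injected truth is stored in the returned object.
#'
#' @param phantom a [ChromophoreVolume] covering the scanned FOV.
#' @param config a [ScanConfig]; `fovSlowMm` and the stitched fast range
#'   must fit inside the phantom.
#' @param perturbation a [FacetPerturbation] (default: none).
#' @param snrDb white-noise level (dB); `Inf` = noise-free.
#' @param seed RNG seed for noise and wobble phases.
#' @param table an [ExtinctionTable].
#' @return a [RawScan].
#' @export
simulateScan <- function(phantom, config,
                         perturbation = NULL, snrDb = Inf, seed = 1L,
                         table = defaultExtinctionTable()) {
  geom <- config@geometry
  if (is.null(perturbation))
    perturbation <- FacetPerturbation(nFacets = geom@nFacets)
  if (length(perturbation@offsetsUm) != geom@nFacets)
    stop("perturbation length must equal nFacets")

  d <- dim(phantom@cHbO2)
  extMm <- c(d[2], d[1]) * phantom@voxelUm / 1000
  effRange <- effectiveRangeMm(config@channelRangeMm, config@channelRangeMm,
                               config@overlapMm)
  nB <- as.integer(round(config@fovSlowMm * 1e3 / config@slowStepUm))
  if (effRange > extMm[1] + 1e-9 || config@fovSlowMm > extMm[2] + 1e-9)
    stop(sprintf(
      "FOV %.3f x %.3f mm exceeds phantom lateral extent %.3f x %.3f mm",
      effRange, config@fovSlowMm, extMm[1], extMm[2]))

  nA <- as.integer(floor(config@prfKHz * 1e3 / config@bscanRateHz))
  if (nA < 2) stop("prf/bscanRate must give at least 2 A-lines per B-scan")
  nS <- alineSamples(config)
  chOffset <- c(0, config@channelRangeMm - config@overlapMm)

  ## nominal trajectory: A-lines at mid-step scan angles across each pass
  omega <- matrix(0, nA, 2)
  fastLocal <- matrix(0, nA, 2)
  for (ch in 1:2) {
    fp <- facetPass(geom, ch)
    omega[, ch] <- fp["start"] + (seq_len(nA) - 0.5) / nA * fp["width"]
    fastLocal[, ch] <- focusTrajectory(omega[, ch], geom, config, ch)
  }
  ## channel 2's pass sweeps the fast axis in reverse; store A-lines in
  ## position order so stacks read left-to-right
  ord2 <- order(fastLocal[, 2])
  omega[, 2] <- omega[ord2, 2]
  fastLocal[, 2] <- fastLocal[ord2, 2]

  vols <- aperturedVolumes(phantom, config, table)
  zMm <- (seq_len(d[3]) - 0.5) * phantom@voxelUm / 1000
  arc <- cbind(pathOffsetMm(omega[, 1], geom, config, 1),
               pathOffsetMm(omega[, 2], geom, config, 2))

  facetOf <- as.integer((seq_len(nB) - 1L) %% geom@nFacets)
  yPos <- (seq_len(nB) - 1L) * config@slowStepUm * 1e-3
  wobblePhase <- withSeed(childSeed(seed, "wobble"),
                          stats::runif(nB, 0, 2 * pi))

  ch <- list(array(0, c(nB, nA, nS)), array(0, c(nB, nA, nS)))
  for (b in seq_len(nB)) {
    f <- facetOf[b] + 1L
    wob <- perturbation@wobbleAmpUm * 1e-3 *
      sin(2 * pi * perturbation@wobbleCycles * (seq_len(nA) - 1) / nA +
          wobblePhase[b])
    for (cc in 1:2) {
      half <- config@channelRangeMm / 2
      xAct <- perturbation@gains[f] * (fastLocal[, cc] - half) + half +
        perturbation@offsetsUm[f] * 1e-3 + wob + chOffset[cc]
      for (a in seq_len(nA)) {
        p532 <- volumeColumn(vols$a532, xAct[a], yPos[b], phantom@voxelUm)
        p558 <- volumeColumn(vols$a558, xAct[a], yPos[b], phantom@voxelUm)
        ch[[cc]][b, a, ] <- alineSignal(p532, p558, zMm, arc[a, cc],
                                        config, nS)
      }
    }
  }
  if (is.finite(snrDb)) {
    ch[[1]] <- addNoise(ch[[1]], snrDb, childSeed(seed, "noise1"))
    ch[[2]] <- addNoise(ch[[2]], snrDb, childSeed(seed, "noise2"))
  }

  new("RawScan", ch1 = ch[[1]], ch2 = ch[[2]], config = config,
      omegaDeg = omega, fastPosLocalMm = fastLocal,
      channelOffsetMm = chOffset, facetOfBscan = facetOf, yPosMm = yPos,
      truth = list(perturbation = perturbation, snrDb = snrDb,
                   seed = as.integer(seed), phantomSpec = phantom@spec,
                   wobblePhase = wobblePhase))
}
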