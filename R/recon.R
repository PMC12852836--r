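## Reconstruction: in-A-line wavelength demultiplexing, depth correction,
## volume assembly, en-face projection and dual-channel stitching.

#' Demultiplex the two wavelengths within each A-line
#'
#' The 558-nm pulse lags the 532-nm pulse by the configured delay, so the
#' two wavelengths' echoes occupy disjoint time windows within one
#' A-line. Gating is surface-anchored: the surface time `t_surf` is the
#' first envelope sample above threshold (5x the record's MAD by
#' default), the 532-nm window is `[t_surf, t_surf + W)` with
#' `W = floor(delay * fs)` samples, and the 558-nm window is the same
#' interval after the record is advanced by the *exact* (fractional)
#' delay `delay * fs` via Fourier resampling -- so both windows sample
#' identical waveforms and amplitude ratios carry no half-sample
#' sampling-phase error.
#'
#' @param raw a [RawScan].
#' @param channel 1 or 2.
#' @param thresholdFactor surface threshold in MADs of the envelope.
#' @param guardSamples ring-down guard subtracted from the gate length so
#'   the tail of the *other* wavelength's pulse never enters a window;
#'   default: the 6-sigma impulse-response extent from the config.
#' @return a [WavelengthPair]; A-lines with no supra-threshold sample are
#'   flagged empty (not an error).
#' @export
demultiplexWavelengths <- function(raw, channel = 1L, thresholdFactor = 5,
                                   guardSamples = NULL) {
  config <- raw@config
  stack <- rawChannel(raw, channel)
  nB <- dim(stack)[1]; nA <- dim(stack)[2]; nS <- dim(stack)[3]
  shift <- config@pulseDelayNs * config@digitizerRateMHz * 1e-3
  if (is.null(guardSamples))
    guardSamples <- ceiling(8 * irSigmaNs(config) / dtNs(config))
  W <- as.integer(floor(shift) - guardSamples)
  if (W < 1) stop("pulse delay too short for the gate: nothing to demultiplex")

  a532 <- array(0, c(nB, nA, W))
  a558 <- array(0, c(nB, nA, W))
  tSurf <- matrix(0L, nB, nA)
  emptyFlag <- matrix(FALSE, nB, nA)
  nOverrun <- 0L
  globalMax <- max(abs(stack))

  ## surface detector: boxcar-smoothed envelope over about one pulse
  ## width, so single-sample noise spikes cannot fake a surface while a
  ## real pulse edge still triggers at its rise
  wBox <- 2L * ceiling(irSigmaNs(config) / dtNs(config)) + 1L
  box <- rep(1 / wBox, wBox)

  for (b in seq_len(nB)) {
    m <- t(stack[b, , , drop = TRUE])          # samples x alines
    if (nA == 1) m <- matrix(stack[b, 1, ], ncol = 1)
    env <- Mod(analyticSignal(m))              # surface detection only
    envSm <- apply(env, 2, function(e)
      as.numeric(stats::filter(e, box, sides = 2)))
    envSm[is.na(envSm)] <- 0
    mShift <- fourierShift(m, -shift)          # exact fractional advance
    for (a in seq_len(nA)) {
      e <- envSm[, a]
      ## noise floor: the envelope has a positive mean under noise, so
      ## threshold above the record's median, not above zero
      thr <- max(stats::median(e) + thresholdFactor * stats::mad(e),
                 1e-3 * globalMax)
      hit <- which(e > thr)
      if (!length(hit)) {
        emptyFlag[b, a] <- TRUE
        next
      }
      t0 <- hit[1]                              # 1-based R index
      if (t0 + W - 1L > nS) {
        ## no room for a gate after this crossing: an isolated late
        ## "surface" is a noise spike, flagged empty; widespread
        ## overruns are a systemic depth-range problem (checked below)
        emptyFlag[b, a] <- TRUE
        nOverrun <- nOverrun + 1L
        next
      }
      tSurf[b, a] <- t0 - 1L                    # 0-based
      ## gate the raw signal first, then envelope each window separately:
      ## inside a gate the record is (to the pulse's Gaussian decay) a
      ## scaled copy of the same waveform at both wavelengths, so the
      ## amplitude ratio carries no envelope-tail cross-talk
      win <- t0:(t0 + W - 1L)
      a532[b, a, ] <- envelope(m[win, a])
      a558[b, a, ] <- envelope(mShift[win, a])
    }
  }
  if (nOverrun > 0.2 * nB * nA)
    stop(sprintf(
      paste0("gating window (%d samples) overruns the %d-sample record on ",
             "%d of %d A-lines: increase depthRangeMm or shorten the gate"),
      W, nS, nOverrun, nB * nA))
  new("WavelengthPair", a532 = a532, a558 = a558, tSurf = tSurf,
      emptyFlag = emptyFlag, windowSamples = W,
      channel = as.integer(channel),
      omegaDeg = raw@omegaDeg[, channel],
      fastPosLocalMm = raw@fastPosLocalMm[, channel],
      facetOfBscan = raw@facetOfBscan, yPosMm = raw@yPosMm,
      depthCorrected = FALSE)
}

## depth pitch of the native A-line sampling (um per sample)
nativeZPitchUm <- function(config) {
  cMmPerNs(config) * dtNs(config) * 1e3
}

#' @describeIn depthCorrect per-A-line correction of the demultiplexed
#'   windows: the arc offset delta(omega) from [pathOffsetMm] is removed
#'   by an integer adjustment of the surface anchor plus a sub-sample
#'   linear re-interpolation of the window content. Re-application is a
#'   no-op (the object is marked corrected).
#' @export
setMethod("depthCorrect", "WavelengthPair",
  function(x, geom, config, ...) {
    if (x@depthCorrected) return(x)
    delta <- pathOffsetMm(x@omegaDeg, geom, config, x@channel)
    sSamples <- delta * 1e3 / nativeZPitchUm(config)
    sInt <- round(sSamples)
    sFrac <- sSamples - sInt
    nB <- dim(x@a532)[1]
    for (a in seq_len(ncol(x@tSurf))) {
      if (sInt[a] == 0 && sFrac[a] == 0) next
      x@tSurf[, a] <- x@tSurf[, a] - as.integer(sInt[a])
      if (sFrac[a] != 0) for (b in seq_len(nB)) {
        x@a532[b, a, ] <- linearShift(x@a532[b, a, ], -sFrac[a])
        x@a558[b, a, ] <- linearShift(x@a558[b, a, ], -sFrac[a])
      }
    }
    x@depthCorrected <- TRUE
    x
  })

#' @describeIn depthCorrect column-wise correction of an assembled
#'   volume, using the per-column scan-angle provenance; columns at the
#'   facet-pass center (delta = 0) are untouched. Idempotent via the
#'   provenance flag.
#' @export
setMethod("depthCorrect", "ImageVolume",
  function(x, geom, config, ...) {
    prov <- x@provenance
    if (is.null(prov$omegaOfCol) || is.null(prov$channel))
      stop("volume lacks scan-angle provenance; cannot depth-correct")
    if (isTRUE(prov$depthCorrected)) return(x)
    delta <- pathOffsetMm(prov$omegaOfCol, geom, config, prov$channel)
    sSamples <- delta * 1e3 / x@zPitchUm
    d <- dim(x@a532)
    for (j in seq_len(d[2])) {
      if (!is.finite(sSamples[j]) || sSamples[j] == 0) next
      for (i in seq_len(d[1])) {
        x@a532[i, j, ] <- linearShift(x@a532[i, j, ], -sSamples[j])
        x@a558[i, j, ] <- linearShift(x@a558[i, j, ], -sSamples[j])
      }
    }
    x@provenance$depthCorrected <- TRUE
    x
  })

#' Assemble demultiplexed A-lines into a regular volume
#'
#' Scatters each A-line onto the reconstruction lattice at its
#' (possibly nonuniform) fast-axis position by nearest-bin assignment,
#' averaging collisions; the depth axis keeps the native sampling pitch,
#' anchored at the shallowest detected surface. Positions outside the
#' lattice are dropped and counted in the provenance.
#'
#' @param pair a [WavelengthPair].
#' @param config a [ScanConfig] (lattice pitch, channel range).
#' @param positionsMm fast-axis position per A-line (default: the nominal
#'   trajectory carried by `pair`).
#' @return an [ImageVolume] `[nBscan, nx, nz]`.
#' @export
assembleVolume <- function(pair, config, positionsMm = NULL) {
  if (is.null(positionsMm)) positionsMm <- pair@fastPosLocalMm
  nA <- dim(pair@a532)[2]
  if (length(positionsMm) != nA)
    stop("need one fast-axis position per A-line")
  pitchMm <- config@latticeUm * 1e-3
  nx <- as.integer(round(config@channelRangeMm / pitchMm))
  ix <- as.integer(round(positionsMm / pitchMm + 0.5))
  keep <- ix >= 1L & ix <= nx
  dropped <- sum(!keep)

  nB <- dim(pair@a532)[1]; W <- pair@windowSamples
  use <- !pair@emptyFlag
  if (!any(use)) stop("every A-line is empty; nothing to assemble")
  z0 <- min(pair@tSurf[use])
  nz <- max(pair@tSurf[use]) - z0 + W
  a532 <- array(0, c(nB, nx, nz))
  a558 <- array(0, c(nB, nx, nz))
  hits <- matrix(0, nB, nx)
  omegaSum <- numeric(nx); omegaN <- integer(nx)

  for (a in seq_len(nA)) {
    if (!keep[a]) next
    j <- ix[a]
    omegaSum[j] <- omegaSum[j] + pair@omegaDeg[a]
    omegaN[j] <- omegaN[j] + 1L
    for (b in seq_len(nB)) {
      if (pair@emptyFlag[b, a]) next
      zi <- (pair@tSurf[b, a] - z0) + seq_len(W)
      a532[b, j, zi] <- a532[b, j, zi] + pair@a532[b, a, ]
      a558[b, j, zi] <- a558[b, j, zi] + pair@a558[b, a, ]
    }
    hits[, j] <- hits[, j] + as.numeric(use[, a])
  }
  scale <- ifelse(hits > 0, 1 / hits, 0)
  for (k in seq_len(nz)) {
    a532[, , k] <- a532[, , k] * scale
    a558[, , k] <- a558[, , k] * scale
  }
  omegaOfCol <- ifelse(omegaN > 0, omegaSum / pmax(omegaN, 1L), NA_real_)
  ## lattice occupancy counts assigned A-lines (empty-flagged ones are
  ## still assigned to their bin; they just contribute no amplitude)
  occupancy <- mean(tabulate(ix[keep], nbins = nx) > 0)

  new("ImageVolume", a532 = a532, a558 = a558,
      pitchUm = config@latticeUm, zPitchUm = nativeZPitchUm(config),
      originMm = c(0, 0, z0 * nativeZPitchUm(config) * 1e-3),
      provenance = list(channel = pair@channel, omegaOfCol = omegaOfCol,
                        facetOfRow = pair@facetOfBscan,
                        depthCorrected = pair@depthCorrected,
                        droppedAlines = dropped,
                        occupancy = occupancy))
}

#' @describeIn projectMip per-(x, y) maximum over the depth axis of a 3-D
#'   array.
#' @export
setMethod("projectMip", "array", function(x, ...) {
  stopifnot(length(dim(x)) == 3L)
  apply(x, c(1, 2), max)
})

#' @describeIn projectMip en-face MIPs of both wavelengths of an
#'   [ImageVolume]; returns `list(a532, a558, pitchUm)`.
#' @export
setMethod("projectMip", "ImageVolume", function(x, ...) {
  list(a532 = projectMip(x@a532), a558 = projectMip(x@a558),
       pitchUm = x@pitchUm)
})

#' Stitch the two channels' en-face images
#'
#' Places channel 2's image `channelRange - overlap` to the right of
#' channel 1's and blends the shared `overlapMm` band with a ramp from
#' channel 1 to channel 2 (linear by default, cosine optional); pixels
#' outside the band are copied verbatim, so pixel mass there is conserved
#' exactly and two 14-mm channels with 4-mm overlap give a 24-mm output.
#'
#' @param img1,img2 en-face matrices of the two channels (equal row
#'   count, columns at `latticeUm` pitch).
#' @param config a [ScanConfig].
#' @param ramp `"linear"` or `"cosine"`.
#' @return stitched matrix of width
#'   `effectiveRangeMm(...) / latticeUm * 1000` columns.
#' @export
stitchChannels <- function(img1, img2, config, ramp = c("linear", "cosine")) {
  ramp <- match.arg(ramp)
  if (nrow(img1) != nrow(img2))
    stop("channel images must share the slow-axis extent")
  ov <- as.integer(round(config@overlapMm * 1e3 / config@latticeUm))
  n1 <- ncol(img1); n2 <- ncol(img2)
  if (ov > min(n1, n2)) stop("overlap exceeds a channel image width")
  out <- matrix(0, nrow(img1), n1 + n2 - ov)
  out[, seq_len(n1 - ov)] <- img1[, seq_len(n1 - ov), drop = FALSE]
  if (ov > 0) {
    w2 <- (seq_len(ov) - 0.5) / ov
    if (ramp == "cosine") w2 <- (1 - cos(pi * w2)) / 2
    blend <- sweep(img1[, n1 - ov + seq_len(ov), drop = FALSE], 2, 1 - w2, "*") +
      sweep(img2[, seq_len(ov), drop = FALSE], 2, w2, "*")
    out[, n1 - ov + seq_len(ov)] <- blend
  }
  out[, n1 + seq_len(n2 - ov)] <- img2[, ov + seq_len(n2 - ov), drop = FALSE]
  out
}
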