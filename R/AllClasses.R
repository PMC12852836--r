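## S4 classes for the dual-channel polygon-scanner PAM simulator.
## Conventions used throughout the package:
##   * volumes and image stacks are arrays [slow (y), fast (x), depth (z)],
##     en-face images are matrices [slow (y), fast (x)];
##   * angles cross API boundaries in degrees, lengths in the unit named by
##     the slot/argument suffix (mm, um, ns, MHz, kHz);
##   * indices reported in documentation are 0-based sample/pixel offsets,
##     R arrays are of course accessed 1-based.

#' Hexagon-scanner geometry
#'
#' Geometry of the rotating polygon mirror that steers both excitation
#' beams: circumscribed radius R, the orthogonal offset d of each fixed
#' incident beam from the polygon center, facet count, and the physical
#' facet aperture. The initial angle theta0 = arccos(d/R) derives from
#' these and separates the two steering regimes.
#'
#' @slot radiusMm circumscribed polygon radius R (mm). The shipped default
#'   interprets the 14-mm "polygon diameter" as circumscribed, so R = 7.
#' @slot beamOffsetMm orthogonal distance d from the polygon center to each
#'   incident beam (mm); must satisfy 0 <= d <= R.
#' @slot nFacets integer facet count (hexagon: 6).
#' @slot facetWidthMm facet extent along the fast axis (mm).
#' @slot facetHeightMm facet extent along the slow axis (mm).
#' @export
setClass("ScannerGeometry",
  representation(
    radiusMm = "numeric",
    beamOffsetMm = "numeric",
    nFacets = "integer",
    facetWidthMm = "numeric",
    facetHeightMm = "numeric"
  )
)

setValidity("ScannerGeometry", function(object) {
  msg <- character()
  if (length(object@radiusMm) != 1L || !is.finite(object@radiusMm) ||
      object@radiusMm <= 0)
    msg <- c(msg, "radiusMm must be a single positive number")
  if (length(object@beamOffsetMm) != 1L || !is.finite(object@beamOffsetMm))
    msg <- c(msg, "beamOffsetMm must be a single finite number")
  else if (object@beamOffsetMm < 0)
    msg <- c(msg, "beamOffsetMm must satisfy d >= 0")
  else if (length(object@radiusMm) == 1L &&
           object@beamOffsetMm > object@radiusMm)
    msg <- c(msg, "beamOffsetMm must satisfy d <= radiusMm (beam misses the polygon)")
  if (length(object@nFacets) != 1L || object@nFacets < 3L)
    msg <- c(msg, "nFacets must be an integer >= 3")
  if (object@facetWidthMm <= 0 || object@facetHeightMm <= 0)
    msg <- c(msg, "facet dimensions must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn ScannerGeometry-class Constructor.
#' @param radiusMm,beamOffsetMm,nFacets,facetWidthMm,facetHeightMm see slots.
#' @return a `ScannerGeometry` object.
#' @examples
#' geom <- ScannerGeometry(radiusMm = 7, beamOffsetMm = 5)
#' initialAngle(geom)
#' @export
ScannerGeometry <- function(radiusMm = 7, beamOffsetMm = 5, nFacets = 6L,
                            facetWidthMm = 7, facetHeightMm = 10) {
  new("ScannerGeometry", radiusMm = radiusMm, beamOffsetMm = beamOffsetMm,
      nFacets = as.integer(nFacets), facetWidthMm = facetWidthMm,
      facetHeightMm = facetHeightMm)
}

setMethod("show", "ScannerGeometry", function(object) {
  cat(sprintf(
    "ScannerGeometry: %d facets, R = %g mm, d = %g mm (theta0 = %.3f deg)\n",
    object@nFacets, object@radiusMm, object@beamOffsetMm,
    initialAngle(object)))
  cat(sprintf("  facet aperture %g x %g mm (fast x slow)\n",
              object@facetWidthMm, object@facetHeightMm))
})

#' Acquisition timing and sampling configuration
#'
#' All timing/sampling parameters of the dual-wavelength, dual-channel
#' acquisition, plus the scanner geometry. Validity enforces the design
#' rule that the inter-pulse lag times the speed of sound exceeds the
#' optical depth of focus, so the two wavelengths' echoes cannot overlap
#' within one A-line, and that the inter-channel overlap is smaller than
#' one channel's range.
#'
#' @slot pulseDelayNs lag of the 558-nm pulse behind the 532-nm pulse (ns).
#' @slot soundSpeedMs speed of sound c (m/s).
#' @slot digitizerRateMHz A-line sampling rate (MHz).
#' @slot prfKHz per-wavelength pulse repetition rate (kHz).
#' @slot bscanRateHz fast-axis line rate (Hz).
#' @slot slowStepUm stepper-motor slow-axis step (um).
#' @slot channelRangeMm fast-axis scanning range per channel (mm).
#' @slot overlapMm inter-channel overlap near the range edges (mm).
#' @slot fovFastMm,fovSlowMm target field of view (mm).
#' @slot rpm polygon rotation speed (revolutions per minute).
#' @slot depthOfFocusMm optical depth of focus (mm).
#' @slot lateralResUm,axialResUm system lateral/axial resolution (um).
#' @slot transducerMHz ultrasound transducer center frequency (MHz).
#' @slot depthRangeMm imaged depth range below the detected surface (mm).
#' @slot arcSagMm depth distortion amplitude at the facet-pass edges caused
#'   by the rotary scan arc (mm); the optical prescription behind it is not
#'   modeled, so this is a normalized, configurable sagitta.
#' @slot latticeUm lateral reconstruction lattice pitch (um).
#' @slot geometry a [ScannerGeometry].
#' @export
setClass("ScanConfig",
  representation(
    pulseDelayNs = "numeric",
    soundSpeedMs = "numeric",
    digitizerRateMHz = "numeric",
    prfKHz = "numeric",
    bscanRateHz = "numeric",
    slowStepUm = "numeric",
    channelRangeMm = "numeric",
    overlapMm = "numeric",
    fovFastMm = "numeric",
    fovSlowMm = "numeric",
    rpm = "numeric",
    depthOfFocusMm = "numeric",
    lateralResUm = "numeric",
    axialResUm = "numeric",
    transducerMHz = "numeric",
    depthRangeMm = "numeric",
    arcSagMm = "numeric",
    latticeUm = "numeric",
    geometry = "ScannerGeometry"
  )
)

setValidity("ScanConfig", function(object) {
  msg <- character()
  pos <- c(pulseDelayNs = object@pulseDelayNs,
           soundSpeedMs = object@soundSpeedMs,
           digitizerRateMHz = object@digitizerRateMHz,
           prfKHz = object@prfKHz,
           bscanRateHz = object@bscanRateHz,
           slowStepUm = object@slowStepUm,
           channelRangeMm = object@channelRangeMm,
           fovFastMm = object@fovFastMm,
           fovSlowMm = object@fovSlowMm,
           rpm = object@rpm,
           depthOfFocusMm = object@depthOfFocusMm,
           lateralResUm = object@lateralResUm,
           axialResUm = object@axialResUm,
           transducerMHz = object@transducerMHz,
           depthRangeMm = object@depthRangeMm,
           latticeUm = object@latticeUm)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad))
    msg <- c(msg, paste0("fields must be strictly positive: ",
                         paste(bad, collapse = ", ")))
  if (object@overlapMm < 0)
    msg <- c(msg, "overlapMm must be >= 0")
  if (object@arcSagMm < 0)
    msg <- c(msg, "arcSagMm must be >= 0")
  if (is.finite(object@overlapMm) && is.finite(object@channelRangeMm) &&
      object@overlapMm >= object@channelRangeMm)
    msg <- c(msg, "overlapMm must be smaller than channelRangeMm")
  sep <- pulseSeparationMm(object@pulseDelayNs, object@soundSpeedMs)
  if (is.finite(sep) && sep <= object@depthOfFocusMm)
    msg <- c(msg, sprintf(
      paste0("pulse spatial separation pulseDelayNs * soundSpeedMs = %.4f mm ",
             "must exceed depthOfFocusMm = %.4f mm ",
             "(non-overlap condition for in-A-line demultiplexing)"),
      sep, object@depthOfFocusMm))
  if (length(msg)) msg else TRUE
})

#' @describeIn ScanConfig-class Constructor. Defaults are the in vivo
#'   acquisition settings: 450-ns pulse lag, 1500 m/s, 250-MHz digitizer,
#'   500-kHz PRF, 300-Hz B-scan rate, 5-um slow step, 14-mm channel range
#'   with 4-mm overlap, 24 x 22.5 mm FOV, 3000 rpm (6 facets x 50 Hz ...
#'   here rpm is tied to the B-scan rate: rpm = 60 * bscanRateHz / nFacets).
#' @param ... slot values overriding the defaults.
#' @export
ScanConfig <- function(pulseDelayNs = 450, soundSpeedMs = 1500,
                       digitizerRateMHz = 250, prfKHz = 500,
                       bscanRateHz = 300, slowStepUm = 5,
                       channelRangeMm = 14, overlapMm = 4,
                       fovFastMm = 24, fovSlowMm = 22.5,
                       rpm = NULL, depthOfFocusMm = 0.221,
                       lateralResUm = 7.5, axialResUm = 33,
                       transducerMHz = 30, depthRangeMm = 2,
                       arcSagMm = 0.3, latticeUm = 5,
                       geometry = ScannerGeometry()) {
  if (is.null(rpm)) rpm <- 60 * bscanRateHz / geometry@nFacets
  new("ScanConfig", pulseDelayNs = pulseDelayNs, soundSpeedMs = soundSpeedMs,
      digitizerRateMHz = digitizerRateMHz, prfKHz = prfKHz,
      bscanRateHz = bscanRateHz, slowStepUm = slowStepUm,
      channelRangeMm = channelRangeMm, overlapMm = overlapMm,
      fovFastMm = fovFastMm, fovSlowMm = fovSlowMm, rpm = rpm,
      depthOfFocusMm = depthOfFocusMm, lateralResUm = lateralResUm,
      axialResUm = axialResUm, transducerMHz = transducerMHz,
      depthRangeMm = depthRangeMm, arcSagMm = arcSagMm,
      latticeUm = latticeUm, geometry = geometry)
}

setMethod("show", "ScanConfig", function(object) {
  cat("ScanConfig:\n")
  cat(sprintf("  dual-wavelength lag %g ns (%.3f mm at c = %g m/s)\n",
              object@pulseDelayNs,
              pulseSeparationMm(object@pulseDelayNs, object@soundSpeedMs),
              object@soundSpeedMs))
  cat(sprintf("  digitizer %g MHz, PRF %g kHz, B-scan rate %g Hz, rpm %g\n",
              object@digitizerRateMHz, object@prfKHz, object@bscanRateHz,
              object@rpm))
  cat(sprintf("  channel range %g mm, overlap %g mm, FOV %g x %g mm, slow step %g um\n",
              object@channelRangeMm, object@overlapMm, object@fovFastMm,
              object@fovSlowMm, object@slowStepUm))
  show(object@geometry)
})

#' @rdname accessors
#' @param x object to access.
#' @export
setMethod("scanGeometry", "ScanConfig", function(x) x@geometry)

#' Molar extinction table for HbO2 / HbR
#'
#' Tabulated molar extinction coefficients (L mol^-1 cm^-1) of oxy- and
#' deoxy-hemoglobin by wavelength. The shipped table approximates a
#' standard compilation and is explicitly configuration: override it with
#' your own CSV (`wavelength_nm,eps_hbo2,eps_hbr`) for quantitative work.
#' Entries at 532 and 558 nm must be present and form a nonsingular 2x2
#' system for the spectral unmixing.
#'
#' @slot data data.frame with columns `wavelength_nm`, `eps_hbo2`,
#'   `eps_hbr`.
#' @export
setClass("ExtinctionTable", representation(data = "data.frame"))

setValidity("ExtinctionTable", function(object) {
  d <- object@data
  msg <- character()
  need <- c("wavelength_nm", "eps_hbo2", "eps_hbr")
  if (!all(need %in% names(d)))
    return(paste("columns required:", paste(need, collapse = ", ")))
  if (anyDuplicated(d$wavelength_nm))
    msg <- c(msg, "wavelengths must be unique")
  if (any(d$eps_hbo2 <= 0) || any(d$eps_hbr <= 0))
    msg <- c(msg, "extinction coefficients must be positive")
  if (all(c(532, 558) %in% d$wavelength_nm)) {
    E <- extinctionMatrix2(object)
    if (abs(det(E)) < 1e-6 * prod(sqrt(colSums(E^2))))
      msg <- c(msg, "2x2 extinction matrix at 532/558 nm is (near-)singular")
  } else {
    msg <- c(msg, "entries at 532 and 558 nm are required")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ExtinctionTable", function(object) {
  cat(sprintf("ExtinctionTable: %d wavelengths (%g-%g nm)\n",
              nrow(object@data), min(object@data$wavelength_nm),
              max(object@data$wavelength_nm)))
})

#' Synthetic phantom specification
#'
#' Stated world of the synthetic chromophore phantoms that stand in for
#' the imaged animals: vessel networks with per-vessel oxygen saturation,
#' flat slab targets for depth-correction tests, and point absorbers for
#' impulse-response tests.
#'
#' @slot kind one of `"vessels"`, `"flat_target"`, `"point"`.
#' @slot extentMm physical extent (x fast, y slow, z depth), mm.
#' @slot voxelUm isotropic voxel pitch (um).
#' @slot nVessels number of vessels (vessel phantoms).
#' @slot radiusRangeUm min/max vessel radius (um).
#' @slot so2Arteries,so2Veins default saturation assigned to alternating
#'   vessels (arteries 0.97, veins 0.70 unless overridden).
#' @slot so2Values optional explicit per-vessel sO2 (recycled).
#' @slot tHbMolar total hemoglobin concentration inside vessels (mol/L);
#'   default 2.3e-3 (about 150 g/L whole blood).
#' @slot seed RNG seed making generation a pure function of the spec.
#' @export
setClass("PhantomSpec",
  representation(
    kind = "character",
    extentMm = "numeric",
    voxelUm = "numeric",
    nVessels = "integer",
    radiusRangeUm = "numeric",
    so2Arteries = "numeric",
    so2Veins = "numeric",
    so2Values = "numeric",
    tHbMolar = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("vessels", "flat_target", "point"))
    msg <- c(msg, "kind must be one of 'vessels', 'flat_target', 'point'")
  if (length(object@extentMm) != 3L || any(object@extentMm <= 0))
    msg <- c(msg, "extentMm must be 3 positive numbers (x, y, z)")
  if (object@voxelUm <= 0) msg <- c(msg, "voxelUm must be positive")
  if (object@nVessels < 0L) msg <- c(msg, "nVessels must be >= 0")
  if (length(object@radiusRangeUm) != 2L || any(object@radiusRangeUm <= 0) ||
      diff(object@radiusRangeUm) < 0)
    msg <- c(msg, "radiusRangeUm must be an increasing positive pair")
  so2 <- c(object@so2Arteries, object@so2Veins, object@so2Values)
  if (any(so2 < 0 | so2 > 1))
    msg <- c(msg, "sO2 values must lie in [0, 1]")
  if (object@tHbMolar < 0) msg <- c(msg, "tHbMolar must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn PhantomSpec-class Constructor.
#' @param kind,extentMm,voxelUm,nVessels,radiusRangeUm,so2Arteries,so2Veins,so2Values,tHbMolar,seed
#'   see slots.
#' @export
PhantomSpec <- function(kind = c("vessels", "flat_target", "point"),
                        extentMm = c(1.2, 0.6, 0.8), voxelUm = 5,
                        nVessels = 8L, radiusRangeUm = c(15, 45),
                        so2Arteries = 0.97, so2Veins = 0.70,
                        so2Values = numeric(), tHbMolar = 2.3e-3,
                        seed = 1L) {
  new("PhantomSpec", kind = match.arg(kind), extentMm = extentMm,
      voxelUm = voxelUm, nVessels = as.integer(nVessels),
      radiusRangeUm = radiusRangeUm, so2Arteries = so2Arteries,
      so2Veins = so2Veins, so2Values = as.numeric(so2Values),
      tHbMolar = tHbMolar, seed = as.integer(seed))
}

#' Voxelized chromophore concentration maps
#'
#' 3-D concentration grids for HbO2 and HbR on a common lattice, ordered
#' `[y (slow), x (fast), z (depth)]`, plus the integer vessel-label grid
#' used by round-trip tests (0 = background).
#'
#' @slot cHbO2,cHbR concentration arrays (mol/L), same shape.
#' @slot voxelUm isotropic voxel pitch (um).
#' @slot originMm physical position of voxel (1,1,1) center (x, y, z), mm.
#' @slot labels integer array of vessel ids (same shape; 0 outside).
#' @slot spec the generating [PhantomSpec] (may be a placeholder for
#'   hand-built volumes).
#' @export
setClass("ChromophoreVolume",
  representation(
    cHbO2 = "array",
    cHbR = "array",
    voxelUm = "numeric",
    originMm = "numeric",
    labels = "array",
    spec = "PhantomSpec"
  )
)

setValidity("ChromophoreVolume", function(object) {
  msg <- character()
  if (!identical(dim(object@cHbO2), dim(object@cHbR)))
    msg <- c(msg, "cHbO2 and cHbR must have identical shape")
  if (length(dim(object@cHbO2)) != 3L)
    msg <- c(msg, "concentration grids must be 3-D [y, x, z]")
  if (min(object@cHbO2) < 0 || min(object@cHbR) < 0)
    msg <- c(msg, "concentrations must be >= 0")
  if (object@voxelUm <= 0) msg <- c(msg, "voxelUm must be positive")
  if (length(object@originMm) != 3L)
    msg <- c(msg, "originMm must have length 3 (x, y, z)")
  if (!identical(dim(object@labels), dim(object@cHbO2)))
    msg <- c(msg, "labels must match the concentration grids' shape")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ChromophoreVolume", function(object) {
  d <- dim(object@cHbO2)
  cat(sprintf(
    "ChromophoreVolume: %d x %d x %d voxels [y, x, z] at %g um (%s)\n",
    d[1], d[2], d[3], object@voxelUm, object@spec@kind))
  cat(sprintf("  extent %.3f x %.3f x %.3f mm, %d labeled vessels\n",
              d[2] * object@voxelUm / 1000, d[1] * object@voxelUm / 1000,
              d[3] * object@voxelUm / 1000, max(object@labels)))
})

#' Per-facet trajectory perturbation
#'
#' Injected imperfections of the water-immersed polygon: per-facet
#' fast-axis offsets and gain factors (facet size variation), plus a
#' low-frequency sinusoidal wobble of the fast-axis position within each
#' B-scan (water damping).
#'
#' @slot offsetsUm per-facet fast-axis offset (um), length nFacets.
#' @slot gains per-facet multiplicative range gain, length nFacets, > 0.
#' @slot wobbleAmpUm wobble amplitude (um).
#' @slot wobbleCycles wobble cycles per B-scan.
#' @export
setClass("FacetPerturbation",
  representation(
    offsetsUm = "numeric",
    gains = "numeric",
    wobbleAmpUm = "numeric",
    wobbleCycles = "numeric"
  )
)

setValidity("FacetPerturbation", function(object) {
  msg <- character()
  if (length(object@offsetsUm) != length(object@gains))
    msg <- c(msg, "offsetsUm and gains must have the same length (nFacets)")
  if (any(object@gains <= 0)) msg <- c(msg, "gains must be positive")
  if (object@wobbleAmpUm < 0) msg <- c(msg, "wobbleAmpUm must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn FacetPerturbation-class Constructor; defaults to the
#'   identity perturbation for 6 facets.
#' @param offsetsUm,gains,wobbleAmpUm,wobbleCycles see slots.
#' @param nFacets facet count used when offsets/gains are left at default.
#' @export
FacetPerturbation <- function(offsetsUm = NULL, gains = NULL,
                              wobbleAmpUm = 0, wobbleCycles = 1.5,
                              nFacets = 6L) {
  if (is.null(offsetsUm)) offsetsUm <- rep(0, nFacets)
  if (is.null(gains)) gains <- rep(1, length(offsetsUm))
  new("FacetPerturbation", offsetsUm = offsetsUm, gains = gains,
      wobbleAmpUm = wobbleAmpUm, wobbleCycles = wobbleCycles)
}

#' One simulated time-resolved A-line
#'
#' @slot samples the digitized signal (both wavelengths multiplexed in
#'   time; the 558-nm echo lags by the configured pulse delay).
#' @slot channel acquisition channel (1 or 2).
#' @slot facetIndex originating facet, 0-based, in `[0, nFacets)`.
#' @slot bscanIndex 0-based B-scan (slow-axis) index.
#' @slot fastPositionMm nominal fast-axis focal position (channel-local).
#' @slot triggerS start-of-scan reference time of sample 0 (s).
#' @export
setClass("ALineRecord",
  representation(
    samples = "numeric",
    channel = "integer",
    facetIndex = "integer",
    bscanIndex = "integer",
    fastPositionMm = "numeric",
    triggerS = "numeric"
  )
)

setValidity("ALineRecord", function(object) {
  msg <- character()
  if (!object@channel %in% c(1L, 2L)) msg <- c(msg, "channel must be 1 or 2")
  if (object@facetIndex < 0L) msg <- c(msg, "facetIndex must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Raw dual-channel scan container
#'
#' Per-channel stacks of time-resolved A-lines `[bscan, aline, sample]`
#' with the configuration snapshot, the nominal (unperturbed) trajectory
#' used by reconstruction, and -- for simulated data -- the injected
#' ground truth (perturbation, noise seed, phantom summary) that
#' parameter-recovery tests check against.
#'
#' @slot ch1,ch2 numeric arrays `[nBscan, nAline, nSample]`.
#' @slot config the [ScanConfig] snapshot.
#' @slot omegaDeg matrix `[nAline, 2]`: polygon scan angle per A-line and
#'   channel.
#' @slot fastPosLocalMm matrix `[nAline, 2]`: nominal channel-local focal
#'   position per A-line.
#' @slot channelOffsetMm length-2 global fast-axis offset of each channel.
#' @slot facetOfBscan integer vector, 0-based facet index per B-scan.
#' @slot yPosMm slow-axis position per B-scan (mm).
#' @slot truth list with injected perturbation/noise/phantom ground truth
#'   (empty for non-simulated data).
#' @export
setClass("RawScan",
  representation(
    ch1 = "array",
    ch2 = "array",
    config = "ScanConfig",
    omegaDeg = "matrix",
    fastPosLocalMm = "matrix",
    channelOffsetMm = "numeric",
    facetOfBscan = "integer",
    yPosMm = "numeric",
    truth = "list"
  )
)

setValidity("RawScan", function(object) {
  msg <- character()
  if (!identical(dim(object@ch1), dim(object@ch2)))
    msg <- c(msg, "ch1 and ch2 must share shape [nBscan, nAline, nSample]")
  d <- dim(object@ch1)
  if (length(d) != 3L)
    msg <- c(msg, "channel stacks must be 3-D [bscan, aline, sample]")
  else {
    if (nrow(object@omegaDeg) != d[2] || ncol(object@omegaDeg) != 2L)
      msg <- c(msg, "omegaDeg must be [nAline, 2]")
    if (length(object@facetOfBscan) != d[1])
      msg <- c(msg, "facetOfBscan must have one entry per B-scan")
    if (length(object@yPosMm) != d[1])
      msg <- c(msg, "yPosMm must have one entry per B-scan")
    if (any(object@facetOfBscan < 0L |
            object@facetOfBscan >= object@config@geometry@nFacets))
      msg <- c(msg, "facetOfBscan entries must lie in [0, nFacets)")
  }
  if (length(object@channelOffsetMm) != 2L)
    msg <- c(msg, "channelOffsetMm must have length 2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RawScan", function(object) {
  d <- dim(object@ch1)
  cat(sprintf(
    "RawScan: 2 channels x [%d B-scans x %d A-lines x %d samples]\n",
    d[1], d[2], d[3]))
  cat(sprintf("  channel offsets %g / %g mm, %s ground truth\n",
              object@channelOffsetMm[1], object@channelOffsetMm[2],
              if (length(object@truth)) "with" else "no"))
})

#' @rdname accessors
#' @param channel 1 or 2.
#' @export
setMethod("rawChannel", "RawScan", function(x, channel) {
  stopifnot(channel %in% 1:2)
  if (channel == 1) x@ch1 else x@ch2
})

#' @rdname accessors
#' @export
setMethod("scanTruth", "RawScan", function(x) x@truth)

#' Demultiplexed per-wavelength A-line windows
#'
#' Output of the in-A-line wavelength demultiplexing: two equally shaped
#' stacks of envelope amplitudes `[bscan, aline, windowSample]`, one per
#' excitation wavelength, with the surface-anchored gating metadata.
#'
#' @slot a532,a558 envelope-window stacks, identical shape.
#' @slot tSurf integer matrix `[nBscan, nAline]`: detected surface sample
#'   (0-based) anchoring the 532-nm window.
#' @slot emptyFlag logical matrix: A-lines with no supra-threshold sample.
#' @slot windowSamples gating window length W (samples),
#'   `W = floor(pulseDelayNs * digitizerRate)`.
#' @slot channel source acquisition channel.
#' @slot omegaDeg,fastPosLocalMm,facetOfBscan,yPosMm trajectory provenance
#'   copied from the [RawScan].
#' @slot depthCorrected has [depthCorrect] been applied?
#' @export
setClass("WavelengthPair",
  representation(
    a532 = "array",
    a558 = "array",
    tSurf = "matrix",
    emptyFlag = "matrix",
    windowSamples = "integer",
    channel = "integer",
    omegaDeg = "numeric",
    fastPosLocalMm = "numeric",
    facetOfBscan = "integer",
    yPosMm = "numeric",
    depthCorrected = "logical"
  )
)

setValidity("WavelengthPair", function(object) {
  msg <- character()
  if (!identical(dim(object@a532), dim(object@a558)))
    msg <- c(msg, "a532 and a558 must have identical shapes")
  if (length(dim(object@a532)) != 3L)
    msg <- c(msg, "stacks must be 3-D [bscan, aline, windowSample]")
  else if (dim(object@a532)[3] != object@windowSamples)
    msg <- c(msg, "third dimension must equal windowSamples")
  if (length(msg)) msg else TRUE
})

setMethod("show", "WavelengthPair", function(object) {
  d <- dim(object@a532)
  cat(sprintf(
    "WavelengthPair (channel %d): 2 x [%d x %d x %d] envelope windows%s\n",
    object@channel, d[1], d[2], d[3],
    if (object@depthCorrected) ", depth-corrected" else ""))
  cat(sprintf("  %d empty A-lines flagged\n", sum(object@emptyFlag)))
})

#' Reconstructed per-wavelength image volume
#'
#' Regular-lattice amplitude volumes `[y, x, z]` for both wavelengths,
#' with lateral pitch, depth pitch and provenance (channel, per-column
#' scan angle, per-row facet) required by depth correction and facet
#' registration.
#'
#' @slot a532,a558 amplitude arrays `[ny, nx, nz]`.
#' @slot pitchUm lateral lattice pitch (um).
#' @slot zPitchUm depth pitch (um); natively `c / digitizerRate`.
#' @slot originMm physical origin (x, y, z) of voxel (1,1,1), mm.
#' @slot provenance list: `channel`, `omegaOfCol` (deg, per x column),
#'   `facetOfRow` (0-based, per y row), `depthCorrected`, `droppedAlines`.
#' @export
setClass("ImageVolume",
  representation(
    a532 = "array",
    a558 = "array",
    pitchUm = "numeric",
    zPitchUm = "numeric",
    originMm = "numeric",
    provenance = "list"
  )
)

setValidity("ImageVolume", function(object) {
  msg <- character()
  if (!identical(dim(object@a532), dim(object@a558)))
    msg <- c(msg, "a532 and a558 must have identical shapes")
  if (length(dim(object@a532)) != 3L)
    msg <- c(msg, "volumes must be 3-D [y, x, z]")
  if (object@pitchUm <= 0 || object@zPitchUm <= 0)
    msg <- c(msg, "pitches must be positive")
  if (any(!is.finite(object@a532)) || any(!is.finite(object@a558)))
    msg <- c(msg, "volumes must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@a532)
  cat(sprintf(
    "ImageVolume: 2 wavelengths x [%d x %d x %d] at %g um lateral / %g um depth%s\n",
    d[1], d[2], d[3], object@pitchUm, object@zPitchUm,
    if (isTRUE(object@provenance$depthCorrected)) ", depth-corrected" else ""))
})

#' Per-facet registration transform
#'
#' Rigid 2-D translation (fast, slow) of every facet's compact B-scan
#' stack against the reference facet, estimated by normalized
#' cross-correlation with sub-pixel refinement; slow-axis shifts are in
#' compact-stack rows (one row per B-scan of that facet).
#'
#' @slot shifts matrix `[nFacets, 2]`, columns `fast`, `slow` (pixels).
#' @slot gains optional per-facet amplitude gain (length nFacets).
#' @slot referenceFacet 1-based index of the reference facet (its row is
#'   the identity).
#' @export
setClass("FacetTransform",
  representation(
    shifts = "matrix",
    gains = "numeric",
    referenceFacet = "integer"
  )
)

setValidity("FacetTransform", function(object) {
  msg <- character()
  if (ncol(object@shifts) != 2L)
    msg <- c(msg, "shifts must have 2 columns (fast, slow)")
  if (any(!is.finite(object@shifts)))
    msg <- c(msg, "shifts must be finite")
  if (object@referenceFacet < 1L ||
      object@referenceFacet > nrow(object@shifts))
    msg <- c(msg, "referenceFacet out of range")
  else if (any(object@shifts[object@referenceFacet, ] != 0))
    msg <- c(msg, "reference facet's transform must be the identity")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FacetTransform", function(object) {
  cat(sprintf("FacetTransform: %d facets, reference %d\n",
              nrow(object@shifts), object@referenceFacet))
  print(round(object@shifts, 3))
})

#' Oxygen-saturation map
#'
#' Per-pixel hemoglobin oxygen saturation sO2 = C_HbO2 / (C_HbO2 + C_HbR)
#' in `[0, 1]`, a validity mask (sufficient amplitude at both wavelengths
#' and positive total hemoglobin), and the relative total-hemoglobin
#' proxy.
#'
#' @slot so2 numeric matrix in `[0, 1]` (NA outside the mask).
#' @slot mask logical matrix.
#' @slot thb relative total hemoglobin (arbitrary units).
#' @export
setClass("SO2Map",
  representation(so2 = "matrix", mask = "matrix", thb = "matrix"))

setValidity("SO2Map", function(object) {
  msg <- character()
  if (!identical(dim(object@so2), dim(object@mask)) ||
      !identical(dim(object@so2), dim(object@thb)))
    msg <- c(msg, "so2, mask and thb must share shape")
  v <- object@so2[object@mask]
  if (length(v) && (any(!is.finite(v)) || any(v < 0 | v > 1)))
    msg <- c(msg, "masked sO2 values must be finite and in [0, 1]")
  if (any(!is.na(object@so2[!object@mask])))
    msg <- c(msg, "sO2 must be NA outside the mask")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SO2Map", function(object) {
  cat(sprintf("SO2Map: %d x %d pixels, %.1f%% valid",
              nrow(object@so2), ncol(object@so2),
              100 * mean(object@mask)))
  if (any(object@mask))
    cat(sprintf(", mean sO2 %.3f", mean(object@so2[object@mask])))
  cat("\n")
})

#' Accessors for dcpam objects
#'
#' `so2Values` returns the sO2 matrix, `validMask` the validity mask,
#' `totalHemoglobin` the relative total-hemoglobin image of an [SO2Map];
#' `scanGeometry` the [ScannerGeometry] of a [ScanConfig]; `rawChannel`
#' one channel's stack and `scanTruth` the injected ground truth of a
#' [RawScan].
#'
#' @name accessors
#' @aliases so2Values validMask totalHemoglobin scanGeometry rawChannel
#'   scanTruth
NULL

#' @rdname accessors
#' @export
setMethod("so2Values", "SO2Map", function(x) x@so2)

#' @rdname accessors
#' @export
setMethod("validMask", "SO2Map", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("totalHemoglobin", "SO2Map", function(x) x@thb)
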