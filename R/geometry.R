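## Steering geometry and acquisition-timing arithmetic of the dual-channel
## hexagon scanner.
##
## Lab-frame conventions (verified against a brute-force segment-intersection
## ray trace): the polygon rotates by the scan angle omega; facet k carries
## the outward normal at angle omega + k * (360/n) deg. The two fixed
## incident beams are mirror-symmetric: beam 1 travels along (-1, 0) at
## height y = +d, beam 2 along (+1, 0) at the same height y = +d, so a
## rotation that increases one beam's incidence angle decreases the
## other's. Incidence angles theta1/theta2 are measured from the facet
## normal; with these conventions theta1 + theta2 == 60 deg exactly for
## 60 - theta0 < omega < theta0 and 120 deg for omega >= theta0 (period 60),
## with facet crossings landing exactly on the regime boundaries.

#' Initial polygon angle
#'
#' theta0 = arccos(d / R), the polygon angle at which a vertex crosses an
#' incident beam; it separates the two steering regimes of the hexagon.
#'
#' @param geom a [ScannerGeometry].
#' @return theta0 in degrees, in `[0, 90]`.
#' @examples
#' initialAngle(ScannerGeometry(radiusMm = 7, beamOffsetMm = 3.5)) # 60 deg
#' @export
initialAngle <- function(geom) {
  d <- geom@beamOffsetMm
  R <- geom@radiusMm
  if (d < 0) stop("beamOffsetMm: d must be >= 0, got ", d)
  if (d > R) stop("beamOffsetMm: d must be <= radiusMm (", R, " mm), got ", d)
  rad2deg(acos(d / R))
}

## facet index (0-based, lab frame) each beam is on: the facet whose
## outward side faces the beam and whose vertex span contains the beam
## height y = d. Closed-form span test (no intersection search); a tiny
## rotation epsilon breaks exact vertex-crossing ties toward the facet
## the beam is about to be on, matching the regime boundary convention
## (omega = theta0 belongs to the 120-degree case).
beamFacetIndex <- function(omegaRed, geom, beam) {
  n <- geom@nFacets
  period <- 360 / n
  half <- deg2rad(period / 2)
  R <- geom@radiusMm
  d <- geom@beamOffsetMm
  out <- integer(length(omegaRed))
  for (i in seq_along(omegaRed)) {
    psi <- deg2rad(omegaRed[i] + 1e-9 + (0:(n - 1)) * period)
    lo <- R * sin(psi - half)
    hi <- R * sin(psi + half)
    hit <- if (beam == 1)
      cos(psi) > 0 & lo <= d & d <= hi
    else
      cos(psi) < 0 & hi <= d & d <= lo
    k <- which(hit)
    ## for d > R cos(30 deg) the beam can pass above every facet at some
    ## rotations: a physical no-intersection state, not an error
    out[i] <- if (length(k)) k[1] - 1L else NA_integer_
  }
  out
}

#' Channel steering angles
#'
#' Mirror-reflection ray trace of both fixed incident beams against the
#' rotated hexagon facets: for each scan angle the facet currently under
#' each beam is identified from the vertex-crossing arithmetic, the beam
#' is reflected about that facet's normal, and the incidence angles
#' theta1/theta2 (from the facet normal) are returned together with the
#' reflected-ray directions and the steering regime. In the central
#' regime (`60 - theta0 < omega < theta0`) theta1 + theta2 = 60 deg; for
#' `omega >= theta0` the sum is 120 deg. Scan angles at or below
#' `60 - theta0` after reduction are flagged `"facet-transition"` (a beam
#' straddles two facets at the boundary); they are reported, not an
#' error.
#'
#' The two sum rules characterize the hexagon's *operating band*
#' `theta0` in `[30, 60]` deg, i.e. `R/2 <= d <= R cos(30 deg)`, where
#' each beam works the intended facet pair. Outside the band the ray
#' trace still returns the true incidence angles, but the sums no longer
#' reduce to 60/120 and the regime labels (which follow the stated
#' inequalities) lose their meaning.
#'
#' @param omegaDeg numeric vector of polygon scan angles (degrees); values
#'   are reduced modulo one facet period (`360 / nFacets`).
#' @param geom a [ScannerGeometry].
#' @return data.frame with one row per `omegaDeg`: `omega`, `omegaReduced`,
#'   `theta1`, `theta2`, `theta0`, `facet1`, `facet2` (0-based lab-frame
#'   facet ids), `beta1`, `beta2` (reflected-ray direction angles, deg),
#'   `regime` (`"central"`, `"outer"` or `"facet-transition"`).
#' @examples
#' geom <- ScannerGeometry(radiusMm = 7, beamOffsetMm = 5)
#' ca <- channelAngles(c(20, 30, 50), geom)
#' ca$theta1 + ca$theta2 # 60, 60, 120
#' @export
channelAngles <- function(omegaDeg, geom) {
  stopifnot(length(omegaDeg) >= 1)
  theta0 <- initialAngle(geom)
  period <- 360 / geom@nFacets
  omegaRed <- omegaDeg %% period

  f1 <- beamFacetIndex(omegaRed, geom, 1L)
  f2 <- beamFacetIndex(omegaRed, geom, 2L)

  ## facet normals and reflections, beams u1 = (-1, 0), u2 = (+1, 0)
  psi1 <- deg2rad(omegaRed + f1 * period)
  psi2 <- deg2rad(omegaRed + f2 * period)
  reflect <- function(u, psi) {
    n <- rbind(cos(psi), sin(psi))
    dotun <- u[1] * n[1, ] + u[2] * n[2, ]
    rx <- u[1] - 2 * dotun * n[1, ]
    ry <- u[2] - 2 * dotun * n[2, ]
    list(theta = rad2deg(acos(pmin(abs(dotun), 1))),
         beta = rad2deg(atan2(ry, rx)))
  }
  r1 <- reflect(c(-1, 0), psi1)
  r2 <- reflect(c(1, 0), psi2)

  regime <- ifelse(is.na(f1) | is.na(f2), "no-intersection",
            ifelse(omegaRed > period - theta0 & omegaRed < theta0, "central",
            ifelse(omegaRed >= theta0, "outer", "facet-transition")))

  data.frame(omega = omegaDeg, omegaReduced = omegaRed,
             theta1 = r1$theta, theta2 = r2$theta, theta0 = theta0,
             facet1 = f1, facet2 = f2,
             beta1 = r1$beta, beta2 = r2$beta,
             regime = regime, stringsAsFactors = FALSE)
}

## facet-pass window [start, end) of scan angles during which a channel's
## beam stays on one facet; width is one facet period. Crossing angles
## (period - theta0, theta0) assume the operating band theta0 in [30, 60].
facetPass <- function(geom, channel) {
  theta0 <- initialAngle(geom)
  period <- 360 / geom@nFacets
  start <- if (channel == 1) period - theta0 else theta0
  c(start = start %% period, width = period)
}

#' Fast-axis focal trajectory
#'
#' Maps scan angles to the fast-axis focal-spot coordinate of a channel.
#' The reflected-ray direction from [channelAngles] rotates linearly (at
#' twice the polygon rate) while the beam stays on one facet; because the
#' focusing-optics prescription is not part of the model, the
#' angle-to-position mapping is normalized so that one full facet pass
#' spans exactly `channelRangeMm`, with the pass center mapped to the
#' range midpoint. Positions are channel-local, in `[0, channelRangeMm]`.
#'
#' @param omegaDeg scan angles (degrees); each is interpreted within the
#'   facet pass it falls into.
#' @param geom a [ScannerGeometry].
#' @param config a [ScanConfig] (supplies `channelRangeMm`).
#' @param channel 1 or 2.
#' @return numeric vector of fast-axis positions (mm), strictly monotone
#'   in `omegaDeg` within one facet pass.
#' @export
focusTrajectory <- function(omegaDeg, geom, config, channel = 1L) {
  if (length(omegaDeg) == 0) stop("empty scan-angle grid")
  stopifnot(channel %in% 1:2)
  fp <- facetPass(geom, channel)
  ## phase within the pass; an exact pass-end angle maps to 1 (not 0) so a
  ## closed full-pass grid spans the whole channel range
  u <- (omegaDeg - fp["start"]) / fp["width"]
  phase <- u %% 1
  phase[phase == 0 & u > 0] <- 1
  ## reflected angle is linear in omega with slope -2 for beam 1 and +2
  ## for beam 2 (mirror symmetry); normalize to the channel range with
  ## channel 1 sweeping positive-x and channel 2 negative-x so the two
  ## channels raster the common overlap band in the same sense
  pos <- phase * config@channelRangeMm
  if (channel == 2L) pos <- config@channelRangeMm * (1 - phase)
  unname(pos)
}

#' Rotary-scan depth offset
#'
#' Acoustic path offset delta(omega) between the arc traced by the
#' rotating facet and the flat focal plane, normalized so the offset is 0
#' at the facet-pass center and `arcSagMm` at the pass edges, following
#' the cosine sagitta of the reflected-ray rotation. [depthCorrect]
#' subtracts exactly this model.
#'
#' @param omegaDeg scan angles (deg).
#' @param geom a [ScannerGeometry].
#' @param config a [ScanConfig] (supplies `arcSagMm`).
#' @param channel 1 or 2.
#' @return depth offsets (mm), `>= 0`, 0 at pass center.
#' @export
pathOffsetMm <- function(omegaDeg, geom, config, channel = 1L) {
  fp <- facetPass(geom, channel)
  phase <- ((omegaDeg - fp["start"]) %% fp["width"]) / fp["width"]
  ## reflected ray rotates by 2 * width over the pass; sagitta of the arc
  halfSweep <- deg2rad(fp["width"])          # = 2 * (width/2)
  ang <- (phase - 0.5) * 2 * halfSweep
  unname(config@arcSagMm * (1 - cos(ang)) / (1 - cos(halfSweep)))
}

#' Spatial separation of the two wavelength pulses
#'
#' Distance sound travels during the inter-pulse lag: `delay * c`. With
#' the 450-ns lag and 1500 m/s this is the 0.675 mm that keeps the two
#' wavelengths' echoes disjoint within one A-line.
#'
#' @param delayNs pulse delay (ns), `>= 0`.
#' @param soundSpeedMs speed of sound (m/s), `> 0`.
#' @return separation in mm.
#' @examples
#' pulseSeparationMm(450, 1500) # 0.675
#' @export
pulseSeparationMm <- function(delayNs, soundSpeedMs) {
  if (any(delayNs < 0)) stop("delayNs must be >= 0")
  if (any(soundSpeedMs <= 0)) stop("soundSpeedMs must be > 0")
  delayNs * 1e-9 * soundSpeedMs * 1e3
}

#' Effective stitched scanning range
#'
#' `range1 + range2 - overlap`: two 14-mm channels with the 4-mm edge
#' overlap give the 24-mm total effective range.
#'
#' @param range1Mm,range2Mm per-channel fast-axis ranges (mm).
#' @param overlapMm inter-channel overlap (mm), `0 <= overlap <=
#'   min(range1, range2)`.
#' @return effective range (mm).
#' @examples
#' effectiveRangeMm(14, 14, 4) # 24
#' @export
effectiveRangeMm <- function(range1Mm, range2Mm, overlapMm) {
  if (any(overlapMm < 0)) stop("overlapMm must be >= 0")
  if (any(overlapMm > pmin(range1Mm, range2Mm)))
    stop("overlapMm exceeds a channel range")
  range1Mm + range2Mm - overlapMm
}

#' Acquisition-timing summary
#'
#' The timing identities of the scanner design: total scan time, average
#' fast-axis step, B-scan rate implied by the rotation speed, A-lines per
#' B-scan, and the overlap fraction of one channel's range.
#'
#' @param config a [ScanConfig].
#' @return list with `scan_time_s = (fovSlow / slowStep) / bscanRate`,
#'   `avg_fast_step_um = channelRange * bscanRate / prf`,
#'   `bscan_rate_from_rpm_Hz = (rpm / 60) * nFacets`,
#'   `alines_per_bscan = prf / bscanRate`,
#'   `overlap_fraction_pct = 100 * overlap / channelRange`.
#' @examples
#' timingSummary(ScanConfig())$scan_time_s # 15
#' @export
timingSummary <- function(config) {
  stopifnot(is(config, "ScanConfig"))
  if (config@bscanRateHz <= 0 || config@prfKHz <= 0 || config@rpm <= 0)
    stop("rates must be positive")
  prfHz <- config@prfKHz * 1e3
  list(
    scan_time_s = (config@fovSlowMm * 1e3 / config@slowStepUm) /
      config@bscanRateHz,
    avg_fast_step_um = config@channelRangeMm * 1e3 * config@bscanRateHz /
      prfHz,
    bscan_rate_from_rpm_Hz = (config@rpm / 60) * config@geometry@nFacets,
    alines_per_bscan = prfHz / config@bscanRateHz,
    overlap_fraction_pct = 100 * config@overlapMm / config@channelRangeMm
  )
}
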