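## Synthetic chromophore phantoms. These stand in for the imaged animals:
## the generator states a world (vessel density, radii, hemoglobin
## concentration, arterial/venous saturations) rather than fitting one.

## evaluate expr with a temporary RNG state seeded by `seed`
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

emptyGrids <- function(extentMm, voxelUm) {
  n <- pmax(1L, as.integer(round(extentMm * 1000 / voxelUm)))
  ## dims [y, x, z] from extent (x, y, z)
  dim3 <- c(n[2], n[1], n[3])
  list(dim = dim3, zero = array(0, dim3), labels = array(0L, dim3))
}

#' Generate a random vessel-network phantom
#'
#' Rasterizes `nVessels` random-walk tubes into the HbO2/HbR grids. Each
#' vessel gets one radius from `radiusRangeUm` and one assigned sO2
#' (explicit `so2Values`, else alternating artery/vein defaults); total
#' hemoglobin is uniform (`tHbMolar`) inside vessels and zero outside.
#' Tube profiles are anti-aliased at the wall (linear partial-volume ramp
#' of one voxel) but have hard support: exactly zero outside the radius.
#' Generation is a pure function of the spec, including its seed.
#'
#' @param spec a [PhantomSpec] with `kind = "vessels"`.
#' @return a [ChromophoreVolume]; its `spec` slot carries the per-vessel
#'   assigned sO2 in `so2Values`, and `labels` holds the vessel id of
#'   every occupied voxel.
#' @export
generateVesselPhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  if (spec@kind != "vessels") stop("spec@kind must be 'vessels'")
  if (any(spec@extentMm <= 0)) stop("extentMm must be positive")
  g <- emptyGrids(spec@extentMm, spec@voxelUm)
  ny <- g$dim[1]; nx <- g$dim[2]; nz <- g$dim[3]
  vx <- spec@voxelUm

  nV <- spec@nVessels
  so2 <- if (length(spec@so2Values)) rep_len(spec@so2Values, nV)
         else rep_len(c(spec@so2Arteries, spec@so2Veins), nV)
  W <- g$zero           # winning tube weight per voxel
  L <- g$labels

  ## depth floor: a shallow vessel whose echo arrives within the
  ## transducer ring-down of t = 0 would be clipped by the record start,
  ## so centerlines stay below ~0.15 mm (and above the deep margin)
  zFloorVox <- 0.15 * 1000 / vx
  if (nV > 0) withSeed(spec@seed, {
    for (v in seq_len(nV)) {
      radUm <- stats::runif(1, spec@radiusRangeUm[1], spec@radiusRangeUm[2])
      rVox <- radUm / vx
      zLo <- min(max(0.3 * nz, zFloorVox + rVox), 0.9 * nz)
      zHi <- max(min(0.8 * nz - rVox, nz - rVox), zLo)
      ## centerline random walk, voxel units (x, y, z), 1-based continuous
      step <- max(1, rVox / 2)
      pos <- c(stats::runif(1, 1, nx), stats::runif(1, 1, ny),
               stats::runif(1, zLo, zHi))
      phi <- stats::runif(1, 0, 2 * pi)
      zdrift <- 0
      maxSteps <- ceiling(2 * (nx + ny) / step)
      Wv <- array(0, g$dim)
      for (s in seq_len(maxSteps)) {
        ## stamp a sphere of radius rVox at pos with a 1-voxel AA ramp
        ix <- max(1L, floor(pos[1] - rVox - 1)):min(nx, ceiling(pos[1] + rVox + 1))
        iy <- max(1L, floor(pos[2] - rVox - 1)):min(ny, ceiling(pos[2] + rVox + 1))
        iz <- max(1L, floor(pos[3] - rVox - 1)):min(nz, ceiling(pos[3] + rVox + 1))
        if (length(ix) && length(iy) && length(iz)) {
          dx2 <- (ix - pos[1])^2
          dy2 <- (iy - pos[2])^2
          dz2 <- (iz - pos[3])^2
          dist <- sqrt(outer(outer(dy2, dx2, "+"), dz2, "+"))
          w <- pmin(pmax(rVox - dist + 0.5, 0), 1)
          sub <- Wv[iy, ix, iz, drop = FALSE]
          Wv[iy, ix, iz] <- pmax(sub, w)
        }
        phi <- phi + stats::rnorm(1, 0, 0.12)
        zdrift <- 0.9 * zdrift + stats::rnorm(1, 0, 0.15)
        pos <- pos + c(cos(phi), sin(phi), zdrift) * step
        ## reflect the depth walk at the band edges (clamped: a large
        ## step or a degenerate band must not escape)
        if (pos[3] < zLo) { pos[3] <- 2 * zLo - pos[3]; zdrift <- -zdrift }
        if (pos[3] > zHi) { pos[3] <- 2 * zHi - pos[3]; zdrift <- -zdrift }
        pos[3] <- min(max(pos[3], zLo), zHi)
        if (pos[1] < 1 - rVox || pos[1] > nx + rVox ||
            pos[2] < 1 - rVox || pos[2] > ny + rVox) break
      }
      take <- Wv > W
      W[take] <- Wv[take]
      L[take] <- v
    }
  })

  cT <- spec@tHbMolar * W
  so2Vox <- array(0, g$dim)
  occ <- L > 0L
  so2Vox[occ] <- so2[L[occ]]
  specOut <- spec
  specOut@so2Values <- if (nV > 0) so2 else numeric()
  new("ChromophoreVolume",
      cHbO2 = cT * so2Vox, cHbR = cT * (1 - so2Vox),
      voxelUm = vx, originMm = c(0, 0, 0), labels = L, spec = specOut)
}

#' Uniform absorbing slab at constant depth
#'
#' A flat target used by the depth-correction tests: every lateral
#' position carries the same absorber at physical depth `depthMm`
#' (0-based depth slab index `depthMm * 1000 / voxelUm`).
#'
#' @param depthMm top of the slab (mm below the volume surface).
#' @param thicknessUm slab thickness; at most one voxel thick gives
#'   exactly one occupied z-slab.
#' @param extentMm phantom extent (x, y, z), mm.
#' @param voxelUm voxel pitch (um).
#' @param cTotalMolar total hemoglobin in the slab (mol/L); 0 gives
#'   all-zero grids.
#' @param so2 saturation assigned to the slab.
#' @return a [ChromophoreVolume] (slab labeled 1).
#' @export
flatTargetPhantom <- function(depthMm, thicknessUm = NULL,
                              extentMm = c(1.2, 0.3, 1.0), voxelUm = 5,
                              cTotalMolar = 2.3e-3, so2 = 0.95) {
  g <- emptyGrids(extentMm, voxelUm)
  nz <- g$dim[3]
  if (is.null(thicknessUm)) thicknessUm <- voxelUm
  iz0 <- floor(round(depthMm * 1000 / voxelUm, 9))      # 0-based
  nSlab <- max(1L, as.integer(round(thicknessUm / voxelUm)))
  if (iz0 < 0 || iz0 + nSlab > nz)
    stop(sprintf("slab [%g, %g] mm outside the volume depth extent %g mm",
                 depthMm, depthMm + thicknessUm / 1000, extentMm[3]))
  cT <- g$zero; L <- g$labels
  zIdx <- (iz0 + 1):(iz0 + nSlab)
  cT[, , zIdx] <- cTotalMolar
  if (cTotalMolar > 0) L[, , zIdx] <- 1L
  spec <- PhantomSpec(kind = "flat_target", extentMm = extentMm,
                      voxelUm = voxelUm, nVessels = 0L,
                      so2Values = so2, tHbMolar = cTotalMolar)
  new("ChromophoreVolume", cHbO2 = cT * so2, cHbR = cT * (1 - so2),
      voxelUm = voxelUm, originMm = c(0, 0, 0), labels = L, spec = spec)
}

#' Single point absorber
#'
#' One occupied voxel, used for impulse-response and timing tests.
#'
#' @param positionMm absorber position (x, y, z), mm.
#' @param extentMm phantom extent (x, y, z), mm.
#' @param voxelUm voxel pitch (um).
#' @param cTotalMolar hemoglobin concentration in the voxel.
#' @param so2 assigned saturation.
#' @return a [ChromophoreVolume].
#' @export
pointPhantom <- function(positionMm, extentMm = c(0.4, 0.2, 2.0),
                         voxelUm = 5, cTotalMolar = 2.3e-3, so2 = 0.95) {
  g <- emptyGrids(extentMm, voxelUm)
  idx <- as.integer(floor(round(positionMm * 1000 / voxelUm, 9))) + 1L
  dim3 <- g$dim                                        # [y, x, z]
  at <- c(idx[2], idx[1], idx[3])
  if (any(at < 1L) || any(at > dim3))
    stop("positionMm outside the phantom extent")
  cT <- g$zero; L <- g$labels
  cT[at[1], at[2], at[3]] <- cTotalMolar
  L[at[1], at[2], at[3]] <- 1L
  spec <- PhantomSpec(kind = "point", extentMm = extentMm,
                      voxelUm = voxelUm, nVessels = 0L,
                      so2Values = so2, tHbMolar = cTotalMolar)
  new("ChromophoreVolume", cHbO2 = cT * so2, cHbR = cT * (1 - so2),
      voxelUm = voxelUm, originMm = c(0, 0, 0), labels = L, spec = spec)
}

#' Voxel-wise oxygen saturation of a phantom
#'
#' `sO2 = c_HbO2 / (c_HbO2 + c_HbR)`, NA where no hemoglobin is present.
#'
#' @param phantom a [ChromophoreVolume].
#' @return array of the same shape.
#' @export
phantomSo2 <- function(phantom) {
  tot <- phantom@cHbO2 + phantom@cHbR
  out <- phantom@cHbO2 / tot
  out[tot == 0] <- NA_real_
  out
}
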