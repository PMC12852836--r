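## Ground-truth evaluation helpers: project the phantom's vessel labels
## onto the reconstructed image lattice so per-vessel statistics can be
## measured without contamination from neighboring vessels.

#' Per-vessel projection masks on the image lattice
#'
#' For each vessel id, the en-face pixels whose phantom column contains
#' that vessel only, eroded by `marginUm` around every *other* vessel's
#' projection so the lateral-aperture blur of a neighboring vessel (with
#' a possibly different sO2) cannot leak into the measurement.
#'
#' @param phantom a labeled [ChromophoreVolume].
#' @param config the [ScanConfig] used for the scan (image lattice).
#' @param nRow,nCol dimensions of the target en-face image (stitched:
#'   rows = B-scans, cols at `latticeUm` pitch).
#' @param marginUm erosion margin around other vessels (default 40, i.e.
#'   several lateral-resolution widths).
#' @return named list of logical `nRow x nCol` masks, one per vessel id.
#' @export
vesselProjectionMasks <- function(phantom, config, nRow, nCol,
                                  marginUm = 40) {
  lab <- phantom@labels
  vox <- phantom@voxelUm
  nV <- max(lab)
  if (nV < 1L) stop("phantom has no labeled vessels")
  ## exclusive column projection: vessel id, 0 empty, -1 mixed
  labProj <- apply(lab, c(1, 2), function(v) {
    u <- unique(v[v > 0])
    if (length(u) == 1L) u else if (!length(u)) 0L else -1L
  })
  dilate <- function(m, it) {
    ny <- nrow(m); nx <- ncol(m)
    for (k in seq_len(it)) {
      d <- m
      d[-1, ] <- d[-1, ] | m[-ny, ]; d[-ny, ] <- d[-ny, ] | m[-1, ]
      d[, -1] <- d[, -1] | m[, -nx]; d[, -nx] <- d[, -nx] | m[, -1]
      m <- d
    }
    m
  }
  it <- ceiling(marginUm / vox)
  ## image-pixel -> phantom-voxel index maps
  yMm <- (seq_len(nRow) - 1) * config@slowStepUm / 1000
  xMm <- (seq_len(nCol) - 0.5) * config@latticeUm / 1000
  iy <- pmin(pmax(round(yMm * 1000 / vox + 0.5), 1), nrow(labProj))
  ix <- pmin(pmax(round(xMm * 1000 / vox + 0.5), 1), ncol(labProj))
  out <- vector("list", nV)
  for (v in seq_len(nV)) {
    keepVox <- labProj == v & !dilate(labProj != v & labProj != 0L, it)
    out[[v]] <- matrix(keepVox[iy, ix], nRow, nCol)
  }
  names(out) <- paste0("vessel", seq_len(nV))
  out
}

#' Per-vessel sO2 recovery against the phantom truth
#'
#' Compares an unmixed [SO2Map] with the per-vessel saturations assigned
#' at phantom generation, over the eroded exclusive masks of
#' [vesselProjectionMasks].
#'
#' @param so2map an [SO2Map] on the stitched lattice.
#' @param phantom the generating [ChromophoreVolume].
#' @param config the [ScanConfig] used.
#' @param marginUm erosion margin (um).
#' @return data.frame with `vessel`, `assigned`, `nPixels`, `meanSo2`,
#'   `maxAbsError` (NA for vessels without uncontaminated pixels).
#' @export
vesselRecovery <- function(so2map, phantom, config, marginUm = 40) {
  so2 <- so2Values(so2map)
  masks <- vesselProjectionMasks(phantom, config, nrow(so2), ncol(so2),
                                 marginUm)
  assigned <- phantom@spec@so2Values
  if (!length(assigned)) stop("phantom spec carries no assigned sO2")
  assigned <- rep_len(assigned, length(masks))
  rows <- lapply(seq_along(masks), function(v) {
    sel <- masks[[v]] & validMask(so2map)
    data.frame(vessel = v, assigned = assigned[v], nPixels = sum(sel),
               meanSo2 = if (any(sel)) mean(so2[sel]) else NA_real_,
               maxAbsError = if (any(sel))
                 max(abs(so2[sel] - assigned[v])) else NA_real_)
  })
  do.call(rbind, rows)
}
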