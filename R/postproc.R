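## Post-processing chain: facet registration, frame stabilization,
## classical upsampling (stand-in for a learned upsampler behind the same
## interface), sO2 unmixing and region metrics.

#' Split an en-face image into per-facet stacks
#'
#' Partitions the B-scan rows of an image by originating facet. Each
#' facet scans consistently with itself, so its compact stack (one row
#' per B-scan of that facet) is the unit on which registration operates.
#'
#' @param img en-face matrix `[nBscan, nx]`.
#' @param facetOf 0-based facet index per row (B-scan provenance).
#' @return list with one compact matrix per facet id present, each
#'   carrying its original row indices in `attr(, "rows")`.
#' @export
splitByFacet <- function(img, facetOf) {
  if (is.null(facetOf)) stop("facet provenance is missing")
  if (length(facetOf) != nrow(img))
    stop("facetOf must have one entry per image row")
  ids <- sort(unique(facetOf))
  out <- lapply(ids, function(f) {
    rows <- which(facetOf == f)
    m <- img[rows, , drop = FALSE]
    attr(m, "rows") <- rows
    m
  })
  names(out) <- paste0("facet", ids)
  out
}

#' Recombine per-facet stacks into a full image
#'
#' Inverse of [splitByFacet]: rows return to their original interleaved
#' positions. With identity transforms this reproduces the input image
#' exactly.
#'
#' @param stacks list from [splitByFacet] (row indices in attributes).
#' @param nRow total row count of the target image.
#' @return the interleaved matrix.
#' @export
interleaveFacets <- function(stacks, nRow = NULL) {
  allRows <- unlist(lapply(stacks, attr, "rows"))
  if (is.null(nRow)) nRow <- max(allRows)
  out <- matrix(0, nRow, ncol(stacks[[1]]))
  for (m in stacks) out[attr(m, "rows"), ] <- m
  out
}

#' Estimate per-facet alignment transforms
#'
#' Registers every facet's compact stack against the reference facet's
#' by normalized cross-correlation with sub-pixel (upsampled-DFT)
#' refinement, yielding one rigid 2-D translation per facet; the
#' reference facet maps to the identity. Fast-axis shifts are in lattice
#' pixels, slow-axis shifts in compact-stack rows.
#'
#' @param stacks list of equally sized compact facet stacks (from
#'   [splitByFacet]).
#' @param referenceFacet 1-based index into `stacks`.
#' @param maxShift search bound (pixels).
#' @param estimateGains also estimate per-facet amplitude gains (mean
#'   ratio against the reference)?
#' @return a [FacetTransform].
#' @export
estimateFacetTransforms <- function(stacks, referenceFacet = 1L,
                                    maxShift = 15, estimateGains = FALSE) {
  n <- length(stacks)
  if (n < 2) stop("need at least 2 facets with overlapping structure")
  dims <- vapply(stacks, dim, integer(2))
  nr <- min(dims[1, ]); nc <- min(dims[2, ])
  crop <- function(m) m[seq_len(nr), seq_len(nc), drop = FALSE]
  ref <- crop(stacks[[referenceFacet]])
  if (stats::sd(ref) == 0)
    stop("insufficient structure: reference facet stack is constant")
  ## the facets sample interleaved slow-axis rows, so a facet's content
  ## genuinely sits a fraction of a compact row away from the reference's;
  ## when row provenance is available, resample the reference onto the
  ## target facet's row positions first, so the correlation peak measures
  ## pure misalignment instead of the interleave geometry
  refRows <- attr(stacks[[referenceFacet]], "rows")
  refAt <- function(targetRows) {
    if (is.null(refRows) || is.null(targetRows)) return(ref)
    apply(ref, 2, function(col)
      stats::approx(refRows[seq_len(nr)], col, xout = targetRows[seq_len(nr)],
                    rule = 2)$y)
  }
  shifts <- matrix(0, n, 2, dimnames = list(names(stacks), c("fast", "slow")))
  gains <- rep(1, n)
  for (f in seq_len(n)) {
    if (f == referenceFacet) next
    m <- crop(stacks[[f]])
    if (stats::sd(m) == 0)
      stop(sprintf("insufficient structure: facet stack %d is constant", f))
    r <- registerTranslation(refAt(attr(stacks[[f]], "rows")), m,
                             maxShift = maxShift)
    shifts[f, ] <- c(r$dx, r$dy)
    if (estimateGains && mean(m) > 0) gains[f] <- mean(ref) / mean(m)
  }
  new("FacetTransform", shifts = shifts, gains = gains,
      referenceFacet = as.integer(referenceFacet))
}

#' Apply facet transforms and merge
#'
#' Resamples every facet stack by the inverse of its estimated
#' translation (bilinear interpolation), scales by its gain, and
#' interleaves the aligned rows back into a single image.
#'
#' @param stacks list of compact facet stacks (from [splitByFacet]).
#' @param transforms a [FacetTransform] covering all stacks.
#' @param nRow total row count of the merged image.
#' @return the merged, aligned en-face matrix.
#' @export
applyFacetTransforms <- function(stacks, transforms, nRow = NULL) {
  if (nrow(transforms@shifts) != length(stacks))
    stop("transforms must cover all facets")
  nc <- unique(vapply(stacks, ncol, integer(1)))
  if (length(nc) != 1) stop("facet stacks must share width")
  aligned <- vector("list", length(stacks))
  for (f in seq_along(stacks)) {
    m <- translateImage(stacks[[f]],
                        dy = -transforms@shifts[f, "slow"],
                        dx = -transforms@shifts[f, "fast"]) *
      transforms@gains[f]
    attr(m, "rows") <- attr(stacks[[f]], "rows")
    aligned[[f]] <- m
  }
  interleaveFacets(aligned, nRow = nRow)
}

#' Stabilize a frame sequence
#'
#' Registers every frame to the first by phase-correlation translation
#' (sub-pixel refined) and resamples the frames onto the first frame's
#' grid. Frames whose phase-correlation peak falls below `minPeak` are
#' flagged low-confidence (e.g. pure noise); a single frame is returned
#' unchanged.
#'
#' @param frames list of equally sized matrices.
#' @param maxShift search bound (pixels).
#' @param minPeak normalized-correlation confidence threshold.
#' @return list with `shifts` (matrix `[nFrame, 2]`, columns `dy`, `dx`),
#'   `frames` (aligned), `peak` (per-frame correlation) and
#'   `lowConfidence` (logical).
#' @export
stabilizeFrames <- function(frames, maxShift = NULL, minPeak = 0.3) {
  n <- length(frames)
  if (n < 1) stop("empty frame sequence")
  shifts <- matrix(0, n, 2, dimnames = list(NULL, c("dy", "dx")))
  peak <- rep(1, n)
  out <- frames
  if (n >= 2) for (k in 2:n) {
    r <- registerTranslation(frames[[1]], frames[[k]], maxShift = maxShift,
                             method = "phase")
    shifts[k, ] <- c(r$dy, r$dx)
    peak[k] <- r$peak
    out[[k]] <- translateImage(frames[[k]], dy = -r$dy, dx = -r$dx)
  }
  list(shifts = shifts, frames = out, peak = peak,
       lowConfidence = peak < minPeak)
}

#' Spline upsampling of an en-face image
#'
#' Separable cubic-spline interpolation onto a `factor`-times finer grid,
#' preserving values at the original sample sites (a classical stand-in
#' behind the interface where a learned upsampler could be slotted in).
#' The output grid is `seq(1, n, by = 1/factor)` along each axis, so
#' linear structures are reproduced exactly.
#'
#' @param img numeric matrix.
#' @param factor upsampling factor, `>= 1` (may be fractional).
#' @return the upsampled matrix.
#' @export
upsampleImage <- function(img, factor) {
  if (factor < 1) stop("factor must be >= 1")
  if (factor == 1) return(img)
  upAxis <- function(m) {
    n <- nrow(m)
    xo <- seq(1, n, by = 1 / factor)
    if (n == 1) return(m[rep(1, length(xo)), , drop = FALSE])
    apply(m, 2, function(col)
      stats::splinefun(seq_len(n), col, method = "natural")(xo))
  }
  t(upAxis(t(upAxis(img))))
}

#' Linear spectral unmixing of oxygen saturation
#'
#' Solves, per pixel, `[a532; a558] = ln(10) E [c_HbO2; c_HbR]` with the
#' 2x2 molar-extinction matrix at the two excitation wavelengths, then
#' `sO2 = c_HbO2 / (c_HbO2 + c_HbR)` clipped to `[0, 1]`. The validity
#' mask requires supra-threshold amplitude at both wavelengths (threshold
#' `maskThresholdFactor` background MADs) and positive total hemoglobin.
#'
#' @param a532,a558 equally shaped amplitude images.
#' @param table an [ExtinctionTable] (must contain 532 and 558 nm).
#' @param maskThresholdFactor amplitude threshold in background MADs.
#' @param calib558 calibration scalar applied to `a558` (dual-wavelength
#'   pulse-energy imbalance; 1 = balanced).
#' @return an [SO2Map].
#' @export
unmixSO2 <- function(a532, a558, table, maskThresholdFactor = 3,
                     calib558 = 1) {
  if (!identical(dim(a532), dim(a558)))
    stop("a532 and a558 must have identical shape")
  E <- log(10) * extinctionMatrix2(table)
  if (abs(det(E)) < .Machine$double.eps * 100 * prod(sqrt(colSums(E^2))))
    stop("extinction matrix at 532/558 nm is singular")
  Einv <- solve(E)
  a558c <- a558 * calib558
  cHbO2 <- Einv[1, 1] * a532 + Einv[1, 2] * a558c
  cHbR <- Einv[2, 1] * a532 + Einv[2, 2] * a558c
  thb <- cHbO2 + cHbR
  thr1 <- maskThresholdFactor * stats::mad(a532)
  thr2 <- maskThresholdFactor * stats::mad(a558c)
  mask <- a532 > thr1 & a558c > thr2 & thb > 0 & a532 > 0 & a558c > 0
  so2 <- pmin(pmax(cHbO2 / thb, 0), 1)
  so2[!mask] <- NA_real_
  new("SO2Map", so2 = so2, mask = mask, thb = thb)
}

#' Region summary metric
#'
#' Masked mean over a region, per frame: `mean_amplitude` (perfusion
#' proxy, the mean envelope amplitude) on image frames, `mean_so2` on
#' [SO2Map] frames (valid pixels only).
#'
#' @param x a matrix / [SO2Map], or a list of them (a time series of
#'   frames).
#' @param regionMask logical matrix of the region (within image bounds).
#' @param metric `"mean_amplitude"` or `"mean_so2"`.
#' @return scalar (single frame) or numeric vector (one value per
#'   frame).
#' @export
regionMetric <- function(x, regionMask,
                         metric = c("mean_amplitude", "mean_so2")) {
  metric <- match.arg(metric)
  if (is.list(x))
    return(vapply(x, regionMetric, numeric(1),
                  regionMask = regionMask, metric = metric))
  if (!any(regionMask)) stop("empty region mask")
  if (metric == "mean_amplitude") {
    if (is(x, "SO2Map")) stop("mean_amplitude expects an amplitude image")
    if (!identical(dim(x), dim(regionMask)))
      stop("mask must match image dimensions")
    mean(x[regionMask])
  } else {
    if (!is(x, "SO2Map")) stop("mean_so2 expects an SO2Map")
    if (!identical(dim(so2Values(x)), dim(regionMask)))
      stop("mask must match image dimensions")
    sel <- regionMask & validMask(x)
    if (!any(sel)) stop("no valid sO2 pixels in region")
    mean(so2Values(x)[sel])
  }
}
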