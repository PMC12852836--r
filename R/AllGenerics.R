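#' Depth-axis distortion correction
#'
#' Compensates the arc traced by the rotating polygon facet: the acoustic
#' path offset between the arc and the flat focal plane is removed per
#' A-line, and samples are re-binned onto a common depth lattice.
#'
#' @param x object carrying per-A-line depth profiles with scan-angle
#'   provenance (a [WavelengthPair] or an [ImageVolume]).
#' @param geom a [ScannerGeometry].
#' @param config a [ScanConfig].
#' @param ... further arguments for methods.
#' @return an object of the same class as `x`, depth-corrected and marked
#'   as such (a second application only re-bins and is idempotent to one
#'   sample).
#' @export
setGeneric("depthCorrect", function(x, geom, config, ...)
  standardGeneric("depthCorrect"))

#' Maximum-intensity projection along depth
#'
#' @param x a 3-D array `[slow, fast, depth]` or an [ImageVolume].
#' @param ... further arguments for methods.
#' @return for an array, the 2-D en-face matrix of per-(x, y) maxima over
#'   depth; for an [ImageVolume], a named list with one such matrix per
#'   wavelength (`a532`, `a558`) plus the lateral pixel pitch.
#' @export
setGeneric("projectMip", function(x, ...) standardGeneric("projectMip"))

#' @rdname accessors
#' @export
setGeneric("scanGeometry", function(x) standardGeneric("scanGeometry"))

#' @rdname accessors
#' @export
setGeneric("rawChannel", function(x, channel) standardGeneric("rawChannel"))

#' @rdname accessors
#' @export
setGeneric("scanTruth", function(x) standardGeneric("scanTruth"))

#' @rdname accessors
#' @export
setGeneric("so2Values", function(x) standardGeneric("so2Values"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("totalHemoglobin", function(x) standardGeneric("totalHemoglobin"))
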