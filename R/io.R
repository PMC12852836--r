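## Configuration and file plumbing. Units live in the key names; loading
## is strict (unknown keys are rejected). Raw scans and volumes persist
## as RDS at run time, en-face images as TSV with a JSON sidecar
## carrying pitch/origin metadata.

configKeyMap <- c(
  pulse_delay_ns = "pulseDelayNs",
  sound_speed_m_s = "soundSpeedMs",
  digitizer_rate_MHz = "digitizerRateMHz",
  prf_kHz = "prfKHz",
  bscan_rate_Hz = "bscanRateHz",
  slow_step_um = "slowStepUm",
  channel_range_mm = "channelRangeMm",
  overlap_mm = "overlapMm",
  fov_fast_mm = "fovFastMm",
  fov_slow_mm = "fovSlowMm",
  rpm = "rpm",
  depth_of_focus_mm = "depthOfFocusMm",
  lateral_res_um = "lateralResUm",
  axial_res_um = "axialResUm",
  transducer_center_MHz = "transducerMHz",
  depth_range_mm = "depthRangeMm",
  arc_sag_mm = "arcSagMm",
  lattice_um = "latticeUm"
)

geometryKeyMap <- c(
  radius_mm = "radiusMm",
  beam_offset_mm = "beamOffsetMm",
  n_facets = "nFacets",
  facet_width_mm = "facetWidthMm",
  facet_height_mm = "facetHeightMm"
)

#' Read an acquisition configuration (strict JSON schema)
#'
#' Keys mirror the configuration fields with units suffixed in the names
#' (e.g. `pulse_delay_ns`, `geometry.radius_mm`). Unknown keys are
#' rejected; omitted keys keep the shipped defaults. Validity (pulse
#' separation vs. depth of focus, overlap vs. channel range, positivity)
#' is enforced on construction, so an invalid file fails before any
#' simulation.
#'
#' @param path JSON file.
#' @return a [ScanConfig].
#' @export
readScanConfig <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(j), c(names(configKeyMap), "geometry"))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  geomArgs <- list()
  if (!is.null(j$geometry)) {
    gUnknown <- setdiff(names(j$geometry), names(geometryKeyMap))
    if (length(gUnknown))
      stop("unknown geometry keys: ", paste(gUnknown, collapse = ", "))
    geomArgs <- stats::setNames(j$geometry,
                                geometryKeyMap[names(j$geometry)])
    j$geometry <- NULL
  }
  args <- stats::setNames(j, configKeyMap[names(j)])
  args$geometry <- do.call(ScannerGeometry, lapply(geomArgs, unlist))
  do.call(ScanConfig, lapply(args, function(v)
    if (is.list(v)) v[[1]] else v))
}

#' @describeIn readScanConfig Write a config back to strict-schema JSON.
#' @param config a [ScanConfig].
#' @export
writeScanConfig <- function(config, path) {
  out <- lapply(configKeyMap, function(slot) methods::slot(config, slot))
  out$geometry <- lapply(geometryKeyMap, function(slot)
    methods::slot(config@geometry, slot))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @describeIn readScanConfig The configuration shipped with the package
#'   (the full-scale in vivo settings).
#' @export
defaultScanConfig <- function() {
  readScanConfig(system.file("extdata", "default_config.json",
                             package = "dcpam", mustWork = TRUE))
}

#' Persist / load a raw scan
#'
#' @param raw a [RawScan].
#' @param path `.rds` destination.
#' @return `readRawScan` returns the validated [RawScan].
#' @export
saveRawScan <- function(raw, path) {
  stopifnot(is(raw, "RawScan"))
  saveRDS(raw, path)
  invisible(path)
}

#' @rdname saveRawScan
#' @export
readRawScan <- function(path) {
  if (!file.exists(path)) stop("raw scan not found: ", path)
  raw <- readRDS(path)
  if (!is(raw, "RawScan")) stop("not a RawScan: ", path)
  validObject(raw)
  raw
}

#' Write / read an en-face image as TSV + JSON sidecar
#'
#' Plain-text persistence of en-face images: tab-separated amplitude
#' rows, with pixel pitch and axis metadata in `<path>.json`.
#'
#' @param img numeric matrix `[slow, fast]`.
#' @param path destination `.tsv`.
#' @param pitchUm lateral pixel pitch.
#' @param meta extra metadata fields for the sidecar.
#' @export
writeImageTsv <- function(img, path, pitchUm = NA_real_, meta = list()) {
  utils::write.table(img, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  side <- c(list(rows_slow = nrow(img), cols_fast = ncol(img),
                 pitch_um = pitchUm), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeImageTsv
#' @export
readImageTsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side))
    attr(m, "meta") <- jsonlite::read_json(side, simplifyVector = TRUE)
  m
}
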