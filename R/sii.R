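#' Octave-band constants for the unaided Speech Intelligibility Index
#'
#' Bundles the band importance weights, band speech levels and audibility
#' window used by [siiUnaided()]. The unaided SII approximates the
#' proportion of average-vocal-effort speech information audible to an
#' unaided listener, computed from pure-tone air-conduction thresholds on
#' an octave-band grid.
#'
#' The default importance weights are the standard octave-band importance
#' function (they sum to 1); the default band speech levels are
#' octave-band long-term average speech levels for average vocal effort
#' expressed in dB HL. Each band contributes
#' `importance * clip((band_speech_level + peak_offset - threshold) / dynamic_range, 0, 1)`,
#' i.e. speech in a band is fully audible when the threshold sits
#' `peak_offset` dB below the band level and fades linearly to inaudible
#' over `dynamic_range` dB. All constants are editable, either directly or
#' via a YAML file (see [readSiiConstants()]), because clinical devices
#' implement device-specific variants of the calculation.
#'
#' @param bands Octave centre frequencies in Hz.
#' @param importance Band importance weights; must be non-negative and sum
#'   to 1.
#' @param band_speech_level Long-term average speech level per band, dB HL.
#' @param dynamic_range Width of the audibility window in dB (default 30).
#' @param peak_offset dB by which speech peaks exceed the band level
#'   (default 15).
#' @return An object of class `sii_constants`.
#' @export
#' @examples
#' k <- siiConstants()
#' sum(k$importance)
siiConstants <- function(bands = OCTAVE_FREQS,
                         importance = c(0.0617, 0.1671, 0.2373, 0.2648,
                                        0.2142, 0.0549),
                         band_speech_level = c(45, 50, 45, 38, 33, 28),
                         dynamic_range = 30,
                         peak_offset = 15) {
  if (length(bands) != length(importance) ||
      length(bands) != length(band_speech_level))
    wfs_stop("bands, importance and band_speech_level must have equal length",
             "wfshear_config")
  if (any(importance < 0))
    wfs_stop("SII importance weights must be non-negative", "wfshear_config")
  if (abs(sum(importance) - 1) > 1e-9)
    wfs_stop(sprintf("SII importance weights must sum to 1 (got %.10f)",
                     sum(importance)), "wfshear_config")
  if (dynamic_range <= 0)
    wfs_stop("SII dynamic_range must be positive", "wfshear_config")
  structure(list(bands = as.numeric(bands),
                 importance = as.numeric(importance),
                 band_speech_level = as.numeric(band_speech_level),
                 dynamic_range = as.numeric(dynamic_range),
                 peak_offset = as.numeric(peak_offset)),
            class = "sii_constants")
}

#' Read SII constants from a YAML file
#'
#' The file must define `bands`, `importance`, `band_speech_level` and may
#' override `dynamic_range` and `peak_offset`. The packaged default is at
#' `system.file("extdata", "sii_constants.yaml", package = "wfshear")`.
#'
#' @param path Path to a YAML file.
#' @return An object of class `sii_constants`.
#' @export
readSiiConstants <- function(path) {
  if (!file.exists(path))
    wfs_stop(sprintf("SII constants file not found: %s", path),
             "wfshear_config")
  y <- yaml::read_yaml(path)
  siiConstants(bands = y$bands,
               importance = y$importance,
               band_speech_level = y$band_speech_level,
               dynamic_range = y$dynamic_range %||% 30,
               peak_offset = y$peak_offset %||% 15)
}

#' @export
print.sii_constants <- function(x, ...) {
  cat("SII octave-band constants\n")
  print(data.frame(band_hz = x$bands, importance = x$importance,
                   speech_level_db_hl = x$band_speech_level))
  cat(sprintf("dynamic range %g dB, peak offset +%g dB\n",
              x$dynamic_range, x$peak_offset))
  invisible(x)
}

#' Proportion of speech audible within one octave band
#'
#' Linear audibility ramp: 1 when the threshold is at or below
#' `band_level + peak_offset - dynamic_range`, 0 when at or above
#' `band_level + peak_offset`. A missing threshold (`NA`, i.e. no response
#' at the equipment limit) gives audibility 0.
#'
#' @param threshold Air-conduction threshold(s), dB HL; `NA` for no
#'   response.
#' @param band_level Band speech level(s), dB HL.
#' @param constants An [siiConstants()] object supplying the window.
#' @return Audibility proportion(s) in \[0, 1\].
#' @export
bandAudibility <- function(threshold, band_level, constants = siiConstants()) {
  a <- ((band_level + constants$peak_offset) - threshold) /
    constants$dynamic_range
  a <- pmin(pmax(a, 0), 1)
  a[is.na(threshold)] <- 0
  a
}
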