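#' Construct a single-ear audiogram
#'
#' Holds one ear's air-conduction thresholds for one test session.
#' Thresholds are given as a named numeric vector (names are frequencies in
#' Hz, values in dB HL); `NA` marks a no-response frequency, where the
#' stimulus at the equipment limit was not heard. All six octave
#' frequencies 250-8000 Hz must be present; inter-octave frequencies (750,
#' 1500, 3000, 6000 Hz) are optional. Measured levels must be multiples of
#' 5 dB in \[-10, 120\] because the audiometric step size is 5 dB.
#'
#' @param ear `"left"` or `"right"`.
#' @param thresholds Named numeric vector, names in Hz, values in dB HL or
#'   `NA` for no response.
#' @param conductive Logical; session showed a conductive component
#'   (tympanometry/bone-conduction QC flag).
#' @param invalid Logical; audiogram judged invalid (inconsistent with
#'   prior and subsequent results).
#' @return An object of class `ear_audiogram`.
#' @export
#' @examples
#' earAudiogram("left", c(`250` = 10, `500` = 10, `1000` = 15,
#'                        `2000` = 20, `4000` = 40, `8000` = NA))
earAudiogram <- function(ear = c("left", "right"), thresholds,
                         conductive = FALSE, invalid = FALSE) {
  ear <- match.arg(ear)
  if (is.null(names(thresholds)))
    wfs_stop("thresholds must be a named vector (names = frequency in Hz)")
  freq <- suppressWarnings(as.numeric(names(thresholds)))
  if (anyNA(freq) || any(!freq %in% ALLOWED_FREQS))
    wfs_stop(sprintf("unsupported audiometric frequency: %s",
                     paste(names(thresholds)[is.na(freq) |
                                             !freq %in% ALLOWED_FREQS],
                           collapse = ", ")))
  if (anyDuplicated(freq))
    wfs_stop("duplicated frequency in thresholds")
  missing_oct <- setdiff(OCTAVE_FREQS, freq)
  if (length(missing_oct))
    wfs_stop(sprintf("octave frequency missing from audiogram: %s Hz",
                     paste(missing_oct, collapse = ", ")))
  lev <- as.numeric(thresholds)
  meas <- !is.na(lev)
  if (any(lev[meas] %% 5 != 0))
    wfs_stop("thresholds must be multiples of 5 dB (5-dB audiometric step)")
  if (any(lev[meas] < -10 | lev[meas] > 120))
    wfs_stop("thresholds must lie in [-10, 120] dB HL")
  o <- order(freq)
  structure(list(ear = ear,
                 frequencies = freq[o],
                 levels = lev[o],
                 no_response = !meas[o],
                 conductive = isTRUE(conductive),
                 invalid = isTRUE(invalid)),
            class = "ear_audiogram")
}

#' @export
print.ear_audiogram <- function(x, ...) {
  lv <- ifelse(x$no_response, "NR", x$levels)
  cat(sprintf("<%s ear audiogram>%s%s\n", x$ear,
              if (x$conductive) " [conductive]" else "",
              if (x$invalid) " [invalid]" else ""))
  print(setNames(lv, paste0(x$frequencies, "Hz")), quote = FALSE)
  invisible(x)
}

level_at <- function(ear, freq, substitute_nr = TRUE, required = TRUE) {
  i <- match(freq, ear$frequencies)
  if (is.na(i)) {
    if (required)
      wfs_stop(sprintf("required frequency %g Hz absent from audiogram", freq))
    return(NA_real_)
  }
  if (ear$no_response[i]) {
    if (!substitute_nr) return(NA_real_)
    return(NO_RESPONSE_SUBSTITUTE)
  }
  ear$levels[i]
}

#' Construct one test session (both ears)
#'
#' @param patient_id Patient identifier.
#' @param age_at_session Age in years at the session.
#' @param session_index Visit number, 1-based, in chronological order.
#' @param left,right [earAudiogram()] objects for each side.
#' @return An object of class `audiogram_session`.
#' @export
audiogramSession <- function(patient_id, age_at_session, session_index,
                             left, right) {
  stopifnot(inherits(left, "ear_audiogram"),
            inherits(right, "ear_audiogram"))
  if (left$ear != "left" || right$ear != "right")
    wfs_stop("left/right arguments must carry matching ear labels")
  if (!is.numeric(age_at_session) || age_at_session < 0)
    wfs_stop("age_at_session must be a non-negative number of years")
  structure(list(patient_id = as.character(patient_id),
                 age_at_session = as.numeric(age_at_session),
                 session_index = as.integer(session_index),
                 left = left, right = right),
            class = "audiogram_session")
}

AUDIOGRAM_COLS <- c("patient_id", "age_at_session", "session_index", "ear",
                    "frequency_hz", "threshold_db_hl", "no_response",
                    "conductive", "invalid")

#' Read a long-format audiogram table
#'
#' Expects a UTF-8 CSV with header columns `patient_id`, `age_at_session`,
#' `session_index`, `ear` (left/right), `frequency_hz`, `threshold_db_hl`
#' (empty when no response), `no_response`, `conductive`, `invalid`
#' (0/1 flags). One row per threshold. Validates the 5-dB step, the
#' level/no-response exclusivity, and that ages increase with session
#' index within each patient.
#'
#' @param path CSV file path.
#' @return A validated `data.frame` with the columns above.
#' @export
readAudiograms <- function(path) {
  if (!file.exists(path))
    wfs_stop(sprintf("audiogram file not found: %s", path))
  d <- read.csv(path, stringsAsFactors = FALSE)
  validateAudiogramTable(d)
}

#' Validate an in-memory long-format audiogram table
#'
#' Applies the same checks as [readAudiograms()]; useful when audiograms
#' are generated programmatically.
#'
#' @param d A data.frame in the long audiogram schema.
#' @return The validated data.frame (flags coerced to integer 0/1).
#' @export
validateAudiogramTable <- function(d) {
  miss <- setdiff(AUDIOGRAM_COLS, names(d))
  if (length(miss))
    wfs_stop(sprintf("audiogram table lacks column(s): %s",
                     paste(miss, collapse = ", ")))
  d$ear <- tolower(d$ear)
  if (any(!d$ear %in% c("left", "right")))
    wfs_stop("ear must be 'left' or 'right'")
  if (any(!d$frequency_hz %in% ALLOWED_FREQS))
    wfs_stop("frequency_hz outside the supported audiometric frequencies")
  for (fl in c("no_response", "conductive", "invalid"))
    d[[fl]] <- as.integer(d[[fl]] != 0)
  d$threshold_db_hl <- suppressWarnings(as.numeric(d$threshold_db_hl))
  bad <- is.na(d$threshold_db_hl) & d$no_response == 0
  if (any(bad))
    wfs_stop(sprintf("%d row(s) have neither a threshold nor a no_response flag",
                     sum(bad)))
  bad <- !is.na(d$threshold_db_hl) & d$no_response == 1
  if (any(bad))
    wfs_stop("threshold present on a no_response row; the two are exclusive")
  meas <- !is.na(d$threshold_db_hl)
  # continuous (un-quantized) tables are produced by the generator for
  # quantization-bias studies and bypass the 5-dB step rule
  if (!isTRUE(attr(d, "continuous")) &&
      any(d$threshold_db_hl[meas] %% 5 != 0))
    wfs_stop("thresholds must be multiples of 5 dB")
  if (any(d$threshold_db_hl[meas] < -10 | d$threshold_db_hl[meas] > 120))
    wfs_stop("thresholds must lie in [-10, 120] dB HL")
  # ages strictly increasing along session_index within patient
  ses <- unique(d[, c("patient_id", "session_index", "age_at_session")])
  ses <- ses[order(ses$patient_id, ses$session_index), ]
  for (p in unique(ses$patient_id)) {
    a <- ses$age_at_session[ses$patient_id == p]
    if (length(a) > 1 && any(diff(a) <= 0))
      wfs_stop(sprintf("ages not strictly increasing across sessions for %s", p))
  }
  d
}

copyContinuousAttr <- function(to, from) {
  if (isTRUE(attr(from, "continuous"))) attr(to, "continuous") <- TRUE
  to
}

# Build an ear_audiogram from the rows of one (patient, session, ear) group.
rowsToEar <- function(rows) {
  th <- ifelse(rows$no_response == 1, NA_real_, rows$threshold_db_hl)
  earAudiogram(rows$ear[1],
               setNames(th, rows$frequency_hz),
               conductive = any(rows$conductive == 1),
               invalid = any(rows$invalid == 1))
}

#' Convert a long audiogram table to session objects
#'
#' @param d Validated long-format audiogram table.
#' @return A list of [audiogramSession()] objects; sessions with a missing
#'   ear are dropped with a warning.
#' @export
asSessions <- function(d) {
  d <- validateAudiogramTable(d)
  keys <- unique(d[, c("patient_id", "session_index")])
  keys <- keys[order(keys$patient_id, keys$session_index), ]
  out <- vector("list", nrow(keys))
  kept <- logical(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    rows <- d[d$patient_id == keys$patient_id[i] &
                d$session_index == keys$session_index[i], ]
    if (!all(c("left", "right") %in% rows$ear)) next
    out[[i]] <- audiogramSession(keys$patient_id[i],
                                 rows$age_at_session[1],
                                 keys$session_index[i],
                                 rowsToEar(rows[rows$ear == "left", ]),
                                 rowsToEar(rows[rows$ear == "right", ]))
    kept[i] <- TRUE
  }
  if (any(!kept))
    warning(sprintf("%d session(s) lacked one ear and were dropped",
                    sum(!kept)))
  out[kept]
}
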