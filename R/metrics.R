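#' Pure tone average (PTA)
#'
#' Arithmetic mean of the air-conduction thresholds at 500, 1000 and
#' 2000 Hz, in dB HL. A no-response at any of the three frequencies is
#' substituted with 95 dB HL (the same substitution used at 8 kHz for the
#' high frequency average); substituted frequencies are recorded in the
#' `"substituted"` attribute so downstream reports can flag them.
#'
#' @param ear An [earAudiogram()].
#' @return PTA in dB HL (unrounded); attribute `substituted` lists
#'   frequencies where 95 dB HL replaced a no-response.
#' @export
#' @examples
#' e <- earAudiogram("left", c(`250` = 10, `500` = 20, `1000` = 25,
#'                             `2000` = 30, `4000` = 40, `8000` = 50))
#' pta(e)  # 25
pta <- function(ear) {
  stopifnot(inherits(ear, "ear_audiogram"))
  fr <- c(500, 1000, 2000)
  lv <- vapply(fr, function(f) level_at(ear, f), numeric(1))
  sub <- fr[vapply(fr, function(f) {
    i <- match(f, ear$frequencies); ear$no_response[i]
  }, logical(1))]
  structure(mean(lv), substituted = sub)
}

#' High frequency average (HFA)
#'
#' Mean of the 4000 and 8000 Hz thresholds in dB HL. When no response is
#' obtained at the equipment limit, 95 dB HL is used in the calculation
#' (this is the standard rule at 8 kHz and is applied at 4 kHz as well,
#' with the substitution recorded in the `"substituted"` attribute).
#' Negative averages are possible for ears with better-than-reference
#' thresholds.
#'
#' @inheritParams pta
#' @return HFA in dB HL (unrounded).
#' @export
#' @examples
#' e <- earAudiogram("left", c(`250` = 10, `500` = 10, `1000` = 10,
#'                             `2000` = 15, `4000` = 70, `8000` = NA))
#' hfa(e)  # (70 + 95) / 2 = 82.5
hfa <- function(ear) {
  stopifnot(inherits(ear, "ear_audiogram"))
  fr <- c(4000, 8000)
  lv <- vapply(fr, function(f) level_at(ear, f), numeric(1))
  sub <- fr[vapply(fr, function(f) {
    i <- match(f, ear$frequencies); ear$no_response[i]
  }, logical(1))]
  structure(mean(lv), substituted = sub)
}

#' Classify hearing status of one ear
#'
#' Hearing is abnormal when the PTA (500/1000/2000 Hz) exceeds 20 dB HL,
#' or when more than two measured frequencies have thresholds above
#' 20 dB HL (a no-response counts as above 20). The count runs over every
#' frequency actually measured, octaves and any recorded inter-octaves
#' alike. Loss is profound when the PTA is at least 80 dB HL. An ear
#' flagged invalid is refused.
#'
#' @inheritParams pta
#' @return A list with elements `category` (`"normal"` or
#'   `"hearing_loss"`), `profound` (logical) and `pta` (dB HL).
#' @export
classifyHearing <- function(ear) {
  stopifnot(inherits(ear, "ear_audiogram"))
  if (ear$invalid)
    wfs_stop("audiogram flagged invalid; classification refused",
             "wfshear_invalid_audiogram")
  p <- as.numeric(pta(ear))
  above20 <- ear$no_response | (!is.na(ear$levels) & ear$levels > 20)
  loss <- p > 20 || sum(above20) >= 3
  list(category = if (loss) "hearing_loss" else "normal",
       profound = p >= 80,
       pta = p)
}

#' Unaided Speech Intelligibility Index from pure-tone thresholds
#'
#' Importance-weighted sum of octave-band audibilities (see
#' [bandAudibility()]): 0 means no speech information is audible, 1 means
#' all of it is. No-response bands contribute zero audibility. The result
#' is a proportion; clinical reports usually print it as an integer
#' percentage.
#'
#' @inheritParams pta
#' @param constants An [siiConstants()] object.
#' @return SII as a proportion in \[0, 1\].
#' @export
siiUnaided <- function(ear, constants = siiConstants()) {
  stopifnot(inherits(ear, "ear_audiogram"),
            inherits(constants, "sii_constants"))
  th <- vapply(constants$bands,
               function(f) level_at(ear, f, substitute_nr = FALSE),
               numeric(1))
  sum(constants$importance * bandAudibility(th, constants$band_speech_level,
                                            constants))
}

#' All per-ear metrics for one audiogram
#'
#' @inheritParams siiUnaided
#' @return A list of class `ear_metrics`: `pta`, `hfa` (dB HL), `sii`
#'   (proportion), `category`, `profound`, and `amplification_candidate`
#'   (`TRUE` when the unaided SII falls below 0.75, the level below which
#'   speech transmission is considered significantly compromised).
#' @export
earMetrics <- function(ear, constants = siiConstants()) {
  cl <- classifyHearing(ear)
  s <- siiUnaided(ear, constants)
  structure(list(pta = as.numeric(pta(ear)), hfa = as.numeric(hfa(ear)),
                 sii = s, category = cl$category, profound = cl$profound,
                 amplification_candidate = s < 0.75),
            class = "ear_metrics")
}

#' @export
print.ear_metrics <- function(x, ...) {
  cat(sprintf("PTA %s dB HL, HFA %s dB HL, SII %s (%s%s)\n",
              fmtDb(x$pta), fmtDb(x$hfa), fmtSiiPct(x$sii),
              x$category, if (x$profound) ", profound" else ""))
  invisible(x)
}

#' Rank the two ears of a session as worse / better
#'
#' The worse ear is the one with the lower unaided SII. Ties are broken by
#' the higher HFA, then the higher PTA; a completely tied pair designates
#' the left ear as worse (a fixed, documented convention so the ranking is
#' deterministic). Sessions with an invalid ear are refused.
#'
#' @param session An [audiogramSession()].
#' @param constants An [siiConstants()] object.
#' @return A list with `worse`, `better` (the [earAudiogram()] objects),
#'   `worse_side` (`"left"`/`"right"`), and `tie_broken_by`
#'   (`"sii"`, `"hfa"`, `"pta"`, or `"convention"`).
#' @export
rankEars <- function(session, constants = siiConstants()) {
  stopifnot(inherits(session, "audiogram_session"))
  if (session$left$invalid || session$right$invalid)
    wfs_stop(sprintf("session %d of %s has an invalid ear; excluded from ranking",
                     session$session_index, session$patient_id),
             "wfshear_invalid_audiogram")
  sL <- siiUnaided(session$left, constants)
  sR <- siiUnaided(session$right, constants)
  if (sL != sR) {
    side <- if (sL < sR) "left" else "right"
    by <- "sii"
  } else {
    hL <- as.numeric(hfa(session$left)); hR <- as.numeric(hfa(session$right))
    if (hL != hR) {
      side <- if (hL > hR) "left" else "right"
      by <- "hfa"
    } else {
      pL <- as.numeric(pta(session$left)); pR <- as.numeric(pta(session$right))
      if (pL != pR) {
        side <- if (pL > pR) "left" else "right"
        by <- "pta"
      } else {
        side <- "left"
        by <- "convention"
      }
    }
  }
  list(worse = session[[side]],
       better = session[[setdiff(c("left", "right"), side)]],
       worse_side = side, tie_broken_by = by)
}

#' Per-ear metrics for every session in a long audiogram table
#'
#' Vectorised companion to [earMetrics()]: computes PTA, HFA, unaided SII,
#' category and the profound flag for every (patient, session, ear) in a
#' validated long-format table. No-response thresholds are substituted
#' with 95 dB HL for PTA/HFA and contribute zero audibility to the SII.
#'
#' @param d Long-format audiogram table (see [readAudiograms()]).
#' @param constants An [siiConstants()] object.
#' @return A data.frame with one row per patient-session-ear: identifiers,
#'   age, flags, `pta`, `hfa`, `sii`, `category`, `profound`.
#' @export
sessionMetrics <- function(d, constants = siiConstants()) {
  d <- validateAudiogramTable(d)
  key <- interaction(d$patient_id, d$session_index, d$ear, drop = TRUE,
                     lex.order = TRUE)
  ids <- !duplicated(key)
  out <- data.frame(patient_id = d$patient_id[ids],
                    session_index = d$session_index[ids],
                    ear = d$ear[ids],
                    age_at_session = d$age_at_session[ids],
                    conductive = as.integer(tapply(d$conductive, key, max)[as.character(key[ids])] > 0),
                    invalid = as.integer(tapply(d$invalid, key, max)[as.character(key[ids])] > 0),
                    stringsAsFactors = FALSE)
  kk <- as.character(key[ids])
  # frequency x group matrix of levels with NR substitution
  sub <- ifelse(d$no_response == 1, NO_RESPONSE_SUBSTITUTE, d$threshold_db_hl)
  getlev <- function(f, substitute = TRUE) {
    i <- d$frequency_hz == f
    v <- if (substitute) sub[i] else ifelse(d$no_response[i] == 1, NA_real_,
                                            d$threshold_db_hl[i])
    setNames(v, as.character(key)[i])[kk]
  }
  oct <- lapply(OCTAVE_FREQS, getlev)
  names(oct) <- OCTAVE_FREQS
  missing_oct <- vapply(oct, anyNA, logical(1))
  if (any(missing_oct))
    wfs_stop(sprintf("octave frequency missing from audiogram: %s Hz",
                     paste(OCTAVE_FREQS[missing_oct], collapse = ", ")))
  out$pta <- (oct[["500"]] + oct[["1000"]] + oct[["2000"]]) / 3
  out$hfa <- (oct[["4000"]] + oct[["8000"]]) / 2
  # SII over the constants' bands (NA -> audibility 0)
  sii <- 0
  for (b in seq_along(constants$bands)) {
    th <- getlev(constants$bands[b], substitute = FALSE)
    sii <- sii + constants$importance[b] *
      bandAudibility(th, constants$band_speech_level[b], constants)
  }
  out$sii <- as.numeric(sii)
  # frequency count criterion over all measured frequencies
  above <- tapply(d$no_response == 1 |
                    (!is.na(d$threshold_db_hl) & d$threshold_db_hl > 20),
                  key, sum)[kk]
  out$category <- ifelse(out$pta > 20 | above >= 3, "hearing_loss", "normal")
  out$profound <- out$pta >= 80
  rownames(out) <- NULL
  out
}

# -- report formatting helpers (centralised so tables and JSON agree) ----

#' Format a dB value for reports (1 decimal)
#' @param x Numeric dB value(s).
#' @return Character vector.
#' @export
fmtDb <- function(x) formatC(round(x, 1), format = "f", digits = 1)

#' Format an SII proportion as an integer percentage
#' @param x SII proportion(s) in \[0, 1\].
#' @return Character vector like `"78%"`.
#' @export
fmtSiiPct <- function(x) paste0(round(100 * x), "%")
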