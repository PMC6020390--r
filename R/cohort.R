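COHORT_COLS <- c("patient_id", "sex", "enrollment_age", "sibship",
                 "dm_onset", "di_onset", "hl_onset", "oa_onset",
                 "cochlear_implant", "n_sessions")
SYMPTOMS <- c("DM", "DI", "HL", "OA")
STATUS_TOKENS <- c("normal", "not diagnosed", "no dx")

parse_status <- function(x, column, id) {
  x <- trimws(x)
  v <- suppressWarnings(as.numeric(x))
  status <- character(length(x))
  onset <- rep(NA_real_, length(x))
  for (i in seq_along(x)) {
    if (!is.na(v[i])) {
      if (v[i] < 0)
        wfs_stop(sprintf("negative onset age in %s for %s", column, id[i]))
      status[i] <- "diagnosed"
      onset[i] <- v[i]
    } else {
      tok <- tolower(gsub("[_ ]+", " ", x[i]))
      if (!tok %in% STATUS_TOKENS)
        wfs_stop(sprintf("unknown status token '%s' in %s for %s",
                         x[i], column, id[i]))
      status[i] <- c("normal", "not_diagnosed", "no_dx")[match(tok, STATUS_TOKENS)]
    }
  }
  list(status = status, onset = onset)
}

#' Load a cohort symptom table
#'
#' Reads a CSV with one row per patient and columns `patient_id`, `sex`
#' (M/F), `enrollment_age`, `sibship`, `dm_onset`, `di_onset`, `hl_onset`,
#' `oa_onset`, `cochlear_implant` (0/1) and `n_sessions`. Each onset cell
#' is either an age in years or one of the tokens `Normal` (hearing
#' confirmed normal by testing; hearing-loss column only), `Not Diagnosed`
#' or `No dx` (case-insensitive). The packaged example cohort (n = 40) is
#' at `system.file("extdata", "wfs_cohort.csv", package = "wfshear")`.
#'
#' @param path CSV file path, or a data.frame already in the schema.
#' @return A data.frame of class `wfs_cohort` with numeric onset columns
#'   (`NA` when not diagnosed) plus `*_status` columns.
#' @export
#' @examples
#' co <- loadCohort(system.file("extdata", "wfs_cohort.csv",
#'                              package = "wfshear"))
#' nrow(co)        # 40
#' table(co$sex)   # 18 M, 22 F
loadCohort <- function(path) {
  d <- if (is.data.frame(path)) path else {
    if (!file.exists(path))
      wfs_stop(sprintf("cohort file not found: %s", path))
    read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  }
  miss <- setdiff(COHORT_COLS, names(d))
  if (length(miss))
    wfs_stop(sprintf("cohort table lacks column(s): %s",
                     paste(miss, collapse = ", ")))
  if (anyDuplicated(d$patient_id))
    wfs_stop(sprintf("duplicate patient_id: %s",
                     paste(unique(d$patient_id[duplicated(d$patient_id)]),
                           collapse = ", ")))
  out <- data.frame(patient_id = as.character(d$patient_id),
                    sex = toupper(trimws(as.character(d$sex))),
                    enrollment_age = as.numeric(d$enrollment_age),
                    sibship = as.character(d$sibship),
                    stringsAsFactors = FALSE)
  if (any(!out$sex %in% c("M", "F")))
    wfs_stop("sex must be M or F")
  if (anyNA(out$enrollment_age))
    wfs_stop("enrollment_age must be numeric")
  for (s in c("dm", "di", "hl", "oa")) {
    p <- parse_status(as.character(d[[paste0(s, "_onset")]]),
                      paste0(s, "_onset"), out$patient_id)
    if (s != "hl" && any(p$status == "normal"))
      wfs_stop(sprintf("'Normal' is only meaningful in hl_onset (found in %s_onset)", s))
    out[[paste0(s, "_onset")]] <- p$onset
    out[[paste0(s, "_status")]] <- p$status
  }
  out$cochlear_implant <- as.integer(d$cochlear_implant) != 0
  out$n_sessions <- as.integer(d$n_sessions)
  if (any(out$cochlear_implant & out$n_sessions > 0))
    wfs_stop("cochlear-implant patients cannot have analyzable sessions")
  class(out) <- c("wfs_cohort", "data.frame")
  out
}

onset_col <- function(symptom) {
  symptom <- toupper(symptom)
  if (!symptom %in% SYMPTOMS)
    wfs_stop(sprintf("unknown symptom '%s' (use DM, DI, HL or OA)", symptom))
  paste0(tolower(symptom), "_onset")
}

#' Onset-age summary for one symptom
#'
#' Mean and sample standard deviation (n - 1 denominator) of the onset
#' ages among diagnosed patients only; `Normal`, `Not Diagnosed` and
#' `No dx` rows are excluded. Values are unrounded; reports round to one
#' decimal.
#'
#' @param cohort A [loadCohort()] result.
#' @param symptom One of `"DM"`, `"DI"`, `"HL"`, `"OA"`.
#' @return A list with `n`, `mean`, `sd` (`sd` is `NA` when n < 2; `mean`
#'   is `NA` when n = 0).
#' @export
symptomSummary <- function(cohort, symptom) {
  v <- cohort[[onset_col(symptom)]]
  v <- v[!is.na(v)]
  list(n = length(v),
       mean = if (length(v)) mean(v) else NA_real_,
       sd = if (length(v) > 1) sd(v) else NA_real_)
}

#' Prevalence of a symptom in the cohort
#'
#' Proportion of patients diagnosed with the symptom. Cochlear-implant
#' patients count as diagnosed with hearing loss (their onset ages are
#' known even though their ears cannot be tested).
#'
#' @inheritParams symptomSummary
#' @return Proportion in \[0, 1\].
#' @export
prevalence <- function(cohort, symptom) {
  if (!nrow(cohort)) wfs_stop("empty cohort")
  sum(!is.na(cohort[[onset_col(symptom)]])) / nrow(cohort)
}

#' Count patients with symptom onset at or below an age
#'
#' @inheritParams symptomSummary
#' @param age Age cutoff in years (inclusive).
#' @return Integer count.
#' @export
onsetByAge <- function(cohort, symptom = "HL", age = 3) {
  v <- cohort[[onset_col(symptom)]]
  sum(!is.na(v) & v <= age)
}

#' First- and second-symptom counts
#'
#' A symptom is a patient's first when its onset age is strictly less than
#' every other diagnosed onset age; exact ties produce co-first symptoms,
#' each counted and flagged. Second symptoms are counted with the same
#' strict-ordering policy among the remaining diagnoses. Patients with no
#' diagnosed symptom contribute nothing.
#'
#' @inheritParams symptomSummary
#' @return A list with `first` and `second` (named integer vectors over
#'   DM/DI/HL/OA) and `n_tied_first` (patients whose earliest onset is
#'   shared by more than one symptom).
#' @export
firstSymptomCounts <- function(cohort) {
  first <- second <- setNames(integer(length(SYMPTOMS)), SYMPTOMS)
  n_tied <- 0L
  for (i in seq_len(nrow(cohort))) {
    on <- vapply(SYMPTOMS, function(s) cohort[[onset_col(s)]][i], numeric(1))
    on <- on[!is.na(on)]
    if (!length(on)) next
    m1 <- min(on)
    f <- names(on)[on == m1]
    first[f] <- first[f] + 1L
    if (length(f) > 1) n_tied <- n_tied + 1L
    rest <- on[on > m1]
    if (length(rest)) {
      m2 <- min(rest)
      s2 <- names(rest)[rest == m2]
      second[s2] <- second[s2] + 1L
    }
  }
  list(first = first, second = second, n_tied_first = n_tied)
}

#' Sex by hearing-loss association
#'
#' Pearson chi-square (no continuity correction, df = 1) on the 2x2 table
#' of sex against diagnosed sensorineural hearing loss, with the two-sided
#' p-value from the chi-square distribution.
#'
#' @inheritParams symptomSummary
#' @return A list with `chi_square`, `p`, `df` and the 2x2 `table`; the
#'   statistic is `NA` with a message when a margin is zero.
#' @export
sexAssociation <- function(cohort) {
  snhl <- factor(!is.na(cohort$hl_onset), levels = c(FALSE, TRUE),
                 labels = c("no_snhl", "snhl"))
  sex <- factor(cohort$sex, levels = c("M", "F"))
  tab <- table(sex, snhl)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(chi_square = NA_real_, p = NA_real_, df = 1L, table = tab,
                note = "zero margin; statistic undefined"))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi_square = unname(ct$statistic), p = unname(ct$p.value),
       df = unname(ct$parameter), table = tab)
}

#' Cohort summary (symptom-table analogue)
#'
#' One-stop descriptive summary: enrollment age, sex counts, per-symptom
#' onset summaries and prevalence, first-symptom counts, early-onset
#' hearing-loss count, hearing-status counts and the sex association.
#'
#' @inheritParams symptomSummary
#' @return A list of class `cohort_summary`.
#' @export
cohortSummary <- function(cohort) {
  per <- lapply(setNames(SYMPTOMS, SYMPTOMS), function(s)
    c(symptomSummary(cohort, s), prevalence = prevalence(cohort, s)))
  fs <- firstSymptomCounts(cohort)
  structure(list(
    n = nrow(cohort),
    sex_counts = table(factor(cohort$sex, levels = c("M", "F"))),
    enrollment_age = list(mean = mean(cohort$enrollment_age),
                          sd = sd(cohort$enrollment_age)),
    symptoms = per,
    first_symptom = fs$first,
    second_symptom = fs$second,
    n_tied_first = fs$n_tied_first,
    hl_by_age3 = onsetByAge(cohort, "HL", 3),
    hearing_status = c(normal = sum(is.na(cohort$hl_onset)),
                       hearing_loss = sum(!is.na(cohort$hl_onset))),
    n_cochlear_implant = sum(cohort$cochlear_implant),
    sex_association = sexAssociation(cohort)),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients (%d M / %d F), enrollment age %s (SD %s)\n",
              x$n, x$sex_counts[["M"]], x$sex_counts[["F"]],
              fmtDb(x$enrollment_age$mean), fmtDb(x$enrollment_age$sd)))
  for (s in SYMPTOMS) {
    p <- x$symptoms[[s]]
    cat(sprintf("  %s: n = %d, onset %s (SD %s), prevalence %.0f%%\n", s,
                p$n, fmtDb(p$mean), fmtDb(p$sd), 100 * p$prevalence))
  }
  cat(sprintf("  first symptom: %s\n",
              paste(sprintf("%s %d", names(x$first_symptom), x$first_symptom),
                    collapse = ", ")))
  cat(sprintf("  hearing loss by age 3: %d; cochlear implants: %d\n",
              x$hl_by_age3, x$n_cochlear_implant))
  sa <- x$sex_association
  cat(sprintf("  sex x SNHL chi-square %.2f (df %d), p = %.2f\n",
              sa$chi_square, sa$df, sa$p))
  invisible(x)
}

#' Apply the modelling exclusion rules to an audiogram table
#'
#' Drops, with a logged reason per row group: ears flagged conductive,
#' ears flagged invalid, all sessions of cochlear-implant patients, and
#' sessions beyond the fifth visit (very few patients contribute a sixth
#' time point, so modelling uses up to five).
#'
#' @param d Long-format audiogram table.
#' @param cohort Optional [loadCohort()] result used to identify
#'   cochlear-implant patients.
#' @param max_session Highest session index retained (default 5).
#' @return A list with `kept` (audiogram rows) and `exclusions` (one row
#'   per excluded patient-session-ear with a `reason`).
#' @export
applyExclusions <- function(d, cohort = NULL, max_session = 5) {
  d <- validateAudiogramTable(d)
  reason <- rep(NA_character_, nrow(d))
  if (!is.null(cohort)) {
    ci <- cohort$patient_id[cohort$cochlear_implant]
    reason[d$patient_id %in% ci] <- "cochlear_implant"
  }
  take <- is.na(reason) & d$invalid == 1
  reason[take] <- "invalid_audiogram"
  take <- is.na(reason) & d$conductive == 1
  reason[take] <- "conductive_component"
  take <- is.na(reason) & d$session_index > max_session
  reason[take] <- sprintf("session_index_gt_%d", max_session)
  excl <- d[!is.na(reason), c("patient_id", "session_index", "ear")]
  excl$reason <- reason[!is.na(reason)]
  excl <- unique(excl)
  rownames(excl) <- NULL
  list(kept = copyContinuousAttr(d[is.na(reason), , drop = FALSE], d),
       exclusions = excl)
}
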