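# Builders for audiograms and small audiogram tables used across tests.

octaves <- c(250, 500, 1000, 2000, 4000, 8000)

# Ear from six octave levels (NA = no response).
makeEar <- function(levels, ear = "left", ...) {
  earAudiogram(ear, stats::setNames(levels, octaves), ...)
}

# One long-format audiogram row group for a single ear-session.
earRows <- function(patient_id, age, session, ear, levels,
                    conductive = 0, invalid = 0) {
  data.frame(patient_id = patient_id, age_at_session = age,
             session_index = session, ear = ear, frequency_hz = octaves,
             threshold_db_hl = levels,
             no_response = as.integer(is.na(levels)),
             conductive = conductive, invalid = invalid,
             stringsAsFactors = FALSE)
}

# Long table for one patient with identical flat audiograms in both ears
# unless per-session levels are supplied.
patientRows <- function(patient_id, ages, levels_by_session = NULL,
                        base = c(10, 10, 10, 10, 10, 10)) {
  do.call(rbind, lapply(seq_along(ages), function(k) {
    lv <- if (is.null(levels_by_session)) base else levels_by_session[[k]]
    rbind(earRows(patient_id, ages[k], k, "left", lv),
          earRows(patient_id, ages[k], k, "right", lv))
  }))
}

cohortFixturePath <- function() {
  system.file("extdata", "wfs_cohort.csv", package = "wfshear")
}

# Direct simulation of the random-slope model on a visit grid: the
# independent oracle for fitRandomSlope (no audiogram machinery).
simLongData <- function(n_patients, visit_times, beta0 = 40, beta1 = 2,
                        delta = 0, epsilon = 0.01, age0_mean = 13,
                        age0_sd = 5, outcome = "HFA") {
  age0 <- rnorm(n_patients, age0_mean, age0_sd)
  sl <- rnorm(n_patients, beta1, delta)
  do.call(rbind, lapply(seq_len(n_patients), function(i) {
    data.frame(patient_id = sprintf("P%03d", i),
               session_index = seq_along(visit_times),
               ear = "left", t = visit_times, age0 = age0[i],
               sex = sample(c("M", "F"), 1),
               outcome = outcome,
               y = beta0 + sl[i] * visit_times +
                 rnorm(length(visit_times), 0, epsilon),
               stringsAsFactors = FALSE)
  }))
}
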