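# Truncated-normal draw by rejection with a pmin/pmax guard for
# degenerate windows.
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(pmin(pmax(rep(mean, n), lo), hi))
  x <- rnorm(n, mean, sd)
  for (k in 1:50) {
    bad <- x < lo | x > hi
    if (!any(bad)) break
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lo), hi)
}

#' Configuration of the synthetic Wolfram-syndrome cohort generator
#'
#' Defaults emulate the study conditions of a 40-patient natural-history
#' cohort: enrollment ages N(13.5, 5.6) truncated to 5-26 years; onset-age
#' distributions and not-diagnosed probabilities per symptom chosen to
#' match the cohort table (hearing loss N(8.3, 5.1) with 25% of patients
#' remaining normal, i.e. a 75% prevalence target); high-frequency-
#' dominant progression (per-frequency slopes averaging 1.77 dB/year over
#' 4-8 kHz); a shared patient random slope; annual visits (up to 6) with
#' imperfect attendance; occasional conductive or invalid sessions; 5-dB
#' threshold quantization; and an equipment ceiling beyond which
#' no-response is recorded. Patients with hearing-loss onset by age 3
#' usually receive cochlear implants and contribute no audiograms.
#'
#' @param n_patients Cohort size.
#' @param enrollment_age_mean,enrollment_age_sd,enrollment_age_range
#'   Truncated-normal enrollment-age distribution (years).
#' @param p_male Probability of male sex.
#' @param onset Named list (`DM`, `DI`, `HL`, `OA`) of `c(mean, sd)` onset
#'   ages in years.
#' @param p_not_diagnosed Named vector of per-symptom probabilities of no
#'   diagnosis (for HL this is the probability of confirmed-normal
#'   hearing).
#' @param onset_min Minimum onset age (years).
#' @param hl_onset_before_enrollment Force hearing-loss onset at or before
#'   enrollment, so every affected patient progresses throughout the
#'   observation window (used by parameter-recovery studies).
#' @param frequencies Octave frequencies generated (Hz).
#' @param normal_baseline Mean thresholds (dB HL) per frequency for
#'   normal-hearing patients.
#' @param affected_baseline Mean thresholds (dB HL) per frequency at
#'   hearing-loss diagnosis.
#' @param baseline_sd Patient-level SD of the baseline shift (dB).
#' @param ear_baseline_sd Ear-level baseline asymmetry SD (dB).
#' @param slope Per-frequency progression slope (dB/year of affected
#'   time); the default averages 1.77 dB/year over 4 and 8 kHz.
#' @param slope_sd SD of the shared patient random slope (dB/year).
#' @param ear_slope_sd Ear-level slope asymmetry SD (dB/year).
#' @param resid_sd Residual (test-retest) SD per threshold (dB).
#' @param profound_onset_age,profound_offset Onset age at or below which
#'   the severe early phenotype applies, and its baseline offset (dB).
#' @param p_implant_early Cochlear-implant probability for early-onset
#'   patients (no testable audiograms).
#' @param n_visits_max,p_attend,visit_interval,visit_jitter_sd Visit
#'   schedule: up to `n_visits_max` visits `visit_interval` years apart,
#'   first visit always attended, later ones with probability `p_attend`,
#'   ages jittered by `visit_jitter_sd`.
#' @param p_conductive,p_invalid Per-ear-session probabilities of a
#'   transient conductive component or an invalid audiogram.
#' @param conductive_shift dB added at 250-1000 Hz in conductive sessions.
#' @param ceiling Equipment limit (dB HL); louder thresholds are recorded
#'   as no-response.
#' @param floor Lowest recordable threshold (dB HL).
#' @param quantize Round thresholds to the 5-dB audiometric step.
#' @param seed Default seed used by [generateCohort()].
#' @return An object of class `generator_config`.
#' @export
generatorConfig <- function(n_patients = 40,
                            enrollment_age_mean = 13.5,
                            enrollment_age_sd = 5.6,
                            enrollment_age_range = c(5, 26),
                            p_male = 0.45,
                            onset = list(DM = c(5.6, 2.9), DI = c(11.3, 4.2),
                                         HL = c(8.3, 5.1), OA = c(10.0, 4.0)),
                            p_not_diagnosed = c(DM = 0.10, DI = 0.40,
                                                HL = 0.25, OA = 0.075),
                            onset_min = 0.3,
                            hl_onset_before_enrollment = FALSE,
                            frequencies = OCTAVE_FREQS,
                            normal_baseline = c(5, 5, 8, 8, 10, 12),
                            affected_baseline = c(12, 15, 18, 24, 30, 34),
                            baseline_sd = 10,
                            ear_baseline_sd = 4,
                            slope = c(0.10, 0.15, 0.20, 0.30, 1.54, 2.00),
                            slope_sd = 1.0,
                            ear_slope_sd = 0.2,
                            resid_sd = 5,
                            profound_onset_age = 3,
                            profound_offset = 55,
                            p_implant_early = 0.8,
                            n_visits_max = 6,
                            p_attend = 0.85,
                            visit_interval = 1,
                            visit_jitter_sd = 0.05,
                            p_conductive = 0.01,
                            p_invalid = 0.003,
                            conductive_shift = 15,
                            ceiling = 115,
                            floor = -10,
                            quantize = TRUE,
                            seed = 1L) {
  cfg <- as.list(environment())
  if (any(vapply(cfg[c("baseline_sd", "ear_baseline_sd", "slope_sd",
                       "ear_slope_sd", "resid_sd", "visit_jitter_sd")],
                 function(x) any(x < 0), logical(1))))
    wfs_stop("standard deviations must be non-negative")
  probs <- c(cfg$p_male, cfg$p_not_diagnosed, cfg$p_implant_early,
             cfg$p_attend, cfg$p_conductive, cfg$p_invalid)
  if (any(probs < 0 | probs > 1))
    wfs_stop("probabilities must lie in [0, 1]")
  if (cfg$ceiling > 120) wfs_stop("equipment ceiling cannot exceed 120 dB HL")
  if (length(cfg$slope) != length(cfg$frequencies) ||
      length(cfg$normal_baseline) != length(cfg$frequencies) ||
      length(cfg$affected_baseline) != length(cfg$frequencies))
    wfs_stop("per-frequency vectors must match 'frequencies' in length")
  structure(cfg, class = "generator_config")
}

#' Recovery-study preset of the generator
#'
#' [generatorConfig()] specialised for parameter-recovery experiments: 35
#' patients, every patient with hearing loss onset at or before
#' enrollment (so the population mean worse-ear HFA slope equals the
#' configured 1.77 dB/year), and at most 5 annual visits.
#'
#' @param ... Overrides passed on to [generatorConfig()].
#' @return A `generator_config`.
#' @export
recoveryConfig <- function(...) {
  args <- list(n_patients = 35,
               p_not_diagnosed = c(DM = 0.10, DI = 0.40, HL = 0, OA = 0.075),
               hl_onset_before_enrollment = TRUE,
               n_visits_max = 5,
               p_implant_early = 1)
  override <- list(...)
  args[names(override)] <- override
  do.call(generatorConfig, args)
}

#' Generate a synthetic cohort with longitudinal audiograms
#'
#' Draws a cohort symptom table, per-session per-ear per-frequency
#' audiograms, and the generating truth. Thresholds follow
#' `baseline_f + slope_f * max(age - onset, 0) + (b_i + v_ie) * t + noise`
#' for affected patients (flat for normal-hearing ones), then are
#' quantized to 5 dB, floored at -10 dB HL, and censored at the equipment
#' ceiling into no-response markers.
#'
#' @param config A [generatorConfig()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A list of class `synthetic_wfs` with elements `cohort` (the
#'   cohort CSV schema; loads with [loadCohort()]), `audiograms` (the long
#'   audiogram schema), and `truth` (per-patient generating values plus
#'   the config).
#' @export
generateCohort <- function(config = generatorConfig(), seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  n <- config$n_patients
  nf <- length(config$frequencies)
  hf <- config$frequencies %in% c(4000, 8000)

  id <- sprintf("SYN_%02d", seq_len(n))
  sex <- ifelse(rbinom(n, 1, config$p_male) == 1, "M", "F")
  a0 <- round(rtnorm(n, config$enrollment_age_mean, config$enrollment_age_sd,
                     config$enrollment_age_range[1],
                     config$enrollment_age_range[2]), 1)

  onset <- matrix(NA_real_, n, 4, dimnames = list(id, SYMPTOMS))
  for (s in SYMPTOMS) {
    nd <- rbinom(n, 1, config$p_not_diagnosed[[s]]) == 1
    m <- config$onset[[s]][1]; sdv <- config$onset[[s]][2]
    hi <- if (s == "HL" && config$hl_onset_before_enrollment) a0 else
      rep(Inf, n)
    on_s <- round(vapply(seq_len(n), function(i)
      rtnorm(1, m, sdv, config$onset_min, hi[i]), numeric(1)), 1)
    onset[!nd, s] <- on_s[!nd]
  }
  affected <- !is.na(onset[, "HL"])
  early <- affected & onset[, "HL"] <= config$profound_onset_age
  implant <- early & rbinom(n, 1, config$p_implant_early) == 1

  u <- rnorm(n, 0, config$baseline_sd)
  b <- ifelse(affected, rnorm(n, 0, config$slope_sd), 0)
  w <- matrix(rnorm(2 * n, 0, config$ear_baseline_sd), n, 2,
              dimnames = list(id, c("left", "right")))
  v <- matrix(ifelse(affected, rnorm(2 * n, 0, config$ear_slope_sd), 0),
              n, 2, dimnames = list(id, c("left", "right")))

  aud <- list()
  n_sessions <- integer(n)
  for (i in seq_len(n)) {
    if (implant[i]) next
    attend <- c(TRUE, rbinom(config$n_visits_max - 1, 1,
                             config$p_attend) == 1)
    ages <- a0[i] + (seq_len(config$n_visits_max) - 1) * config$visit_interval +
      c(0, rnorm(config$n_visits_max - 1, 0, config$visit_jitter_sd))
    ages <- round(ages[attend], 2)
    ages <- ages + cumsum(c(0, ifelse(diff(ages) <= 0, 0.1, 0)))  # keep strict
    n_sessions[i] <- length(ages)
    t_study <- ages - ages[1]
    for (e in c("left", "right")) {
      base <- if (affected[i])
        config$affected_baseline + u[i] + w[i, e] +
          ifelse(early[i], config$profound_offset, 0)
      else config$normal_baseline + u[i] + w[i, e]
      for (k in seq_along(ages)) {
        mu <- base
        if (affected[i])
          mu <- mu + config$slope * max(ages[k] - onset[i, "HL"], 0) +
            (b[i] + v[i, e]) * t_study[k]
        cond <- rbinom(1, 1, config$p_conductive) == 1
        if (cond)
          mu <- mu + ifelse(config$frequencies <= 1000,
                            config$conductive_shift, 0)
        y <- mu + rnorm(nf, 0, config$resid_sd)
        if (config$quantize) y <- 5 * round(y / 5)
        y <- pmax(y, config$floor)
        nr <- y > config$ceiling
        aud[[length(aud) + 1]] <- data.frame(
          patient_id = id[i], age_at_session = ages[k], session_index = k,
          ear = e, frequency_hz = config$frequencies,
          threshold_db_hl = ifelse(nr, NA_real_, y),
          no_response = as.integer(nr),
          conductive = as.integer(cond),
          invalid = as.integer(rbinom(1, 1, config$p_invalid) == 1),
          stringsAsFactors = FALSE)
      }
    }
  }
  audiograms <- if (length(aud)) do.call(rbind, aud) else
    stats::setNames(data.frame(matrix(ncol = length(AUDIOGRAM_COLS), nrow = 0)),
                    AUDIOGRAM_COLS)
  rownames(audiograms) <- NULL
  # un-quantized tables carry a marker so the schema validator does not
  # enforce the 5-dB step on them
  if (!config$quantize) attr(audiograms, "continuous") <- TRUE

  tok <- function(s) ifelse(is.na(onset[, s]),
                            if (s == "HL") "Normal" else "Not Diagnosed",
                            format(onset[, s], trim = TRUE))
  cohort <- data.frame(patient_id = id, sex = sex, enrollment_age = a0,
                       sibship = "", dm_onset = tok("DM"), di_onset = tok("DI"),
                       hl_onset = tok("HL"), oa_onset = tok("OA"),
                       cochlear_implant = as.integer(implant),
                       n_sessions = n_sessions, stringsAsFactors = FALSE)

  hf_slope <- mean(config$slope[hf])
  truth <- list(
    patients = data.frame(
      patient_id = id, sex = sex, enrollment_age = a0,
      hl_onset = onset[, "HL"], affected = affected, early_onset = early,
      cochlear_implant = implant,
      baseline_shift = u, random_slope = b,
      ear_shift_left = w[, "left"], ear_shift_right = w[, "right"],
      slope_dev_left = v[, "left"], slope_dev_right = v[, "right"],
      hfa_slope_left = ifelse(affected, hf_slope + b + v[, "left"], 0),
      hfa_slope_right = ifelse(affected, hf_slope + b + v[, "right"], 0),
      stringsAsFactors = FALSE),
    mean_hfa_slope = hf_slope,
    seed = seed,
    config = unclass(config))
  structure(list(cohort = cohort, audiograms = audiograms, truth = truth),
            class = "synthetic_wfs")
}

#' @export
print.synthetic_wfs <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients (%d implanted), %d audiogram rows\n",
              nrow(x$cohort), sum(x$cohort$cochlear_implant),
              nrow(x$audiograms)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits `cohort.csv` and `audiograms.csv` in the package's CSV schemas
#' plus `truth.json` with the generating values.
#'
#' @param x A [generateCohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
writeSyntheticCohort <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_wfs"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("cohort.csv", "audiograms.csv", "truth.json"))
  write.csv(x$cohort, paths[1], row.names = FALSE, quote = FALSE)
  write.csv(x$audiograms, paths[2], row.names = FALSE, quote = FALSE, na = "")
  jsonlite::write_json(x$truth, paths[3], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(paths)
}

#' Parameter-recovery harness for the full pipeline
#'
#' For each replicate: generate a synthetic cohort, apply the exclusion
#' rules, build the worse-ear long table, fit the random-slope model to
#' HFA, and compare the fitted slope (at mean baseline age) with the
#' generating population slope. Reports bias, RMSE, Monte-Carlo SE and
#' 95%-CI coverage.
#'
#' @param config A [generatorConfig()]; [recoveryConfig()] is the
#'   intended preset, since its fully-affected cohort makes the
#'   population slope identifiable.
#' @param n_replicates Number of replicate cohorts.
#' @param seed Master seed; replicate seeds are derived from it.
#' @param constants An [siiConstants()] object.
#' @return An object of class `recovery_report` with per-replicate
#'   estimates and a summary; flagged underpowered when `n_replicates`
#'   is below 30.
#' @export
recoveryHarness <- function(config = recoveryConfig(), n_replicates = 200,
                            seed = 1, constants = siiConstants()) {
  truth <- mean(config$slope[config$frequencies %in% c(4000, 8000)])
  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    rows[[i]] <- tryCatch({
      g <- generateCohort(config, seed = deriveSeed(seed, i))
      co <- loadCohort(g$cohort)
      ex <- applyExclusions(g$audiograms, co)
      lt <- buildLongTable(ex$kept, co, "worse", constants)
      fit <- fitRandomSlope(lt, "HFA")
      data.frame(replicate = i, estimate = fit$slope, se = fit$slope_se,
                 df = fit$slope_df, lo = fit$slope_ci[1],
                 hi = fit$slope_ci[2],
                 covered = fit$slope_ci[1] <= truth & truth <= fit$slope_ci[2],
                 n_patients = fit$n_patients, ok = TRUE)
    }, error = function(e)
      data.frame(replicate = i, estimate = NA_real_, se = NA_real_,
                 df = NA_real_, lo = NA_real_, hi = NA_real_, covered = NA,
                 n_patients = NA_integer_, ok = FALSE))
  }
  rows <- do.call(rbind, rows)
  est <- rows$estimate[rows$ok]
  summ <- list(truth = truth,
               n_replicates = n_replicates,
               n_ok = sum(rows$ok),
               mean_estimate = mean(est),
               bias = mean(est) - truth,
               rmse = sqrt(mean((est - truth)^2)),
               mc_se = sd(est) / sqrt(length(est)),
               coverage = mean(rows$covered[rows$ok]))
  structure(list(replicates = rows, summary = summ,
                 underpowered = n_replicates < 30, config = config),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Recovery over %d replicates (%d ok)%s\n", s$n_replicates,
              s$n_ok, if (x$underpowered) " [underpowered]" else ""))
  cat(sprintf("  truth %0.3f; mean estimate %0.3f (MC SE %0.4f); bias %0.4f; RMSE %0.3f\n",
              s$truth, s$mean_estimate, s$mc_se, s$bias, s$rmse))
  cat(sprintf("  95%% CI coverage %0.3f\n", s$coverage))
  invisible(x)
}
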