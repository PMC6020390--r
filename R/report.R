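#' Configuration for a full analysis report
#'
#' @param cohort Path to a cohort CSV or a data.frame in the schema.
#' @param audiograms Path to a long-format audiogram CSV or a data.frame.
#' @param sii_constants Path to a YAML constants file or an
#'   [siiConstants()] object.
#' @param out_dir Output directory for the report bundle.
#' @param subgroups Subsets to model: any of `"whole"`,
#'   `"known_hearing_loss"`.
#' @param ear_roles Ear roles to model: any of `"worse"`, `"better"`.
#' @param include_interaction,include_sex,random_intercept Model options
#'   passed to [fitRandomSlope()].
#' @param max_session Highest session index retained by the exclusion
#'   rules.
#' @param verbose Print progress messages.
#' @return An object of class `run_config`.
#' @export
runConfig <- function(cohort, audiograms, sii_constants = siiConstants(),
                      out_dir, subgroups = c("whole", "known_hearing_loss"),
                      ear_roles = c("worse", "better"),
                      include_interaction = TRUE, include_sex = FALSE,
                      random_intercept = TRUE, max_session = 5,
                      verbose = FALSE) {
  if (is.character(cohort) && !file.exists(cohort))
    wfs_stop(sprintf("cohort path does not exist: %s", cohort))
  if (is.character(audiograms) && !file.exists(audiograms))
    wfs_stop(sprintf("audiogram path does not exist: %s", audiograms))
  if (is.character(sii_constants)) {
    if (!file.exists(sii_constants))
      wfs_stop(sprintf("SII constants path does not exist: %s", sii_constants))
    sii_constants <- readSiiConstants(sii_constants)
  }
  subgroups <- match.arg(subgroups, several.ok = TRUE)
  ear_roles <- match.arg(ear_roles, several.ok = TRUE)
  structure(list(cohort = cohort, audiograms = audiograms,
                 sii_constants = sii_constants, out_dir = out_dir,
                 subgroups = subgroups, ear_roles = ear_roles,
                 include_interaction = include_interaction,
                 include_sex = include_sex,
                 random_intercept = random_intercept,
                 max_session = max_session, verbose = verbose),
            class = "run_config")
}

descRow <- function(v) {
  c(mean = mean(v), sd = sd(v), min = min(v), max = max(v))
}

#' Run the full analysis and write a report bundle
#'
#' Produces, under `config$out_dir`: `cohort_summary.csv` and
#' `cohort_summary.txt` (symptom-onset descriptives), `session1_descriptives.csv`
#' (mean/SD/range of HFA, PTA and SII at the first analyzed session, per
#' ear role), `effect_tables.csv` (F and p per fixed effect plus the
#' annual-change estimate, per outcome, ear role and subgroup),
#' `exclusions.csv`, and `summary.json` holding every number unrounded.
#' Human-readable tables apply the package's central rounding rules
#' (1 decimal dB, integer % SII), so they and the JSON cannot diverge.
#' Any stage failure aborts the run and removes partial output.
#'
#' @param config A [runConfig()].
#' @return Invisibly, a list with the computed objects (`cohort_summary`,
#'   `session1`, `effects`, `exclusions`, `paths`).
#' @export
runReport <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (config$verbose) message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  ok <- FALSE
  on.exit({
    if (!ok && length(written)) unlink(written)
  })
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      wfs_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               "wfshear_stage"))
  }

  say("loading inputs")
  cohort <- stage("load_cohort", loadCohort(config$cohort))
  aud <- stage("load_audiograms",
               if (is.data.frame(config$audiograms))
                 validateAudiogramTable(config$audiograms)
               else readAudiograms(config$audiograms))
  k <- config$sii_constants

  say("cohort summary")
  cs <- stage("cohort_summary", cohortSummary(cohort))
  cs_df <- do.call(rbind, lapply(SYMPTOMS, function(s) {
    p <- cs$symptoms[[s]]
    data.frame(symptom = s, n_diagnosed = p$n,
               onset_mean = round(p$mean, 1), onset_sd = round(p$sd, 1),
               prevalence_pct = round(100 * p$prevalence, 1),
               first_symptom_n = cs$first_symptom[[s]])
  }))

  say("exclusions")
  ex <- stage("exclusions",
              applyExclusions(aud, cohort, config$max_session))

  say("session-1 descriptives")
  s1 <- stage("session1", {
    out <- list()
    for (role in config$ear_roles) {
      lt <- buildLongTable(ex$kept, cohort, role, k)
      lt1 <- lt[lt$session_index ==
                  stats::ave(lt$session_index, lt$patient_id, FUN = min), ]
      for (oc in c("HFA", "PTA", "SII")) {
        v <- lt1$y[lt1$outcome == oc]
        out[[paste(role, oc)]] <- data.frame(
          ear_role = role, outcome = oc, n = length(v),
          t(descRow(v)))
      }
    }
    do.call(rbind, out)
  })

  say("mixed models")
  effects <- list()
  fits <- list()
  for (sg in config$subgroups) {
    for (role in config$ear_roles) {
      lt <- stage("long_table",
                  buildLongTable(ex$kept, cohort, role, k, subgroup = sg))
      for (oc in c("HFA", "PTA", "SII")) {
        fit <- stage(sprintf("fit_%s_%s_%s", sg, role, oc),
                     fitRandomSlope(lt, oc,
                                    include_interaction = config$include_interaction,
                                    include_sex = config$include_sex,
                                    random_intercept = config$random_intercept))
        ac <- estimateAnnualChange(fit)
        an <- as.data.frame(fit$anova)
        effects[[length(effects) + 1]] <- data.frame(
          subgroup = sg, ear_role = role, outcome = oc,
          term = rownames(an), F = an[["F value"]], p = an[["Pr(>F)"]],
          annual_change = ac$value, annual_change_label = ac$label,
          stringsAsFactors = FALSE)
        fits[[sprintf("%s.%s.%s", sg, role, oc)]] <- fit
      }
    }
  }
  effects <- do.call(rbind, effects)
  rownames(effects) <- NULL

  say("writing bundle")
  pth <- function(f) file.path(config$out_dir, f)
  paths <- c(cohort_csv = pth("cohort_summary.csv"),
             cohort_txt = pth("cohort_summary.txt"),
             session1 = pth("session1_descriptives.csv"),
             effects = pth("effect_tables.csv"),
             exclusions = pth("exclusions.csv"),
             json = pth("summary.json"))
  write.csv(cs_df, paths["cohort_csv"], row.names = FALSE)
  written <- c(written, paths["cohort_csv"])
  txt <- utils::capture.output(print(cs))
  writeLines(txt, paths["cohort_txt"])
  written <- c(written, paths["cohort_txt"])
  s1r <- s1
  s1r[c("mean", "sd", "min", "max")] <- round(s1r[c("mean", "sd", "min", "max")], 1)
  write.csv(s1r, paths["session1"], row.names = FALSE)
  written <- c(written, paths["session1"])
  er <- effects
  er$F <- round(er$F, 2); er$p <- round(er$p, 4)
  er$annual_change <- round(er$annual_change, 2)
  write.csv(er, paths["effects"], row.names = FALSE)
  written <- c(written, paths["effects"])
  write.csv(ex$exclusions, paths["exclusions"], row.names = FALSE)
  written <- c(written, paths["exclusions"])
  json <- list(
    cohort = list(n = cs$n,
                  sex = as.list(cs$sex_counts),
                  enrollment_age = cs$enrollment_age,
                  symptoms = cs$symptoms,
                  first_symptom = as.list(cs$first_symptom),
                  hl_by_age3 = cs$hl_by_age3,
                  hearing_status = as.list(cs$hearing_status),
                  sex_association = cs$sex_association[c("chi_square", "p", "df")]),
    session1 = s1,
    effects = effects,
    exclusions = list(n = nrow(ex$exclusions),
                      by_reason = as.list(table(ex$exclusions$reason))))
  jsonlite::write_json(json, paths["json"], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  written <- c(written, paths["json"])
  ok <- TRUE
  invisible(list(cohort_summary = cs, session1 = s1, effects = effects,
                 fits = fits, exclusions = ex$exclusions, paths = paths))
}
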