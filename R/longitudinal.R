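#' Build a long-format modelling dataset for one ear role
#'
#' Composes the per-session metrics into the repeated-measures table the
#' mixed models consume. For each patient the worse/better ear assignment
#' is made once — worse = lower unaided SII averaged over all of the
#' patient's analyzed sessions, ties broken by higher mean HFA, then
#' higher mean PTA, then the left-ear convention — and held fixed across
#' sessions so that a trajectory always follows the same physical ear.
#' Averaging over sessions (rather than ranking a single session) keeps
#' the assignment orthogonal to any one session's measurement error;
#' ranking on the first session alone demonstrably biases the worse-ear
#' slope downward through regression to the mean, because the session
#' that drives the selection also anchors the start of the trajectory.
#' Time `t` is years
#' since the patient's first analyzed session; `age0` is age at that
#' session. SII is carried in percentage points (0-100) so its annual
#' change is reported on the conventional scale.
#'
#' @param d Long-format audiogram table, already passed through
#'   [applyExclusions()].
#' @param cohort Optional [loadCohort()] result supplying sex and the
#'   hearing-loss status used by the subgroup filter.
#' @param ear_role `"worse"` or `"better"`.
#' @param constants An [siiConstants()] object.
#' @param subgroup `"whole"` or `"known_hearing_loss"` (restricts to
#'   patients with diagnosed hearing loss).
#' @return A data.frame of class `long_dataset` with columns
#'   `patient_id`, `session_index`, `ear`, `t`, `age0`, `sex`, `outcome`
#'   (HFA/PTA/SII) and `y`; attributes `ear_role`, `subgroup`, and
#'   `dropped` (patients omitted, with reasons).
#' @export
buildLongTable <- function(d, cohort = NULL,
                           ear_role = c("worse", "better"),
                           constants = siiConstants(),
                           subgroup = c("whole", "known_hearing_loss")) {
  ear_role <- match.arg(ear_role)
  subgroup <- match.arg(subgroup)
  m <- sessionMetrics(d, constants)
  if (subgroup == "known_hearing_loss") {
    if (is.null(cohort))
      wfs_stop("subgroup filtering requires a cohort table")
    keep <- cohort$patient_id[!is.na(cohort$hl_onset)]
    m <- m[m$patient_id %in% keep, , drop = FALSE]
  }
  dropped <- data.frame(patient_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  recs <- list()
  for (p in unique(m$patient_id)) {
    mp <- m[m$patient_id == p, , drop = FALSE]
    mp <- mp[order(mp$session_index), , drop = FALSE]
    L <- mp[mp$ear == "left", ]
    R <- mp[mp$ear == "right", ]
    if (!nrow(L) || !nrow(R)) {
      dropped <- rbind(dropped,
                       data.frame(patient_id = p,
                                  reason = "only one ear ever analyzable"))
      next
    }
    mL <- c(sii = mean(L$sii), hfa = mean(L$hfa), pta = mean(L$pta))
    mR <- c(sii = mean(R$sii), hfa = mean(R$hfa), pta = mean(R$pta))
    worse_side <- if (mL["sii"] != mR["sii"]) {
      if (mL["sii"] < mR["sii"]) "left" else "right"
    } else if (mL["hfa"] != mR["hfa"]) {
      if (mL["hfa"] > mR["hfa"]) "left" else "right"
    } else if (mL["pta"] != mR["pta"]) {
      if (mL["pta"] > mR["pta"]) "left" else "right"
    } else "left"
    side <- if (ear_role == "worse") worse_side else
      setdiff(c("left", "right"), worse_side)
    me <- mp[mp$ear == side, , drop = FALSE]
    if (!nrow(me)) {
      dropped <- rbind(dropped,
                       data.frame(patient_id = p,
                                  reason = sprintf("no valid %s-ear sessions", side)))
      next
    }
    age0 <- me$age_at_session[1]
    sex <- if (!is.null(cohort)) {
      i <- match(p, cohort$patient_id)
      if (is.na(i)) NA_character_ else cohort$sex[i]
    } else NA_character_
    recs[[p]] <- data.frame(
      patient_id = p,
      session_index = rep(me$session_index, 3),
      ear = side,
      t = rep(me$age_at_session - age0, 3),
      age0 = age0,
      sex = sex,
      outcome = rep(c("HFA", "PTA", "SII"), each = nrow(me)),
      y = c(me$hfa, me$pta, 100 * me$sii),
      stringsAsFactors = FALSE)
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(patient_id = character(), session_index = integer(),
               ear = character(), t = numeric(), age0 = numeric(),
               sex = character(), outcome = character(), y = numeric())
  rownames(out) <- NULL
  structure(out, ear_role = ear_role, subgroup = subgroup,
            dropped = dropped,
            class = c("long_dataset", "data.frame"))
}

#' Fit a random-slope linear mixed model to one outcome
#'
#' Fits, by REML, `y = b0 + b1 t + b2 age0c + b3 t:age0c (+ sex terms) +
#' u0_i + u1_i t + e`, where `age0c` is age at first session centered at
#' the sample mean (one value per patient), `u1_i ~ N(0, delta^2)` is the
#' patient random slope, `u0_i ~ N(0, tau^2)` an optional independent
#' random intercept, and `e ~ N(0, epsilon^2)` homoscedastic error.
#' Fixed effects are tested with type III F tests using Satterthwaite
#' denominator degrees of freedom. If the intercept-plus-slope fit fails
#' to converge the model falls back to the pure random-slope covariance
#' and records that it did so.
#'
#' @param data A [buildLongTable()] result (or any data.frame with
#'   `patient_id`, `t`, `age0`, `sex`, `outcome`, `y`).
#' @param outcome `"HFA"`, `"PTA"` or `"SII"`.
#' @param include_interaction Include the time-by-baseline-age term
#'   (default TRUE).
#' @param include_sex Add sex main effect and sex-by-time interaction.
#' @param random_intercept Include the independent random intercept
#'   (default TRUE); `FALSE` gives the pure random-slope covariance.
#' @return An object of class `slope_fit`: coefficient table with
#'   Satterthwaite df and p-values, type III F table, variance components
#'   (`slope_var`, `intercept_var`, `resid_var`), the slope estimate with
#'   95% CI, per-patient fitted slopes, and the underlying `lmerMod`.
#' @export
fitRandomSlope <- function(data, outcome = c("HFA", "PTA", "SII"),
                           include_interaction = TRUE,
                           include_sex = FALSE,
                           random_intercept = TRUE) {
  outcome <- match.arg(outcome)
  d <- as.data.frame(data)
  d <- d[d$outcome == outcome, , drop = FALSE]
  if (!nrow(d)) wfs_stop(sprintf("no rows for outcome %s", outcome))
  per <- table(d$patient_id)
  if (sum(per >= 2) < 2)
    wfs_stop("need at least 2 patients with at least 2 time points",
             "wfshear_precondition")
  if (include_sex && anyNA(d$sex))
    wfs_stop("sex terms requested but sex is missing for some patients")
  first <- !duplicated(d$patient_id)
  age0_mean <- mean(d$age0[first])
  d$age0c <- d$age0 - age0_mean
  d$patient_id <- factor(d$patient_id)
  fx <- if (include_interaction) "t * age0c" else "t + age0c"
  if (include_sex) fx <- paste(fx, "+ sex + t:sex")
  re_full <- "(1 | patient_id) + (0 + t | patient_id)"
  re_slope <- "(0 + t | patient_id)"
  fit_one <- function(re) {
    f <- stats::as.formula(paste("y ~", fx, "+", re))
    ok <- TRUE
    fit <- withCallingHandlers(
      suppressMessages(lmerTest::lmer(f, data = d, REML = TRUE)),
      warning = function(w) {
        if (grepl("converge", conditionMessage(w), ignore.case = TRUE))
          ok <<- FALSE
        invokeRestart("muffleWarning")
      })
    list(fit = fit, ok = ok)
  }
  fallback <- FALSE
  r <- fit_one(if (random_intercept) re_full else re_slope)
  if (!r$ok && random_intercept) {
    fallback <- TRUE
    r <- fit_one(re_slope)
  }
  fit <- r$fit
  co <- coef(summary(fit))
  an <- suppressMessages(stats::anova(fit, type = 3))
  vc <- as.data.frame(lme4::VarCorr(fit))
  slope_var <- sum(vc$vcov[vc$var1 %in% "t" & is.na(vc$var2)], na.rm = TRUE)
  int_var <- sum(vc$vcov[vc$var1 %in% "(Intercept)" & is.na(vc$var2)],
                 na.rm = TRUE)
  resid_var <- vc$vcov[vc$grp == "Residual"]
  b1 <- co["t", "Estimate"]
  se1 <- co["t", "Std. Error"]
  df1 <- co["t", "df"]
  ci <- b1 + c(-1, 1) * qt(0.975, df1) * se1
  # fitted per-patient slopes: fixed slope at mean age0 + random deviation
  re <- lme4::ranef(fit)$patient_id
  slopes <- b1 + if ("t" %in% colnames(re)) re[, "t"] else 0
  structure(list(outcome = outcome,
                 coefficients = co,
                 anova = an,
                 slope = b1, slope_se = se1, slope_df = df1, slope_ci = ci,
                 slope_p = co["t", "Pr(>|t|)"],
                 varcomp = list(slope_var = slope_var,
                                intercept_var = if (random_intercept && !fallback)
                                  int_var else NA_real_,
                                resid_var = resid_var),
                 patient_slopes = setNames(slopes, rownames(re)),
                 n_patients = nlevels(d$patient_id),
                 n_obs = nrow(d),
                 age0_mean = age0_mean,
                 include_interaction = include_interaction,
                 include_sex = include_sex,
                 random_intercept = random_intercept && !fallback,
                 fallback = fallback,
                 converged = r$ok,
                 ear_role = attr(data, "ear_role"),
                 subgroup = attr(data, "subgroup"),
                 model = fit),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("Random-slope fit: %s%s, %d patients, %d observations\n",
              x$outcome,
              if (!is.null(x$ear_role)) paste0(" (", x$ear_role, " ear)") else "",
              x$n_patients, x$n_obs))
  cat(sprintf("  slope %0.3f / year (SE %0.3f, df %0.1f, p = %0.4g, 95%% CI %0.3f..%0.3f)\n",
              x$slope, x$slope_se, x$slope_df, x$slope_p,
              x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  variance components: slope %0.3f, intercept %s, residual %0.3f\n",
              x$varcomp$slope_var,
              if (is.na(x$varcomp$intercept_var)) "-" else
                sprintf("%0.3f", x$varcomp$intercept_var),
              x$varcomp$resid_var))
  if (x$fallback)
    cat("  note: fell back to pure random-slope covariance\n")
  print(round(as.data.frame(x$anova), 4))
  invisible(x)
}

#' Average annual change implied by a fit
#'
#' Reports the fixed time slope of the age-centered model, i.e. the
#' average annual change for a patient of mean baseline age. Direction
#' labels follow the outcome convention: HFA and PTA worsen upward (dB
#' increase), SII worsens downward (percentage-point decrease).
#'
#' @param fit A [fitRandomSlope()] result.
#' @return A list of class `annual_change` with `outcome`, `value`
#'   (signed, outcome units per year), `direction` and a formatted
#'   `label`.
#' @export
estimateAnnualChange <- function(fit) {
  stopifnot(inherits(fit, "slope_fit"))
  b <- fit$slope
  unit <- if (fit$outcome %in% c("HFA", "PTA")) " dB" else ""
  direction <- if (b > 0) "increase" else if (b < 0) "decrease" else "no change"
  label <- if (b == 0) sprintf("0.00%s (no change)", unit) else
    sprintf("%.2f%s %s", abs(b), unit, direction)
  structure(list(outcome = fit$outcome, value = b, direction = direction,
                 label = label),
            class = "annual_change")
}

#' @export
print.annual_change <- function(x, ...) {
  cat(sprintf("%s: estimated average change over 1 year = %s\n",
              x$outcome, x$label))
  invisible(x)
}
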