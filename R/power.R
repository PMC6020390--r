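#' Two-arm trial design for a progression-slowing intervention
#'
#' @param n_per_arm Patients per arm (equal allocation).
#' @param visit_times Assessment times in years; default every six months
#'   over a 3-year follow-up (7 visits).
#' @param reduction Proportional reduction `r` of the mean annual
#'   progression rate in the treatment arm (0.5 = 50% slowing).
#' @param alpha Two-sided significance level (default 0.05).
#' @return An object of class `trial_design`.
#' @export
trialDesign <- function(n_per_arm, visit_times = seq(0, 3, by = 0.5),
                        reduction = 0.6, alpha = 0.05) {
  if (length(visit_times) < 2 || is.unsorted(visit_times, strictly = TRUE))
    wfs_stop("visit_times must be at least two strictly increasing times")
  if (visit_times[1] != 0)
    wfs_stop("visit_times must start at baseline (0)")
  if (reduction < 0 || reduction > 1)
    wfs_stop("reduction must lie in [0, 1]")
  if (n_per_arm < 2)
    wfs_stop("n_per_arm must be at least 2")
  structure(list(n_per_arm = as.integer(n_per_arm),
                 visit_times = as.numeric(visit_times),
                 reduction = reduction, alpha = alpha),
            class = "trial_design")
}

#' Simulation parameters for the power analysis
#'
#' The generating model for one subject in arm `g` is
#' `y_it = baseline_mean + slope_i * t + e_it`, with
#' `slope_i ~ N(beta_g, delta^2)`, `beta_treatment = (1 - r) *
#' beta_placebo`, and `e_it ~ N(0, epsilon^2)`. Baseline means are equal
#' in both arms, so no random intercept is simulated.
#'
#' @param beta_placebo Mean annual progression in the placebo arm
#'   (outcome units / year).
#' @param delta SD of the patient random slope.
#' @param epsilon Residual SD.
#' @param baseline_mean Common baseline mean (default 50).
#' @param n_sims Number of simulated trials (default 1000).
#' @param seed Master seed; every replicate draws an independent
#'   substream from it.
#' @return An object of class `sim_params`.
#' @export
simParams <- function(beta_placebo, delta, epsilon, baseline_mean = 50,
                      n_sims = 1000, seed = 1) {
  if (delta < 0 || epsilon < 0)
    wfs_stop("delta and epsilon must be non-negative")
  if (n_sims < 1) wfs_stop("n_sims must be at least 1")
  structure(list(beta_placebo = beta_placebo, delta = delta,
                 epsilon = epsilon, baseline_mean = baseline_mean,
                 n_sims = as.integer(n_sims), seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate one two-arm trial
#'
#' Draws per-subject slopes and visit-level observations under the
#' random-slope model of [simParams()]. Uses the current RNG state unless
#' `seed` is given.
#'
#' @param design A [trialDesign()].
#' @param params A [simParams()].
#' @param seed Optional integer seed for a self-contained reproducible
#'   draw.
#' @return A data.frame with `subject`, `arm` (placebo/treatment, with a
#'   0/1 numeric `arm01`), `time` and `y`; true per-subject slopes are in
#'   `attr(, "true_slopes")`.
#' @export
simulateTrial <- function(design, params, seed = NULL) {
  stopifnot(inherits(design, "trial_design"), inherits(params, "sim_params"))
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  n <- design$n_per_arm
  tt <- design$visit_times
  beta_g <- c(rep(params$beta_placebo, n),
              rep((1 - design$reduction) * params$beta_placebo, n))
  slopes <- rnorm(2 * n, beta_g, params$delta)
  d <- expand.grid(subject = seq_len(2 * n), time = tt,
                   KEEP.OUT.ATTRS = FALSE)
  d$arm01 <- as.numeric(d$subject > n)
  d$arm <- factor(ifelse(d$arm01 == 1, "treatment", "placebo"),
                  levels = c("placebo", "treatment"))
  d$y <- params$baseline_mean + slopes[d$subject] * d$time +
    rnorm(nrow(d), 0, params$epsilon)
  d$subject <- factor(sprintf("S%03d", d$subject))
  attr(d, "true_slopes") <- slopes
  d
}

#' Analyze one simulated trial
#'
#' Fits `y ~ time * arm` with a per-subject random slope (pure
#' random-slope covariance by default, matching the generating model;
#' a random intercept can be added) and tests the treatment-by-time
#' coefficient two-sided. Satterthwaite degrees of freedom by default; a
#' residual-df Wald test is available as a cheaper fallback.
#'
#' @param table A [simulateTrial()] result (or any long trial table with
#'   `subject`, `arm`, `time`, `y`).
#' @param alpha Two-sided significance level.
#' @param df_method `"satterthwaite"` or `"residual"`.
#' @param random_intercept Add `(1 | subject)` to the covariance.
#' @return A list with `estimate`, `se`, `df`, `p_value`, `rejected`,
#'   `converged`.
#' @export
analyzeTrial <- function(table, alpha = 0.05,
                         df_method = c("satterthwaite", "residual"),
                         random_intercept = FALSE) {
  df_method <- match.arg(df_method)
  if (length(unique(table$time)) < 2)
    wfs_stop("slope not estimable from a single visit time",
             "wfshear_precondition")
  re <- if (random_intercept)
    "(1 | subject) + (0 + time | subject)" else "(0 + time | subject)"
  f <- stats::as.formula(paste("y ~ time * arm +", re))
  ok <- TRUE
  fit <- tryCatch(
    withCallingHandlers(
      suppressMessages(
        if (df_method == "satterthwaite")
          lmerTest::lmer(f, data = table, REML = TRUE)
        else lme4::lmer(f, data = table, REML = TRUE)),
      warning = function(w) {
        if (grepl("converge", conditionMessage(w), ignore.case = TRUE))
          ok <<- FALSE
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(estimate = NA_real_, se = NA_real_, df = NA_real_,
                p_value = NA_real_, rejected = NA, converged = FALSE))
  co <- coef(summary(fit))
  term <- grep("^time:arm", rownames(co), value = TRUE)[1]
  est <- co[term, "Estimate"]
  se <- co[term, "Std. Error"]
  if (df_method == "satterthwaite") {
    dfree <- co[term, "df"]
    p <- co[term, "Pr(>|t|)"]
  } else {
    dfree <- nrow(table) - nrow(co)
    p <- 2 * stats::pt(-abs(est / se), dfree)
  }
  list(estimate = est, se = se, df = dfree, p_value = p,
       rejected = is.finite(p) && p < alpha, converged = ok)
}

#' Empirical power of the trial design by Monte Carlo
#'
#' Simulates `n_sims` trials under the design and parameters, analyzes
#' each with [analyzeTrial()], and reports the rejection proportion.
#' Replicates that fail to converge are excluded from the denominator and
#' counted. Each replicate uses an independent substream of the master
#' seed, so the result is reproducible and independent of execution
#' order.
#'
#' @inheritParams simulateTrial
#' @param df_method Passed to [analyzeTrial()].
#' @param random_intercept Passed to [analyzeTrial()].
#' @return An object of class `power_result`: `power`, `n_sims`,
#'   `n_rejections`, `n_converged`, `mc_se` (binomial Monte-Carlo SE).
#' @export
empiricalPower <- function(design, params,
                           df_method = "satterthwaite",
                           random_intercept = FALSE) {
  states <- substreamStates(params$seed, params$n_sims)
  rej <- conv <- 0L
  for (i in seq_len(params$n_sims)) {
    res <- withRngState(states[[i]], {
      tab <- simulateTrial(design, params)
      analyzeTrial(tab, alpha = design$alpha, df_method = df_method,
                   random_intercept = random_intercept)
    })
    if (isTRUE(res$converged)) {
      conv <- conv + 1L
      if (isTRUE(res$rejected)) rej <- rej + 1L
    }
  }
  p <- if (conv > 0) rej / conv else NA_real_
  structure(list(power = p, n_sims = params$n_sims,
                 n_rejections = rej, n_converged = conv,
                 mc_se = if (conv > 0) sqrt(p * (1 - p) / conv) else NA_real_,
                 design = design, params = params),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Empirical power %.3f (MC SE %.3f) from %d/%d converged trials\n",
              x$power, x$mc_se, x$n_converged, x$n_sims))
  cat(sprintf("  design: n = %d/arm, %d visits over %.1f y, reduction %.0f%%, alpha %.2f\n",
              x$design$n_per_arm, length(x$design$visit_times),
              max(x$design$visit_times), 100 * x$design$reduction,
              x$design$alpha))
  invisible(x)
}

#' Closed-form power of the two-sample slope test (analytic oracle)
#'
#' With known variances, the per-subject OLS slope over the visit
#' schedule has variance `epsilon^2 / sum((t - tbar)^2) + delta^2`, and
#' comparing mean slopes between equal arms is a two-sample z test:
#' `power = P(|Z| > z_{alpha/2} - effect/SE)` with
#' `SE = sqrt(2 * var_slope / n)`. Used as an independent check on the
#' Monte-Carlo machinery (exact in the `delta = 0`, known-`epsilon`
#' case).
#'
#' @inheritParams simulateTrial
#' @return Power of the two-sided two-sample slope test.
#' @export
analyticSlopePower <- function(design, params) {
  sst <- sum((design$visit_times - mean(design$visit_times))^2)
  var_slope <- params$epsilon^2 / sst + params$delta^2
  eff <- abs(design$reduction * params$beta_placebo)
  se <- sqrt(2 * var_slope / design$n_per_arm)
  zc <- stats::qnorm(1 - design$alpha / 2)
  pnorm(eff / se - zc) + pnorm(-eff / se - zc)
}

#' Smallest per-arm sample size reaching a target power
#'
#' Walks a step-5 grid of `n_per_arm` upward until the empirical power
#' reaches the target, then refines by step 1 just below the boundary,
#' and reports the full power-versus-n trace. Each grid point uses a seed
#' derived deterministically from the master seed and n, so the search is
#' reproducible and grid points are mutually independent.
#'
#' @param params A [simParams()]; `beta_placebo` must be non-zero.
#' @param reduction Progression reduction `r` (> 0).
#' @param target_power Target power (default 0.8).
#' @param alpha Two-sided significance level.
#' @param visit_times Assessment schedule (default 7 visits over 3 y).
#' @param n_min,n_max Search bounds for `n_per_arm`.
#' @param coarse_step Coarse grid step (default 5).
#' @param df_method Passed to [analyzeTrial()].
#' @return An object of class `sample_size_result`: `n_required` (`NA`
#'   when the target is unreachable below `n_max`), `achieved`, and
#'   `trace` (data.frame of n, power, mc_se, stage).
#' @export
sampleSizeSearch <- function(params, reduction, target_power = 0.8,
                             alpha = 0.05, visit_times = seq(0, 3, by = 0.5),
                             n_min = 5, n_max = 200, coarse_step = 5,
                             df_method = "satterthwaite") {
  if (params$beta_placebo == 0)
    wfs_stop("beta_placebo must be non-zero for a sample-size search")
  if (reduction <= 0)
    wfs_stop("reduction must be positive for a sample-size search")
  eval_n <- function(n, stage) {
    des <- trialDesign(n, visit_times, reduction, alpha)
    pp <- params
    pp$seed <- deriveSeed(params$seed, n)
    pr <- empiricalPower(des, pp, df_method = df_method)
    data.frame(n = n, power = pr$power, mc_se = pr$mc_se, stage = stage)
  }
  trace <- list()
  hit <- NA_integer_
  for (n in seq(max(n_min, 2), n_max, by = coarse_step)) {
    row <- eval_n(n, "coarse")
    trace[[length(trace) + 1]] <- row
    if (row$power >= target_power) { hit <- n; break }
  }
  if (!is.na(hit) && coarse_step > 1) {
    for (n in seq(max(max(n_min, 2), hit - coarse_step + 1), hit - 1)) {
      row <- eval_n(n, "refine")
      trace[[length(trace) + 1]] <- row
      if (row$power >= target_power) { hit <- n; break }
    }
  }
  trace <- do.call(rbind, trace)
  rownames(trace) <- NULL
  structure(list(n_required = hit, achieved = !is.na(hit),
                 target_power = target_power, reduction = reduction,
                 trace = trace, params = params),
            class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  if (x$achieved)
    cat(sprintf("Smallest n per arm with power >= %.0f%% at %.0f%% reduction: %d\n",
                100 * x$target_power, 100 * x$reduction, x$n_required))
  else
    cat(sprintf("Target power %.0f%% not reached within the search range\n",
                100 * x$target_power))
  print(transform(x$trace, power = round(power, 3), mc_se = round(mc_se, 3)))
  invisible(x)
}
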