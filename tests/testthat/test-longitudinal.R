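test_that("long-table time is years since first analyzed session", {
  rows <- patientRows("P1", ages = c(10.0, 11.1))
  lt <- buildLongTable(rows)
  expect_equal(sort(unique(lt$t)), c(0.0, 1.1))
  expect_equal(unique(lt$age0), 10.0)
  expect_equal(sort(unique(lt$outcome)), c("HFA", "PTA", "SII"))
  # conservation: one record per patient-session-outcome
  expect_equal(nrow(lt), 2 * 3)
})

test_that("worse-ear role follows the consistently worse ear", {
  worse <- c(40, 45, 50, 60, 70, 80)
  better <- rep(10, 6)
  rows <- do.call(rbind, lapply(1:3, function(k)
    rbind(earRows("P1", 9 + k, k, "left", worse),
          earRows("P1", 9 + k, k, "right", better))))
  lt <- buildLongTable(rows, ear_role = "worse")
  expect_equal(unique(lt$ear), "left")
  lt2 <- buildLongTable(rows, ear_role = "better")
  expect_equal(unique(lt2$ear), "right")
  # SII carried as percentage points
  expect_true(all(lt$y[lt$outcome == "SII"] >= 0 &
                    lt$y[lt$outcome == "SII"] <= 100))
})

test_that("record count equals analyzed sessions per outcome", {
  g <- generateCohort(generatorConfig(n_patients = 12, seed = 21))
  co <- loadCohort(g$cohort)
  ex <- applyExclusions(g$audiograms, co)
  lt <- buildLongTable(ex$kept, co, "worse")
  m <- sessionMetrics(ex$kept)
  # per patient: number of sessions of the assigned ear
  per_pat <- table(lt$patient_id[lt$outcome == "HFA"])
  for (p in names(per_pat)) {
    side <- lt$ear[lt$patient_id == p][1]
    expect_equal(unname(per_pat[[p]]),
                 sum(m$patient_id == p & m$ear == side))
  }
})

test_that("noise-free generation is recovered exactly in the limit", {
  set.seed(101)
  d <- simLongData(20, 0:4, beta0 = 40, beta1 = 2, delta = 0,
                   epsilon = 1e-3)
  fit <- fitRandomSlope(d, "HFA")
  expect_equal(fit$slope, 2, tolerance = 1e-2)
  fit2 <- fitRandomSlope(d, "HFA", include_interaction = FALSE)
  expect_equal(fit2$slope, 2, tolerance = 1e-2)
  expect_true(fit$varcomp$resid_var < 1e-4)
})

test_that("single-patient or single-visit data are refused", {
  d <- simLongData(1, 0:3)
  expect_error(fitRandomSlope(d, "HFA"), class = "wfshear_precondition")
  d2 <- simLongData(5, 0)
  expect_error(fitRandomSlope(d2, "HFA"), class = "wfshear_precondition")
})

test_that("fits are invariant to patient order", {
  set.seed(102)
  d <- simLongData(15, 0:3, beta1 = 1.5, delta = 1, epsilon = 3)
  f1 <- fitRandomSlope(d, "HFA")
  d2 <- d[rev(seq_len(nrow(d))), ]
  f2 <- fitRandomSlope(d2, "HFA")
  expect_equal(f1$slope, f2$slope, tolerance = 1e-8)
  expect_equal(f1$slope_se, f2$slope_se, tolerance = 1e-8)
})

test_that("slope recovery is unbiased over replicated direct simulations", {
  set.seed(103)
  est <- replicate(60, {
    d <- simLongData(35, 0:4, beta1 = 1.77, delta = 1, epsilon = 3.5)
    fitRandomSlope(d, "HFA")$slope
  })
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 1.77), 2.5 * mc_se)
  # interaction and no-interaction models agree when true interaction is 0
  set.seed(104)
  pair <- replicate(30, {
    d <- simLongData(35, 0:4, beta1 = 1.77, delta = 1, epsilon = 3.5)
    c(fitRandomSlope(d, "HFA")$slope,
      fitRandomSlope(d, "HFA", include_interaction = FALSE)$slope)
  })
  expect_lt(abs(mean(pair[1, ] - pair[2, ])), 0.1)
})

test_that("sex terms are estimable and near zero without a sex effect", {
  set.seed(105)
  d <- simLongData(30, 0:4, beta1 = 1.5, delta = 0.8, epsilon = 3)
  fit <- fitRandomSlope(d, "HFA", include_sex = TRUE)
  expect_true(any(grepl("sex", rownames(fit$coefficients))))
  expect_true(all(is.finite(fit$coefficients[, "Pr(>|t|)"])))
})

test_that("annual change labels follow the outcome sign convention", {
  set.seed(106)
  d <- simLongData(12, 0:3, beta1 = 1.77, delta = 0, epsilon = 0.01)
  ac <- estimateAnnualChange(fitRandomSlope(d, "HFA"))
  expect_equal(ac$direction, "increase")
  expect_match(ac$label, "dB increase")
  expect_equal(ac$value, 1.77, tolerance = 0.02)
  d2 <- simLongData(12, 0:3, beta0 = 80, beta1 = -1.5, delta = 0,
                    epsilon = 0.01, outcome = "SII")
  ac2 <- estimateAnnualChange(fitRandomSlope(d2, "SII"))
  expect_equal(ac2$direction, "decrease")
  expect_match(ac2$label, "decrease")
  expect_false(grepl("dB", ac2$label))
})

test_that("pure random-slope covariance is available", {
  set.seed(107)
  d <- simLongData(20, 0:3, beta1 = 1, delta = 0.5, epsilon = 2)
  fit <- fitRandomSlope(d, "HFA", random_intercept = FALSE)
  expect_true(is.na(fit$varcomp$intercept_var))
  expect_true(fit$varcomp$slope_var >= 0)
})
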