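test_that("the packaged cohort loads with the expected composition", {
  co <- loadCohort(cohortFixturePath())
  expect_equal(nrow(co), 40)
  expect_equal(sum(co$sex == "M"), 18)
  expect_equal(sum(co$cochlear_implant), 4)
  expect_equal(sum(co$hl_status == "normal"), 10)
  expect_equal(sum(co$hl_status == "diagnosed"), 30)
})

test_that("cohort parsing is strict about schema and tokens", {
  co <- read.csv(cohortFixturePath(), colClasses = "character")
  # empty file with header -> 0 records
  expect_equal(nrow(loadCohort(co[0, ])), 0)
  # case-insensitive status tokens
  co2 <- co
  co2$hl_onset[co2$hl_onset == "Normal"] <- "normal"
  co2$di_onset[co2$di_onset == "Not Diagnosed"] <- "NOT DIAGNOSED"
  expect_equal(loadCohort(co2)$hl_status, loadCohort(co)$hl_status)
  # duplicate id refused
  co3 <- rbind(co, co[1, ])
  expect_error(loadCohort(co3), "duplicate")
  # unknown token refused with location
  co4 <- co
  co4$dm_onset[3] <- "unsure"
  expect_error(loadCohort(co4), "unsure")
})

test_that("symptom summaries use diagnosed patients and sample SD", {
  co <- loadCohort(cohortFixturePath())
  hl <- symptomSummary(co, "HL")
  expect_equal(hl$n, 30)
  # brute-force mean/SD over the diagnosed onsets
  v <- co$hl_onset[!is.na(co$hl_onset)]
  expect_equal(hl$mean, sum(v) / length(v), tolerance = 1e-9)
  expect_equal(hl$sd, sqrt(sum((v - mean(v))^2) / (length(v) - 1)),
               tolerance = 1e-9)
  expect_equal(round(hl$mean, 1), 8.3)
  expect_equal(round(hl$sd, 1), 5.1)
  dm <- symptomSummary(co, "DM")
  expect_equal(dm$n, 36)
  expect_equal(round(dm$mean, 1), 5.6)
  # single patient -> SD undefined
  one <- co[!is.na(co$hl_onset), ][1, ]
  s1 <- symptomSummary(loadCohort(as.data.frame(
    read.csv(cohortFixturePath(), colClasses = "character")[
      match(one$patient_id, co$patient_id), ])), "HL")
  expect_equal(s1$n, 1)
  expect_true(is.na(s1$sd))
})

test_that("prevalence counts implanted patients as diagnosed", {
  co <- loadCohort(cohortFixturePath())
  expect_equal(prevalence(co, "HL"), 0.75)
  # all-normal toy cohort
  toy <- read.csv(cohortFixturePath(), colClasses = "character")[1:3, ]
  toy$hl_onset <- "Normal"
  toy$cochlear_implant <- "0"; toy$n_sessions <- "1"
  expect_equal(prevalence(loadCohort(toy), "HL"), 0)
  # 2 of 3 diagnosed
  toy$hl_onset <- c("4.0", "6.0", "Normal")
  expect_equal(prevalence(loadCohort(toy), "HL"), 2 / 3)
})

test_that("first-symptom counting is strict with tie co-counting", {
  co <- loadCohort(cohortFixturePath())
  fs <- firstSymptomCounts(co)
  expect_equal(fs$first[["HL"]], 7)
  expect_equal(sum(!is.na(co$dm_onset) | !is.na(co$di_onset) |
                     !is.na(co$hl_onset) | !is.na(co$oa_onset)), 40)
  # toy: single diagnosed symptom
  toy <- read.csv(cohortFixturePath(), colClasses = "character")[1, ]
  toy$di_onset <- toy$hl_onset <- toy$oa_onset <- "Not Diagnosed"
  toy$hl_onset <- "Normal"
  toy$dm_onset <- "5.0"
  f1 <- firstSymptomCounts(loadCohort(toy))
  expect_equal(f1$first[["DM"]], 1)
  expect_equal(sum(f1$first), 1)
  # exact tie -> both counted and flagged
  toy$hl_onset <- "5.0"
  f2 <- firstSymptomCounts(loadCohort(toy))
  expect_equal(f2$first[["DM"]], 1)
  expect_equal(f2$first[["HL"]], 1)
  expect_equal(f2$n_tied_first, 1)
})

test_that("first symptoms are unique per patient when onsets are distinct", {
  set.seed(3)
  base <- read.csv(cohortFixturePath(), colClasses = "character")[1:8, ]
  for (col in c("dm_onset", "di_onset", "hl_onset", "oa_onset"))
    base[[col]] <- as.character(round(runif(8, 1, 20), 1))
  # force distinctness within rows
  m <- matrix(round(runif(32, 1, 30), 1), 8, 4)
  m <- t(apply(m, 1, function(r) r + cumsum(c(0, rep(0.1, 3)))))
  base$dm_onset <- as.character(m[, 1]); base$di_onset <- as.character(m[, 2])
  base$hl_onset <- as.character(m[, 3]); base$oa_onset <- as.character(m[, 4])
  fs <- firstSymptomCounts(loadCohort(base))
  expect_equal(sum(fs$first), 8)
  expect_equal(fs$n_tied_first, 0)
})

test_that("sex association reproduces the textbook chi-square", {
  co <- loadCohort(cohortFixturePath())
  sa <- sexAssociation(co)
  expect_equal(round(sa$chi_square, 1), 1.2)
  expect_equal(round(sa$p, 2), 0.27)
  # hand formula on the fixture table (M: 12/6, F: 18/4)
  expect_equal(sa$chi_square,
               40 * (12 * 4 - 6 * 18)^2 / (18 * 22 * 30 * 10),
               tolerance = 1e-12)
  # property: matches n(ad-bc)^2/((a+b)(c+d)(a+c)(b+d)) on random tables
  set.seed(5)
  for (i in 1:25) {
    tab <- matrix(sample(1:30, 4, replace = TRUE), 2)
    n <- sum(tab)
    expect_equal(unname(suppressWarnings(
      stats::chisq.test(tab, correct = FALSE)$statistic)),
      n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
        (sum(tab[1, ]) * sum(tab[2, ]) * sum(tab[, 1]) * sum(tab[, 2])),
      tolerance = 1e-9)
  }
})

test_that("degenerate 2x2 tables are handled", {
  toy <- read.csv(cohortFixturePath(), colClasses = "character")[1:4, ]
  toy$sex <- c("M", "M", "M", "M")
  expect_true(is.na(sexAssociation(loadCohort(toy))$chi_square))
})

test_that("exclusion rules drop flagged ears, implants and late sessions", {
  co <- loadCohort(cohortFixturePath())
  # 6 sessions -> 5 retained
  rows <- patientRows("WFS_02", ages = 10 + 0:5)
  ex <- applyExclusions(rows, co)
  expect_equal(sort(unique(ex$kept$session_index)), 1:5)
  expect_true(all(ex$exclusions$reason == "session_index_gt_5"))
  # no flags, 3 sessions -> all retained
  rows <- patientRows("WFS_02", ages = 10 + 0:2)
  ex <- applyExclusions(rows, co)
  expect_equal(nrow(ex$exclusions), 0)
  expect_equal(nrow(ex$kept), nrow(rows))
  # conductive flag on one ear only -> that ear dropped, other kept
  rows <- rbind(earRows("WFS_02", 10, 1, "left", rep(10, 6), conductive = 1),
                earRows("WFS_02", 10, 1, "right", rep(10, 6)))
  ex <- applyExclusions(rows, co)
  expect_equal(unique(ex$kept$ear), "right")
  expect_equal(ex$exclusions$reason, "conductive_component")
  # implant patients dropped entirely
  rows <- patientRows("WFS_05", ages = c(10, 11))
  ex <- applyExclusions(rows, co)
  expect_equal(nrow(ex$kept), 0)
  expect_true(all(ex$exclusions$reason == "cochlear_implant"))
  # invalid audiogram dropped
  rows <- rbind(earRows("WFS_02", 10, 1, "left", rep(10, 6), invalid = 1),
                earRows("WFS_02", 10, 1, "right", rep(10, 6)))
  ex <- applyExclusions(rows, co)
  expect_equal(unique(ex$kept$ear), "right")
})

test_that("cohort summary assembles consistent category counts", {
  co <- loadCohort(cohortFixturePath())
  cs <- cohortSummary(co)
  expect_equal(unname(sum(cs$hearing_status)), cs$n)
  expect_equal(cs$hl_by_age3, 6)
  expect_equal(round(cs$enrollment_age$mean, 1), 13.5)
  expect_equal(round(cs$enrollment_age$sd, 1), 5.6)
  for (s in c("DM", "DI", "HL", "OA"))
    expect_true(cs$symptoms[[s]]$prevalence >= 0 &&
                  cs$symptoms[[s]]$prevalence <= 1)
})
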