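test_that("audiogram construction enforces the measurement invariants", {
  expect_s3_class(makeEar(c(10, 10, 15, 20, 40, NA)), "ear_audiogram")
  # 5-dB step
  expect_error(makeEar(c(10, 12, 15, 20, 40, 50)), "multiples of 5")
  # range
  expect_error(makeEar(c(10, 10, 15, 20, 40, 125)), "-10, 120")
  # all octaves required
  expect_error(earAudiogram("left", c(`250` = 10, `500` = 10, `1000` = 10,
                                      `2000` = 10, `4000` = 10)),
               "8000 Hz")
  # unsupported frequency
  expect_error(earAudiogram("left", c(`250` = 10, `500` = 10, `1000` = 10,
                                      `2000` = 10, `4000` = 10, `8000` = 10,
                                      `9000` = 10)),
               "unsupported")
})

test_that("pta averages 500/1000/2000 Hz and substitutes no-response", {
  expect_equal(as.numeric(pta(makeEar(c(0, 10, 10, 10, 50, 60)))), 10)
  expect_equal(as.numeric(pta(makeEar(c(0, 20, 25, 30, 50, 60)))), 25)
  expect_equal(as.numeric(pta(makeEar(c(0, 80, 85, 90, 95, 100)))), 85)
  # no-response at a PTA frequency -> 95 substitution, flagged
  p <- pta(makeEar(c(0, NA, 85, 90, 95, 100)))
  expect_equal(as.numeric(p), (95 + 85 + 90) / 3)
  expect_equal(attr(p, "substituted"), 500)
})

test_that("hfa averages 4 and 8 kHz with the 95 dB no-response rule", {
  expect_equal(as.numeric(hfa(makeEar(c(0, 0, 0, 0, 40, 60)))), 50)
  expect_equal(as.numeric(hfa(makeEar(c(0, 0, 0, 0, 70, NA)))), 82.5)
  expect_equal(as.numeric(hfa(makeEar(c(-5, -5, -5, -5, -5, -5)))), -5)
  h <- hfa(makeEar(c(0, 0, 0, 0, NA, NA)))
  expect_equal(as.numeric(h), 95)
  expect_equal(attr(h, "substituted"), c(4000, 8000))
})

test_that("hearing classification follows the PTA / frequency-count rule", {
  expect_equal(classifyHearing(makeEar(rep(10, 6)))$category, "normal")
  # only 8 kHz above 20 -> still normal
  expect_equal(classifyHearing(makeEar(c(10, 10, 10, 10, 10, 25)))$category,
               "normal")
  # PTA 15 but three frequencies above 20 -> loss
  cl <- classifyHearing(makeEar(c(15, 15, 15, 25, 25, 25)))
  expect_equal(cl$category, "hearing_loss")
  expect_false(cl$profound)
  # PTA boundary: exactly 20 is normal, > 20 abnormal
  expect_equal(classifyHearing(makeEar(c(10, 20, 20, 20, 10, 10)))$category,
               "normal")
  expect_equal(classifyHearing(makeEar(c(10, 20, 20, 25, 10, 10)))$category,
               "hearing_loss")
  # profound at PTA >= 80
  expect_true(classifyHearing(makeEar(c(70, 80, 85, 90, 95, 100)))$profound)
  # no-response counts as above 20
  expect_equal(classifyHearing(makeEar(c(10, 10, 10, NA, NA, NA)))$category,
               "hearing_loss")
  expect_error(classifyHearing(makeEar(rep(10, 6), invalid = TRUE)),
               class = "wfshear_invalid_audiogram")
})

test_that("classification agrees with brute force over a level grid", {
  # independent re-implementation: direct transcription of the rule
  brute <- function(lv) {
    p <- mean(lv[2:4])
    if (p > 20 || sum(lv > 20) > 2) "hearing_loss" else "normal"
  }
  grid <- c(0, 15, 25, 85)
  set.seed(42)
  for (i in 1:250) {
    lv <- sample(grid, 6, replace = TRUE)
    expect_equal(classifyHearing(makeEar(lv))$category, brute(lv),
                 info = paste(lv, collapse = "/"))
  }
})

test_that("band audibility is a clipped linear ramp", {
  k <- siiConstants()
  expect_equal(bandAudibility(35, 50, k), 1)     # threshold = level - 15
  expect_equal(bandAudibility(65, 50, k), 0)     # threshold = level + 15
  expect_equal(bandAudibility(50, 50, k), 0.5)   # midpoint
  expect_equal(bandAudibility(NA, 50, k), 0)     # no response
  # monotone non-increasing in threshold
  th <- seq(-10, 120, by = 5)
  a <- bandAudibility(th, 45, k)
  expect_true(all(diff(a) <= 0))
})

test_that("unaided SII hits its boundary constructions", {
  k <- siiConstants()
  # all thresholds at -10: every band fully audible for L_i >= 5
  expect_equal(siiUnaided(makeEar(rep(-10, 6)), k), 1)
  # thresholds exactly at band levels -> every audibility 0.5
  e <- makeEar(c(45, 50, 45, 40, 35, 30))  # quantized near band levels
  k2 <- siiConstants(band_speech_level = c(45, 50, 45, 40, 35, 30))
  expect_equal(siiUnaided(e, k2), 0.5)
  # all no-response -> 0
  expect_equal(siiUnaided(makeEar(rep(NA_real_, 6)), k), 0)
  # weights that do not sum to 1 are refused
  expect_error(siiConstants(importance = rep(0.2, 6)), "sum to 1",
               class = "wfshear_config")
})

test_that("SII is monotone non-increasing in every threshold", {
  k <- siiConstants()
  set.seed(7)
  for (i in 1:50) {
    lv <- 5 * sample(-2:20, 6, replace = TRUE)
    s0 <- siiUnaided(makeEar(lv), k)
    j <- sample(6, 1)
    lv2 <- lv
    lv2[j] <- min(lv[j] + 5 * sample(1:4, 1), 120)
    expect_lte(siiUnaided(makeEar(lv2), k), s0 + 1e-12)
  }
})

test_that("PTA and HFA are non-decreasing in contributing thresholds", {
  set.seed(8)
  for (i in 1:50) {
    lv <- 5 * sample(-2:20, 6, replace = TRUE)
    j <- sample(6, 1)
    lv2 <- lv
    lv2[j] <- min(lv[j] + 5, 120)
    expect_gte(as.numeric(pta(makeEar(lv2))), as.numeric(pta(makeEar(lv))))
    expect_gte(as.numeric(hfa(makeEar(lv2))), as.numeric(hfa(makeEar(lv))))
  }
})

test_that("ear ranking uses SII, then HFA, then PTA, then convention", {
  k <- siiConstants()
  ses <- function(l, r) audiogramSession("P1", 10, 1,
                                         makeEar(l, "left"),
                                         makeEar(r, "right"))
  # clear SII difference
  rk <- rankEars(ses(c(60, 60, 60, 60, 60, 60), rep(0, 6)), k)
  expect_equal(rk$worse_side, "left")
  expect_equal(rk$tie_broken_by, "sii")
  # equal SII (both fully audible), HFA decides: left 60 vs right 45
  rk <- rankEars(ses(c(-10, -10, -10, -10, 10, 110),
                     c(-10, -10, -10, -10, 0, 90)), k)
  expect_equal(siiUnaided(makeEar(c(-10, -10, -10, -10, 10, 110)), k),
               siiUnaided(makeEar(c(-10, -10, -10, -10, 0, 90)), k))
  expect_equal(rk$worse_side, "left")
  expect_equal(rk$tie_broken_by, "hfa")
  # full tie -> left by convention
  rk <- rankEars(ses(rep(0, 6), rep(0, 6)), k)
  expect_equal(rk$worse_side, "left")
  expect_equal(rk$tie_broken_by, "convention")
  # invalid ear -> refusal
  expect_error(rankEars(audiogramSession("P1", 10, 1,
                                         makeEar(rep(0, 6), "left",
                                                 invalid = TRUE),
                                         makeEar(rep(0, 6), "right")), k),
               class = "wfshear_invalid_audiogram")
})

test_that("ear ranking is antisymmetric under left/right swap", {
  k <- siiConstants()
  set.seed(9)
  for (i in 1:30) {
    l <- 5 * sample(0:18, 6, replace = TRUE)
    r <- 5 * sample(0:18, 6, replace = TRUE)
    a <- rankEars(audiogramSession("P", 10, 1, makeEar(l, "left"),
                                   makeEar(r, "right")), k)
    b <- rankEars(audiogramSession("P", 10, 1, makeEar(r, "left"),
                                   makeEar(l, "right")), k)
    if (a$tie_broken_by == "convention") {
      expect_equal(b$worse_side, "left")  # full tie stays left
    } else {
      expect_false(a$worse_side == b$worse_side)
    }
  }
})

test_that("sessionMetrics matches the per-ear object computations", {
  k <- siiConstants()
  set.seed(10)
  rows <- rbind(earRows("A", 10, 1, "left", c(10, 15, 20, 25, 70, NA)),
                earRows("A", 10, 1, "right", c(0, 5, 5, 10, 20, 30)),
                earRows("B", 14, 1, "left", c(15, 15, 15, 25, 25, 25)),
                earRows("B", 14, 1, "right", rep(10, 6)))
  m <- sessionMetrics(rows, k)
  e <- makeEar(c(10, 15, 20, 25, 70, NA))
  i <- which(m$patient_id == "A" & m$ear == "left")
  expect_equal(m$pta[i], as.numeric(pta(e)))
  expect_equal(m$hfa[i], 82.5)
  expect_equal(m$sii[i], siiUnaided(e, k))
  j <- which(m$patient_id == "B" & m$ear == "left")
  expect_equal(m$category[j], "hearing_loss")
  expect_equal(m$category[which(m$patient_id == "B" & m$ear == "right")],
               "normal")
})

test_that("SII constants round-trip through YAML", {
  p <- system.file("extdata", "sii_constants.yaml", package = "wfshear")
  k <- readSiiConstants(p)
  expect_equal(k, siiConstants())
  expect_error(readSiiConstants("/nonexistent.yaml"),
               class = "wfshear_config")
})
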