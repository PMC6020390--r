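# wfshear

Natural-history analysis of sensorineural hearing loss (SNHL) in Wolfram
syndrome and similar rare-disease cohorts: per-ear audiometric metrics,
hearing-loss classification, cohort descriptives, random-slope mixed
models of progression, and simulation-based power / sample-size
calculations for progression-slowing trials — plus a synthetic cohort
generator so the whole pipeline runs and is tested without any patient
data.

## Who it is for

Audiology and rare-disease research groups who collect longitudinal
pure-tone audiograms and need (a) standardized per-ear summaries, (b) an
annual rate of change with honest uncertainty, and (c) a defensible
answer to "how many patients per arm would a trial need?".

## What it computes

**Per-ear metrics** from air-conduction thresholds (dB HL, 5-dB steps,
octaves 250–8000 Hz):

- PTA = mean threshold at 0.5/1/2 kHz; HFA = mean at 4/8 kHz with the
  95 dB HL substitution for no-response at the equipment limit;
- classification: abnormal if PTA > 20 dB HL or more than two measured
  frequencies exceed 20 dB HL; profound if PTA ≥ 80 dB HL;
- unaided Speech Intelligibility Index (octave-band audibility,
  SII = Σᵢ Iᵢ·clip((Lᵢ + 15 − Tᵢ)/30, 0, 1), editable constants file);
- worse/better ear roles (lower SII, ties → HFA → PTA → left).

**Progression model** (per outcome, per ear role), fitted by REML with
Satterthwaite type III F tests:

y_it = β₀ + β₁·t + β₂·age0c + β₃·t·age0c + u₀ᵢ + u₁ᵢ·t + e_it,
 u₁ᵢ ~ N(0, δ²), e_it ~ N(0, ε²)

with t years on study and age0c the baseline age, centered. The reported
"average change over 1 year" is β̂₁ (the slope at mean baseline age).

**Trial power**: simulate two arms (treatment slope = (1−r)·placebo
slope, equal baselines, visits every 6 months for 3 years), test the
treatment-by-time interaction in the matching random-slope model, repeat
`n_sims` times; `sampleSizeSearch()` finds the smallest n per arm with
≥ 80% power on a step-5 grid refined to step 1.

## Worked example

```r
library(wfshear)

# packaged 40-patient symptom table
co <- loadCohort(system.file("extdata", "wfs_cohort.csv", package = "wfshear"))
cohortSummary(co)
#> Cohort of 40 patients (18 M / 22 F), enrollment age 13.5 (SD 5.6)
#>   DM: n = 36, onset 5.6 (SD 2.9), prevalence 90%
#>   DI: n = 24, onset 11.3 (SD 4.2), prevalence 60%
#>   HL: n = 30, onset 8.3 (SD 5.1), prevalence 75%
#>   OA: n = 37, onset 10.0 (SD 4.0), prevalence 92%
#>   first symptom: DM 30, DI 0, HL 7, OA 5
#>   hearing loss by age 3: 6; cochlear implants: 4
#>   sex x SNHL chi-square 1.21 (df 1), p = 0.27
```

So 30/40 patients (75%) have SNHL, diagnosed at 8.3 ± 5.1 years; hearing
loss was the strictly-first symptom for 7 patients; the sex split among
SNHL patients is compatible with chance.

```r
# synthetic longitudinal audiograms -> exclusions -> worse-ear model
g  <- generateCohort(generatorConfig(seed = 42))
ex <- applyExclusions(g$audiograms, loadCohort(g$cohort))
lt <- buildLongTable(ex$kept, loadCohort(g$cohort), "worse")
fit <- fitRandomSlope(lt, "HFA")
fit
#> Random-slope fit: HFA (worse ear), 37 patients, 177 observations
#>   slope 1.322 / year (SE 0.271, df 38.4, p = 1.882e-05, 95% CI 0.774..1.871)
#>   variance components: slope 1.208, intercept 461.306, residual 17.371
estimateAnnualChange(fit)
#> HFA: estimated average change over 1 year = 1.32 dB increase
```

The worse-ear HFA worsens by ~1.3 dB/year in this simulated whole-group
cohort — below the configured 1.77 dB/yr affected-patient slope because
normal-hearing patients and patients whose onset falls inside the
observation window progress less (see the methods vignette).

```r
empiricalPower(trialDesign(40, reduction = 0.5),
               simParams(1.77, 1, 3.5, baseline_mean = 40, n_sims = 200, seed = 7))
#> Empirical power 0.705 (MC SE 0.032) from 200/200 converged trials
#>   design: n = 40/arm, 7 visits over 3.0 y, reduction 50%, alpha 0.05
```

40 patients per arm gives ~70% power to detect a 50% slowing of a
1.77 dB/yr progression under these variance parameters — short of the
conventional 80%, which is what `sampleSizeSearch()` quantifies.

## Layout

- `R/` — metrics, cohort, longitudinal, power, generator, report modules
- `inst/extdata/` — packaged cohort table and SII constants (YAML)
- `vignettes/wfshear-methods.Rmd` — model, assumptions, design choices
- `tests/testthat/` — unit, property and end-to-end tests
- `scripts/acceptance.R` — see above
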