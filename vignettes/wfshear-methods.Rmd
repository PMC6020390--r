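---
title: "Methods: longitudinal audiometric analysis for Wolfram syndrome cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal audiometric analysis for Wolfram syndrome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wfshear)
```

## The problem

Wolfram syndrome (WFS1/CISD2) is a rare autosomal recessive disorder whose
cardinal symptoms are diabetes mellitus (DM), diabetes insipidus (DI),
optic nerve atrophy (OA) and sensorineural hearing loss (SNHL). SNHL in
this population is typically high-frequency and slowly progressive, which
raises two practical questions for natural-history studies and trial
design: *how fast do standard audiometric measures change per year*, and
*how many patients would a two-arm trial need to detect a meaningful
slowing of that change*? `wfshear` implements the full analysis chain for
these questions — per-ear audiometric metrics, hearing-loss
classification, cohort descriptives, random-slope mixed models, and a
simulation-based power/sample-size procedure — together with a synthetic
cohort generator so that every stage is testable without patient data.

## Audiometric metrics

Air-conduction thresholds are recorded in dB HL on a 5-dB grid at the
octave frequencies 250–8000 Hz (inter-octaves optional). A threshold that
cannot be obtained at the equipment limit is recorded as *no response*.

* **PTA** — mean threshold at 500, 1000 and 2000 Hz.
* **HFA** — mean threshold at 4000 and 8000 Hz. No response at 8 kHz is
  replaced by 95 dB HL; the same substitution is applied at any other
  frequency that needs one (and recorded in the result's `substituted`
  attribute), so severe losses remain comparable rather than dropping
  out.
* **Classification** — hearing is abnormal when PTA > 20 dB HL *or* more
  than two measured frequencies exceed 20 dB HL (no response counts as
  exceeding); profound when PTA ≥ 80 dB HL. The frequency count runs
  over everything actually measured, because inter-octaves are only
  tested conditionally in the clinic and counting what exists is the only
  self-consistent rule. An isolated elevated 8 kHz threshold therefore
  does not reclassify an otherwise normal ear.
* **Unaided SII** — the proportion of average-vocal-effort speech
  information audible from pure tones alone:
  $\mathrm{SII} = \sum_i I_i \,\mathrm{clip}\!\left(\frac{L_i + 15 - T_i}{30},\, 0,\, 1\right)$
  over octave bands, with importance weights $I_i$ (summing to 1), band
  speech levels $L_i$ in dB HL, a +15 dB peak offset and a 30 dB dynamic
  range. Clinical devices implement proprietary variants of the standard
  octave-band calculation, so the constants ship as an editable YAML file
  (`inst/extdata/sii_constants.yaml`); agreement with any particular
  device cannot be asserted and is not assumed anywhere. No-response
  bands contribute zero audibility. SII is a proportion internally and an
  integer percentage in reports.

## Ear roles

Analyses run separately for each patient's *worse* and *better* ear. The
worse ear is the one with the lower unaided SII; ties fall back to the
higher HFA, then the higher PTA, and a completely tied pair designates
the left ear (any fixed convention works; it only needs to be
deterministic and documented).

Two design points deserve emphasis:

1. **One assignment per patient.** The ear role is fixed per patient, not
   re-ranked session by session — re-ranking would splice different
   physical ears into one trajectory.
2. **The assignment averages the SII over all analyzed sessions** rather
   than ranking a single (e.g. the first) session. Ranking on one
   session selects, in part, on that session's measurement error, and
   because the same session then anchors the trajectory, regression to
   the mean biases the worse-ear slope downward. With the package's
   default noise level this bias was measured at roughly −0.12 dB/yr —
   about 7% of the HFA progression rate — while averaging removes it
   exactly: equal per-session selection weights are orthogonal to the
   slope contrast (whose weights sum to zero), so selection and slope
   error are uncorrelated. The single-session ranking remains available
   as `rankEars()` for session-level reporting.

## Cohort descriptives

`loadCohort()` reads a one-row-per-patient symptom table whose onset
cells are ages or the tokens `Normal` / `Not Diagnosed` / `No dx`
(case-insensitive). Conventions, each chosen to reproduce the standard
descriptive quantities exactly:

* onset means/SDs use diagnosed patients only, with the sample (n−1) SD;
* prevalence counts cochlear-implant patients as diagnosed (their onsets
  are known even though their ears cannot be tested);
* a symptom is a patient's *first* when its onset is strictly earliest;
  exact ties co-count and are flagged. Second symptoms use the same
  strict ordering but are reported as raw counts only;
* the sex-by-SNHL association is the Pearson chi-square *without*
  continuity correction (df = 1) — the corrected statistic gives a
  visibly different value on small 2×2 tables;
* exclusion rules for modelling: conductive ears, invalid audiograms,
  implanted patients, and sessions beyond the fifth visit (sixth-year
  observations are too sparse to support the model), all logged with
  reasons.

## The random-slope model

For outcome $y$ (HFA, PTA in dB; SII in percentage points) of patient
$i$ at time $t$ (years since the patient's first analyzed session):

$$y_{it} = \beta_0 + \beta_1 t + \beta_2 a_i + \beta_3 t a_i
  (+ \text{sex terms}) + u_{0i} + u_{1i} t + e_{it}$$

with $a_i$ the age at first session centered at the sample mean (one
value per patient, so visit counts do not reweight the centering),
$u_{1i} \sim N(0, \delta^2)$ the patient random slope, an optional
independent random intercept $u_{0i} \sim N(0, \tau^2)$, and
homoscedastic error $e_{it} \sim N(0, \varepsilon^2)$. Estimation is
REML via `lme4`, with type III F tests and Satterthwaite denominator
degrees of freedom via `lmerTest` (the residual-df Wald test is the
documented fallback in the trial analysis). If the
intercept-plus-slope covariance fails to converge, the fit falls back to
the pure random-slope covariance and says so.

The random intercept is included by default: audiograms start from very
different severities, and the intercept absorbs that heterogeneity. The
power module's generating model deliberately omits it (baseline means
are equal by design in a randomized trial), and its analysis model uses
the matching pure random-slope covariance.

**Annual change** is reported as $\hat\beta_1$ from the age-centered
interaction model — the average slope at the mean baseline age. This
choice (rather than a time-only model) keeps the headline rate
consistent with the interaction inference reported next to it; the
no-interaction model is available via `include_interaction = FALSE`, and
the two agree when the true interaction is null (property-tested).
Direction labels follow the clinical convention: HFA/PTA worsen upward
("dB increase"), SII worsens downward ("decrease").

## Power and sample size by simulation

For a two-arm trial measuring the outcome every six months over three
years (visits 0, 0.5, …, 3.0):

1. per subject, a slope $\beta_g + N(0, \delta^2)$ with
   $\beta_{\text{treatment}} = (1-r)\,\beta_{\text{placebo}}$, equal
   baselines, and visit-level noise $N(0, \varepsilon^2)$;
2. each simulated trial is analyzed by the mixed model
   `y ~ time * arm + (0 + time | subject)` and the treatment-by-time
   coefficient tested two-sided at $\alpha = 0.05$;
3. empirical power is the rejection proportion over `n_sims` trials
   (non-converged replicates are excluded from the denominator and
   reported);
4. `sampleSizeSearch()` walks n per arm up a step-5 grid until the
   target power (80%) is reached, then refines by step 1 just below the
   boundary, returning the full power-vs-n trace.

Seeding: one master seed spawns one L'Ecuyer-CMRG substream per
replicate (`parallel::nextRNGStream`), so results are byte-reproducible
and independent of replicate order; each grid point in the search
derives its own seed deterministically from the master seed and n.

The analytic cross-check: with $\delta = 0$ and known $\varepsilon$, the
per-subject OLS slope has variance $\varepsilon^2 / \sum_j (t_j -
\bar t)^2$ and the arm comparison is a two-sample z test whose power is
closed-form (`analyticSlopePower()`). The Monte-Carlo machinery is
required to agree with it within Monte-Carlo error; the mixed model is
very slightly more powerful than the per-subject test at small n, which
is visible but stays inside three Monte-Carlo SEs at the problem sizes
used.

Published sample sizes for any particular cohort depend on that cohort's
estimated $\delta^2$ and $\varepsilon^2$, which are not recoverable from
summary tables; the package therefore treats the *procedure* (null
calibration, monotonicity in n and r, agreement with the analytic
oracle) as the testable surface and demonstrates it on its own default
parameters ($\beta = 1.77$ dB/yr, $\delta = 1.0$, $\varepsilon = 3.5$).

## The synthetic cohort generator

`generateCohort()` emulates the statistical structure the analysis
assumes, not any real patient:

* enrollment ages $N(13.5, 5.6^2)$ truncated to 5–26 years; 45% male;
* per-symptom onset ages (years): DM $N(5.6, 2.9^2)$, DI $N(11.3,
  4.2^2)$, HL $N(8.3, 5.1^2)$, OA $N(10.0, 4.0^2)$, truncated below at
  0.3, with not-diagnosed probabilities 0.10 / 0.40 / 0.25 / 0.075 — so
  the expected hearing-loss prevalence is 75%;
* thresholds
  $T = \text{baseline}_f + \text{slope}_f\,(age - onset)_+ + (b_i + v_{ie})\,t + e$,
  quantized to 5 dB, floored at −10, censored into no-response above the
  115 dB HL equipment ceiling. Baselines at diagnosis rise with
  frequency (12–34 dB HL) because the loss is high-frequency first;
  slopes are high-frequency dominant (0.10–0.30 dB/yr below 2 kHz, 1.54
  and 2.00 dB/yr at 4 and 8 kHz, so the generating worse-ear HFA slope
  is 1.77 dB/yr); the shared patient random slope has SD 1.0 dB/yr, ear
  asymmetry SDs are 4 dB (baseline) and 0.2 dB/yr (slope), and
  test-retest noise is 5 dB per threshold — a standard clinical figure;
* onset at or by age 3 produces the severe early phenotype (+55 dB
  baseline offset) and a cochlear implant with probability 0.8; implanted
  patients contribute no audiograms;
* up to six annual visits (attendance 0.85 after the first, ±0.05 y
  jitter), 1% conductive ear-sessions, 0.3% invalid audiograms.

Session-1 distributions under these defaults land in the vicinity of a
worse-ear HFA around 39 ± 26 dB — used as a soft plausibility check
only, never asserted as an equality.

Progression is piecewise-linear in age (flat before onset) but linear in
study time for patients affected before enrollment, which is what the
analysis model assumes. Because patients whose onset falls *inside* the
observation window progress for only part of it, the population mean
in-study slope under the default config is below the configured 1.77;
parameter-recovery studies therefore use `recoveryConfig()` — 35
patients, hearing loss onset forced at or before enrollment, at most
five visits — under which the generating worse-ear slope is exactly the
configured 1.77 dB/yr and `recoveryHarness()` checks bias, RMSE and
95%-CI coverage of the full pipeline (metrics → exclusions → ear roles →
fit).

What the generator does **not** emulate: bone conduction, tympanometric
traces, speech-in-noise scores, correlated symptom onsets, non-linear or
plateauing trajectories, and informative missingness (attendance is
completely at random). Passing recovery tests therefore shows the
estimator chain is unbiased *under the model's own assumptions*, not
that real trajectories are linear.

## Numerical choices and degenerate inputs

* 5-dB quantization is unbiased for slopes (rounding noise is symmetric
  and time-independent); the quantized-vs-continuous recovery difference
  is property-tested to stay far below the 5-dB step per decade. The
  generator can emit un-quantized tables (marked `continuous`) for
  exactly this comparison.
* Ties: SII ear ties fall through HFA → PTA → left; co-first symptoms
  are each counted and flagged; classification uses strict `>` at every
  20-dB comparison and `>= 3` for the frequency count.
* Degenerate fits are refused with typed conditions: fewer than two
  patients with two time points, single-visit trial tables, zero-margin
  2×2 tables, invalid audiograms in ranking.
* Effectively noise-free fits (residual variance → 0) are exercised in
  tests with a small positive ε, since REML on exactly-zero residual
  variance is degenerate.
* Reports round once, in one place (`fmtDb()`, `fmtSiiPct()`): 1 decimal
  for dB, integer percent for SII. The JSON bundle always carries the
  unrounded values.

## Problem sizes used by the test suite

The packaged checks run, as the package's own choice of demonstration
size: slope recovery on 200 replicate cohorts of 35 patients; type-I
calibration on 500 simulated null trials (n = 20/arm); power
monotonicity at n = 20/40/80 with 300 simulations each; sample-size
searches at 200 simulations per grid point; prevalence calibration over
40 generator seeds. At these sizes the Monte-Carlo SEs are small enough
that each assertion's tolerance (stated inline in the tests) is
meaningful.

## Known limitations

* The SII constants are a documented, editable approximation of the
  octave-band standard; device-specific transfer functions are unknown.
* Satterthwaite df are an approximation to whatever df method any other
  mixed-model software uses; exact F statistics from other
  implementations will differ slightly.
* The sample-size search inherits Monte-Carlo noise near the power
  boundary; with 200 simulations per grid point the reported n can
  wobble by a few patients between seeds (the trace makes this visible).
* Sibship clustering is recorded but not modelled.
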