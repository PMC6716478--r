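---
title: "Methods: inhaler adherence, symptom episodes, and EMA mixed models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inhaler adherence, symptom episodes, and EMA mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adhema)
```

## The analysis problem

Smartphone asthma monitoring produces three irregular data streams per
participant: timestamped inhaler actuations from a Bluetooth cap (with a
manual-entry fallback when the cap has not synced), short daily
ecological momentary assessment (EMA) questionnaires — eight items on a
4-point Likert scale (0 "Not at all" to 3 "Extremely") covering cough,
wheeze, chest tightness, stress, anger, boredom, happiness and
relaxation — and a per-participant controller regimen. `adhema` turns
these streams into participant-day records and answers three questions:
how adherent was the cohort to its preventive (controller) medication,
when did new asthma symptom episodes occur, and do daily symptoms and
mood shift the same day's adherence?

## Event deduplication

A manual entry can duplicate a device record of the same actuation once
the cap syncs. We cancel, per participant and medication, manual entries
against device events whose timestamps agree within a tolerance (60 min
by default, `study_config(dedup_tolerance_minutes=)`). Each device event
cancels at most one manual entry, device events are never removed, and
among all feasible pairings we take the one cancelling the most manual
entries, breaking ties by the smallest total timestamp discrepancy. For
points on a time line such an optimal pairing can always be chosen
non-crossing, so it is computed exactly by a quadratic dynamic programme
rather than a heuristic; for the common case — one stray manual entry
near one device event — it reduces to "cancel the nearest". Removed
entries are kept in an audit log attached to the result.

One consequence worth knowing: deduplication is a single-pass operation.
If two manual entries both sit within tolerance of one device event, one
pass cancels exactly one of them (the device event records one
actuation); re-running deduplication on its own output could cancel the
second. The pipeline therefore applies it exactly once, and the
idempotence we guarantee — and test — is over the duplicate structure
the devices actually produce, where each manual entry shadows a distinct
actuation.

## Windowed, capped adherence

Adherence is computed against the prescribed regimen in two half-day
windows of local clock time, AM `[00:00, 12:00)` and PM `[12:00, 24:00)`
(half-open, so 11:59 is AM and 12:00 exactly is PM), as

$$a_w = \frac{\min(\text{taken}_w,\ \text{prescribed}_w)}{\text{prescribed}_w},$$

undefined when nothing is prescribed in the window. The cap is the guard
against overdosing and medication dumping: a burst of actuations —
including the device buffer's worst case of 400 events — can never raise
a window above 1. Daily adherence is the mean of the defined window
adherences, not a pooled dose count, so an AM double-dose cannot mask a
missed PM dose. Cohort adherence is the unweighted mean over all
participant-days with a defined value. Timestamps are treated as civil
wall-clock time throughout; no timezone arithmetic is applied, because
the windows are defined by the clock on the wall where the participant
is. Rescue-medication events are ingested and count as "any data" for
acquisition, but never enter adherence, which is controller-only.
Enrollment day (study day 0) and the final day are both included in the
denominators; both choices are configurable.

## Symptom days and new episodes

A participant-day is an asthma-symptom day when any report that day
endorses cough, wheeze or chest tightness at or above a threshold
(default Likert 1, "A little"; in practice these items rarely exceed "A
little" in high-risk pediatric cohorts, which the default reflects).
Same-day reports are merged by per-item maximum. Days without a report
carry an undefined flag, never `FALSE`: absence of a report is not
evidence of absence of symptoms.

A new symptom episode opens at a symptom report that (1) falls at least
7 days post-enrollment (configurable,
`study_config(initial_exacerbation_days=)`) and (2) is separated from
any earlier symptoms by at least one intervening non-symptom report.
Consecutive symptom reports with no intervening clear report belong to
one episode. Symptoms contiguous from enrollment form the initial
exacerbation, which is never counted as an episode; it ends at the first
non-symptom report, however long it has run. Two boundary decisions were
genuinely open and are resolved as follows. A first-ever report that is
already symptomatic at day 7 or later opens nothing — criterion (2)
demands an interim clear report, and with no prior report of any kind
the onset cannot be placed; such participants are flagged
`indeterminate_onset`. And if enrollment-contiguous symptoms persist
past day 7 without a clear report, they remain the initial exacerbation
until the first clear report, after which the next symptom report can
open an episode. The detector is a single forward scan with two state
bits; its agreement with a direct run-based reading of the definition is
verified exhaustively over all $3^{12}$ report sequences of length 12.

## The adherence mixed models

For each questionnaire item we fit a linear mixed model on
participant-days with defined adherence and an EMA report:

$$y_{ij} = \beta_0 + \beta_t\, d_{ij} + \sum_{\ell} \beta_\ell\,
\mathbf{1}[x_{ij} = \ell] + b_i + \varepsilon_{ij},$$

where $y_{ij}$ is daily adherence on the 0–100 scale, $d_{ij}$ the study
day (a linear time trend capturing drift over the study), $x_{ij}$ the
item's merged Likert level, $b_i \sim N(0, \sigma_b^2)$ a participant
random intercept and $\varepsilon_{ij} \sim N(0, \sigma^2)$. Estimation
is by REML (`lme4::lmer`), intervals are Wald 95%
($\hat\beta \pm 1.96\,\mathrm{SE}$), p-values normal-theory. Reference
levels follow the questionnaire's anchors: "Not at all" for the symptom
and negative-mood items, "Extremely" for happy and relaxed, so each
coefficient reads as the percentage-point change in adherence relative
to the item's unremarkable state. Levels never observed are reported as
`N/A` rows rather than dropped. One model is fitted per item (plus a
binary any-symptom model), not one joint model: with a small cohort and
sparse high Likert levels, a joint model would be badly overparameterised,
and per-item models match how such estimates are conventionally tabled.
A Gaussian identity-link model is used because the quantity of interest
is an additive percentage-point change in adherence; the 0–100 outcome
is bounded and the residuals are not truly Gaussian, which Wald
intervals tolerate well at these sizes (their calibration is checked by
simulation, below). Fits with the random-intercept variance at the
boundary proceed with a message rather than failing: a zero
between-participant variance is a legitimate estimate, and in that case
the fixed effects agree with pooled ordinary least squares (a tested
invariant). A single-participant frame or a constant outcome is a
diagnostic error.

Days without a report are excluded from the primary analysis: their
adherence is systematically lower, and folding them into the reference
group would overstate symptom effects. The sensitivity analysis
(`build_model_frame(daily, "impute_nonreport")`) instead keeps them,
imputing every item at its reference anchor so imputed days contribute
only to the baseline. `sensitivity_compare()` places the two fits side
by side and raises a flag when imputation flips an effect's sign or
moves it by more than the report-only standard error — the signature of
missingness that is not ignorable for that item. The companion
diagnostic `nonreport_vs_nonsymptom_comparison()` contrasts mean
adherence on clear-report days against no-report days with a Welch
t-test.

## The synthetic cohort generator

No participant-level data ship with the package, so every stage is
validated against simulated cohorts with known ground truth
(`simulate_cohort()`). The generator's defaults are the study conditions
the package is designed around: 14 participants followed 60 days on a
1+1 twice-daily controller regimen; a marginal per-dose take probability
of 0.30 with a logit-scale participant random effect (SD 0.8) — the
intercept is calibrated by numerical integration so the *population
mean* take probability equals the configured 0.30 exactly, rather than
`plogis(qlogis(0.3))`-style plug-in, which would bias the marginal mean
upward; EMA reports on 20% of days; symptom runs from an episode process
(per-day hazard 0.012, geometric durations with mean 3 days, and a 50%
chance of enrolling mid-exacerbation, reflecting recruitment around
acute-care visits); dosing timestamps uniform in 06:00–10:00 and
18:00–22:00 sub-windows; 5% of taken doses captured only by a manual
entry, and 15% of device-recorded doses shadowed by a duplicate manual
entry jittered by N(0, 5 min); rescue use on 10% of days. Mood items are
i.i.d. categorical with marginals chosen to echo the reporting
frequencies typical of this population (boredom endorsed on roughly half
of reports, stress and anger rarely, happiness and relaxation skewed
high). Enrollment dates are staggered over 90 days so weekday structure
varies across participants.

Two optional mechanisms plant effects for validation studies. An item
effect map adds a per-level shift to the day's take probability (e.g.
boredom level 3 → +0.20), giving day-level adherence structure the
models should recover. An informative-missingness coefficient tilts the
logit of the reporting probability by the day's latent take probability,
generating the "non-report days are low-adherence days" pattern the
sensitivity machinery is built to catch. Note that with no item effects
the latent take probability varies only between participants, and the
participant random intercept absorbs most of that pathway; day-level
informative missingness (item effects plus a reporting link) is what
moves the imputed estimates.

What the generator does not emulate: within-participant habit dynamics
(weekday/weekend dosing patterns, decaying engagement), symptom
reporting outside episode runs (real cohorts report cough far more
often than they have episodes), measurement error in the caps, and any
feedback from symptoms to rescue use. Passing recovery tests therefore
demonstrates that the estimators are correct for data with this
covariance structure, not that real cohorts satisfy it.

## Numerical and validation choices

Validation runs at deliberate problem sizes: episode-detector
equivalence is exhaustive over all $3^{12}$ length-12 report sequences;
adherence is recounted naively on 1,000 random small cohorts;
deduplication is checked against brute-force optimal matching on 500
instances of up to 8 events (the largest size where full enumeration is
comfortable); parameter recovery and interval calibration use 500
replicates of 30 participants × 60 days drawn from the fitted model
itself, where the planted +20-point effect must be recovered with mean
error under 1.5 points and 93–97% empirical coverage; simulator
calibration uses 200 default cohorts, whose mean adherence must sit
within ±0.02 of 0.30 and EMA fraction within ±0.03 of 0.20 (the
replicate standard errors are roughly 0.003 and 0.001, so these bands
test bias, not noise). Degenerate inputs are defined rather than fatal
wherever a definition exists: zero prescribed doses give undefined (not
zero) adherence, an empty comparison group flags the comparison
undefined, an all-reporting cohort returns undefined subgroup tests, and
an empty EMA table degrades the pipeline to its adherence and
acquisition sections.

## Known limitations

Estimates are associations between same-day states, not causal or
lagged effects. Wald intervals carry no small-sample correction; at 14
participants they are mildly anticonservative, which the coverage checks
at 30 participants do not measure. The episode rule is reporting-driven:
sparse reporting merges or hides true episodes (detected counts are
validated as a subset of true runs, with equality under full reporting).
The Likert label mapping, window boundaries and CSV schemas are fixed
conventions of this package, not a device vendor's export format.
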