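---
title: "Sleep and wrist-temperature features from wearable sensor cohorts: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep and wrist-temperature features from wearable sensor cohorts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristfeat)
```

## The problem

Wrist-worn devices such as the GENEActiv record tri-axial acceleration,
skin temperature and ambient light continuously for weeks. In clinical
cohorts — here, people recovering from a stroke or a transient ischemic
attack (TIA) — these passive recordings carry information about sleep,
circadian rhythm and day-to-day behaviour that questionnaires miss.
`wristfeat` implements an analysis pipeline for such cohorts:

1. **Preprocessing** of epoch-level signals: the ENMONZ activity summary,
   stillness-based non-wear detection, valid-day and valid-night filters,
   low-temperature artefact interpolation, quarter-hour averaging and
   moving-average smoothing.
2. **Novel feature extraction**: 19 wrist-temperature features and 8
   sleep features per subject and wear period.
3. **Feature selection**: relevance–redundancy–complementarity (RRCT)
   ranking inside a leave-one-subject-out (LOSO) loop, aggregated with a
   voting scheme and summarized by per-feature stability scores.
4. **Classification**: fold-standardized L2 logistic regression under
   LOSO cross-validation with incrementally added features, and an
   AUC-weighted probabilistic ensemble across feature groups.
5. **Exploration**: a Spearman correlation screen of features against
   questionnaire outcomes (mRS, GAD-7, PHQ-2, modified FQ subscores).

Because no patient-level dataset of this kind is publicly deposited, the
package ships a first-class synthetic cohort generator with known planted
structure; every stage of the pipeline is tested against that ground
truth.

## Preprocessing rules and their parameters

All thresholds live in `wf_config()` and are overridable; the defaults
follow GGIR-style actigraphy conventions.

* **ENMONZ** (`compute_enmonz()`): `max(0, sqrt(x^2+y^2+z^2) - 1)` in
  milli-g. At rest the Euclidean norm equals gravity; sensor noise can
  push it below 1 g, and those negative values are clipped to zero.
* **Non-wear** (`detect_nonwear()`): the recording is split into 15-min
  blocks anchored to clock quarter-hours; each block is classified from
  the 60-min window centred on its midpoint. A block is non-wear when at
  least two of the three axes have a windowed standard deviation below
  13 mg *or* a value range below 50 mg. Windows are clipped at the
  recording bounds. Because only dispersion enters, the classifier is
  invariant to constant axis offsets (calibration shifts).
* **Valid days** (`filter_valid_days()`): a calendar day counts when at
  least 16 h of wear is present (the inclusive reading of "16 h"; the
  bound is `valid_day_hours`); a wear period is usable with at least 7
  valid days.
* **Valid nights** (`validate_nights()`): noon-to-noon 24-h windows with
  strictly more than 10% non-wear are excluded from temperature work.
* **Activity imputation** (`impute_nonwear_epochs()`): non-wear epochs on
  valid days get the mean of same-clock-time epochs from other days;
  epochs with no donor stay missing rather than invented.
* **Low temperature** (`impute_low_temperature()`): readings below 24 °C
  are off-wrist artefacts (or cold-water contact) and are linearly
  interpolated between the nearest flanking readings at or above the
  threshold. Leading/trailing runs have no anchor on one side and remain
  missing — extrapolation would fabricate data. The operation is
  idempotent and never emits a value below the threshold.
* **Quarter-hour averaging and smoothing**: temperatures are averaged in
  clock-aligned 15-min bins, then smoothed with a centred moving average
  of window `2q + 1` points (`ma_q = 3`, a 7-point ≈ 1.75 h window). At
  the window edges the mean is taken over the available points so series
  length — and hence the 97-point day and the `4·h + 1`-point night —
  is preserved.

### Window conventions

A *night* is the 19:00 → 14:00 (next day) window; sleep windows are
restricted to it. Sleep onset is rounded *down* and offset *up* to the
quarter hour, and both endpoint bins are included (a closed interval), so
an h-hour sleep yields `4·h + 1` points. A *day* is 08:00 → 08:00, 97
points inclusive. A night enters temperature feature extraction only if
(a) its noon-to-noon window passed the 10% non-wear rule, (b) at least 61
of the 77 possible night-window values are present at or above 24 °C, and
(c) at least 15 points lie between onset and offset; a day needs 77 of
its 97 points. The 61/77 counts are taken at face value as hard
thresholds. Residual missing bins inside an admitted window are linearly
interpolated (flat at the edges) before smoothing.

## The temperature features

For each valid night `i` with smoothed series `x_i`, the per-night
building blocks are the mean `T_i`, standard deviation `S_i`, IQR, the
hours after onset of the in-sleep minimum and maximum (ties broken by
earliest occurrence), the maximum rate of increase (MROI) and decrease
(MROD) over successive 15-min intervals with their timing, and the
normalized approximate entropy `ApEn(x_i)/K_i`. Days contribute the clock
times of the 24-h minimum and maximum, the min–max difference and the
normalized 24-h entropy. The per-period features are means and standard
deviations of these across available nights/days (sd features need at
least two), plus:

* `apen_sleep_all_nights`: ApEn of the concatenation of all valid night
  series divided by the total point count `ΣK_i`;
* `sleep_wake_diff_mean`: over each 48-h span starting at 00:00 on the
  day of sleep onset, mean in-sleep temperature minus mean wake
  temperature.

The average temperature itself is deliberately *not* a feature — it is
dominated by uncontrolled externals such as strap tightness — so every
emitted feature is invariant to adding a constant to the whole recording
(the tests assert this).

**Enumeration choice.** The brief inventory of the temperature group (19
features) and the full mean-and-sd prose description cannot both be
taken literally: expanding every mentioned quantity with both a mean and
an sd yields 22–24 columns. The canonical set returned by default
(`temp_feature_names()`) is the 19-member enumeration that contains every
temperature feature referenced in downstream results (timing sds of the
daily extrema, mean+sd of the in-sleep extremum offsets and of the
MROI/MROD times, the variability summaries, both entropy summaries and
the sleep–wake contrast); the remaining expansions (sd of the normalized
entropies, sd of the sleep–wake difference, per-night entropy mean, and
"hours before waking" aliases, derivable as duration minus the
after-onset value) are available with `extended = TRUE`.

**Timing conventions.** MROI/MROD times are reported in hours after
sleep onset at the *end* of the winning 15-min interval, with the onset
bin at 0 h. The sd of daily extremum times uses plain (not circular)
statistics on hours since the 08:00 window start: the 08:00 anchor keeps
the typical nocturnal extrema far from the wrap point, and a plain
standard deviation stays interpretable as "the time varies by ± so many
hours".

## Approximate entropy

`apen(x, m, r)` follows the classical template construction: embed the
series in vectors of length `m`, count for each template the fraction of
templates within Chebyshev distance `r` — *including the self-match*, so
the count is positive and the logarithm always defined — average the
natural logs to get `phi_m`, and return `phi_m − phi_{m+1}`. Defaults are
`m = 2` and `r = 0.2·sd(x)` (sample sd, denominator `K − 1`); a constant
series returns 0 under the relative tolerance. The natural log is used
(the conventional choice; the defining construction does not fix a
base). Night and day entropies are divided by the series length so longer
sleeps do not mechanically score higher. The implementation is verified
against a literal double-loop transcription of the definition to 1e-12
over a thousand random series.

## Sleep features

From per-night sleep variables (produced by an external sleep-detection
pipeline such as GGIR, or by the generator): the weekend–weekday sleep
duration difference (a night is a weekend night iff its *wake-up* falls
on Saturday or Sunday — the free-day convention of social-jetlag work);
the percentage of nights with onset before midnight (clock time in
[19:00, 24:00)); and the trends of six per-night variables (onset,
offset, SPT duration, daytime sustained-inactivity duration, number of
sleep periods, sleep efficiency), each the Pearson correlation between
the ordinal night index of available nights and the variable — skipped
nights leave gaps rather than renumbering. Onset times are encoded as
hours since 19:00 so pre- and post-midnight onsets are monotone on one
axis. The brief inventory counts this group as 6; the enumerated
description yields 8 (two summary features + six trends). All 8 are
emitted rather than silently dropping two.

## Feature selection and voting

`rrct_rank()` is a greedy forward ranking driven by three
correlation-based terms: relevance of a candidate to the target,
redundancy with the already-selected set, and complementarity — whether
the candidate's first-order partial correlation with the target given a
selected feature exceeds its marginal one. All terms transform absolute
Spearman correlations through the standard normal quantile
`qnorm((1+|ρ|)/2)`, which stretches strong associations apart. The
scoring arithmetic is isolated in one internal function so it can be
revised without touching the loop; its contract is behavioural (an
informative feature ranks first; an exact duplicate of the top feature is
pushed down).

`loso_selection()` repeats the ranking once per held-out subject;
`vote_features()` aggregates: for slot `i`, features are scored by their
occurrences anywhere in the first `i` rank columns across folds, and the
best *not-yet-selected* feature is appended (the obvious reading that
keeps the list full when the leader is already taken). Ties break toward
the earlier column in the canonical feature order. Each selected feature
carries a stability score: the percentage of folds whose ranking contains
it. Voting is invariant to fold order. Demographics (age, sex) are
appended to every feature group before selection so they can compete as
covariates.

## Classification and ensembling

Targets are binary: diagnosis (TIA = 0, stroke = 1) and the stroke
severity group (post-period mRS 0 versus above 0; baseline mRS is never
an input). Models are L2-penalized logistic regressions fit via ridge
`glmnet` with penalty equivalent to inverse-regularization `C = 1`
(`lambda = 1/n`), the common default in the absence of any stated value;
the constant is exposed as `lr_inverse_reg` in `wf_config()`. In each
LOSO fold every feature is standardized by the *training fold's* mean and
sd, applied unchanged to the held-out samples; the per-fold statistics
are stored on the result object so leakage checks can inspect them
directly. `auc_curve()` adds voted features one at a time (the first
model uses only the top feature) up to the 10-feature cap, chosen to
avoid complete separation at small sample sizes. AUC is the Mann–Whitney
rank statistic with average ranks on ties (a constant classifier scores
exactly 0.5); balanced accuracy uses the 0.5 threshold. The ensemble
combines per-group held-out probabilities by a weighted average with each
weight the group's maximum out-of-sample AUC; it is a convex combination,
verified sample-wise in the tests.

A property worth knowing when reading LOSO AUCs at these sample sizes:
pooled held-out probabilities carry a small *pessimistic* bias under the
null, because removing a subject of one class shifts the training class
proportion — and hence the fitted intercept — away from the held-out
label. On permuted labels at the study scale (25 subjects, two periods)
the mean null AUC sits near 0.45–0.46 rather than 0.50. This is a known
behaviour of pooled leave-one-out evaluation, not leakage; the
permutation test in the acceptance suite quantifies it.

## The synthetic cohort generator

`generate_cohort(cohort_spec(...))` produces recordings, sleep windows,
per-night sleep variables, outcomes and a truth table, all deterministic
in the spec's seed. The design aims for the *simplest* model that
exhibits every pattern the features measure — not physiological realism:

* **Temperature**: subject baseline + a 24-h sinusoid (amplitude 1 °C,
  peak 04:00 — distal skin temperature rises at night) + a per-night
  shift making each sleep window's mean equal a planted nightly mean
  drawn with the group's between-night variability + AR(1) noise
  (φ = 0.8) whose stationary sd is scaled by the group's irregularity
  multiplier. Group defaults (`temp_sd_of_mean` 0.725 stroke / 0.820
  TIA °C; `temp_apen_scale` 1.3 / 1.0) plant the directions reported for
  such cohorts: lower day-to-day temperature variability and more
  irregular sleep temperature after stroke.
* **Sleep**: onsets around 23:00 (sd 0.75 h), durations around 7.5 h
  (sd 0.75 h) with a planted +0.5 h weekend bonus, all clipped into the
  19:00–14:00 window; a latent per-period "recovery" factor drives
  correlated drifts of duration, number of sleep periods, efficiency and
  daytime inactivity across nights.
* **Acceleration**: orientation (0, 0, 1) g with per-axis noise — 120 mg
  awake, 20 mg asleep. The asleep level is deliberately *above* the
  13 mg/50 mg stillness thresholds so genuine sleep is never classified
  as non-wear.
* **Non-wear**: episodes (default 0.5/day, mean 90 min, placed in the
  daytime) freeze the accelerometer at its entry value and decay the
  temperature exponentially toward 21 °C ambient with a 12-min time
  constant — a single mechanism that exercises both the stillness rule
  and the 24 °C rule.
* **Outcomes**: questionnaire scores are linear functions of planted
  features plus Gaussian noise, rounded and clipped to their ranges:
  GAD-7 and FQ-specific decrease with a positive sleep-duration trend;
  post-period mRS decreases with the subject's planted temperature
  variability; PHQ-2 exists only at baseline and after period 1. The
  couplings make the expected sign of the exploratory screen analytic.
* **Recording span**: each period covers its full calendar days plus a
  14-h tail so the last night's window is complete; the tail day cannot
  pass the 16-h valid-day rule, so with no non-wear the number of valid
  days equals the number of planted nights exactly.

Epochs are 60 s: every in-scope computation operates at epoch or 15-min
scale, so simulating raw 10–100 Hz accelerometry would add cost without
exercising anything.

`calibrate_group_gap()` converts a desired standardized between-group
difference in the extracted "sd of nightly mean temperature" feature
into the two group levels, using the closed-form sampling sd of an sd
estimate from `n` nights (`σ/sqrt(2(n−1))`) combined with the
per-subject heterogeneity (`temp_sd_jitter`, lognormal sd 0.10). At 21
nights the extracted feature reproduces the realized planted level up to
a small attenuation (roughly 5–15%) caused by the closed rounded window
(boundary bins contain some wake temperature) and smoothing; the
acceptance suite pins this ratio to the 0.75–1.05 band.

**What the generator does not emulate** — and hence what passing tests
cannot show about real data: raw high-frequency accelerometry and
posture; physiologic sleep architecture (stages, awakenings); weather or
seasonal temperature confounds; device calibration drift; informative
missingness (removal correlated with symptoms); and the 323-feature
GGIR output, of which only a small synthetic stand-in (clearly labelled,
with no planted group signal) is provided so multi-group ensembles have
realistic inputs.

## Numerical and degenerate-input choices

* Moving-average edges use partial-window means; `q = 0` is the identity.
* Extrema and rate ties break toward the earliest occurrence.
* A constant series has ApEn 0 under relative tolerance; series shorter
  than `m + 2` are an error, not a silent NA.
* Constant features get zero relevance in RRCT and never block a run; a
  feature column still missing after within-subject imputation is
  dropped, and samples whose sleep-derived features are entirely missing
  are removed.
* Training folds containing a single class abort loudly with the subject
  named — silently skipping folds would bias pooled metrics.
* Spearman p-values use the t approximation (adequate at n ≈ 40); an
  exact permutation p is available via `exact = TRUE` for tiny n. No
  multiple-testing correction is applied in the exploratory screen; the
  report carries the number of tests so readers can correct themselves.
* Problem sizes used by the test-suite experiments: the oracle sweep uses
  1,000 series up to length 200; the null-calibration uses a 25-subject,
  two-period cohort with 200 label permutations; the discrimination
  experiment uses 20 cohorts of 60 subjects × 21 days at a calibrated
  1.5-pooled-sd gap. These sizes give the Monte-Carlo statements useful
  precision while keeping the default test run compact.

## Known limitations

* The RRCT scoring follows the published description of the algorithm;
  where the reference's exact arithmetic differs in detail, the isolated
  scoring function is the single place to change, and the behavioural
  tests define what is guaranteed.
* Clock-time rules are evaluated in the recording's civil time zone and
  the generator uses fixed-offset zones; daylight-saving transitions
  inside a wear period are not modelled.
* The GENEActiv binary format is not parsed; recordings enter as
  delimited text (column dictionary in `read_recording()`).
* Severity labels at a single timepoint per period make the severity
  task sensitive to the mRS dichotomization; only the 0 vs >0 split is
  implemented, on clinical-relevance grounds (no disability versus any).
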