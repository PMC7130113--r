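---
title: "Methods: tactile TOJ simulation and psychometric estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tactile TOJ simulation and psychometric estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tactoj)
```

## The task and the estimands

In a tactile temporal order judgment (TOJ) experiment, two brief vibrations
are delivered, one to each hand, separated by a signed stimulus onset
asynchrony (SOA), and the participant reports which hand was stimulated
first. Two quantities summarise a participant's performance:

* the **point of subjective simultaneity (PSS)**, the SOA at which both
  orders are reported equally often — a shift of the PSS away from zero
  indicates that stimuli on one hand are prioritised in perception; and
* the **just noticeable difference (JND)**, the asynchrony needed for 75%
  correct order discrimination — a measure of temporal sensitivity.

The package implements the full analysis chain used to estimate these
quantities per subject and per arm posture in cohorts of unilateral chronic
pain patients (complex regional pain syndrome, shoulder pain, wrist pain),
together with a generative simulator for the entire experiment, so that the
estimator can be validated by parameter recovery without any empirical data.

## The experimental design

`build_trial_schedule()` constructs the main experiment: 4 blocks of 60
trials; each block presents the ten trial types (SOAs of ±10, ±30, ±55, ±90,
±200 ms; negative = left hand first) exactly six times in random order. Arm
posture (uncrossed vs crossed over the midline) alternates between blocks,
two blocks per posture, with the starting posture counterbalanced across
subjects by alternating it with the subject index. `build_practice_blocks()`
adds the three warm-up blocks (8 localisation trials; 12 and 18 paired
trials restricted to the three largest SOAs, uncrossed then crossed).

Randomisation uses one seed per schedule; within a cohort each subject's
stream is derived as `master seed + subject index`, so cohorts are exactly
reproducible while subjects stay independent. Within-block order is an
unconstrained seeded permutation; we do not forbid immediate repetitions of
a trial type, since nothing in the design requires it.

## The generative observer

`observer()` defines the response model in the *affected frame*: all lead
times are expressed as `u`, the lead of the unaffected hand (`u > 0` means
the unaffected hand was stimulated first). The probability of reporting the
affected hand first is

```
P(affected first | u) = lapse/2 + (1 - lapse) * Phi((pss_true - u) / sigma_p)
```

with `Phi` the standard normal CDF and `sigma_p = sigma` uncrossed or
`sigma * crossed_sigma_factor` crossed. Working in the affected frame makes
the fitted PSS directly interpretable — positive always means the painful
limb's stimuli are prioritised — for either affected side, without any
post-hoc sign flip.

The crossed-hands deficit is modelled purely as a widening of the
psychometric function (`crossed_sigma_factor`, default 2.2). This is the
simplest mechanism that reproduces a posture main effect on the JND of
roughly the magnitude seen in crossed-hands TOJ studies; we deliberately do
not give the lapse rate a posture dependence, because the two are not
separately identifiable from 240 trials.

## Estimation

Per subject and posture, `fit_subject()` chains four steps:

1. `aggregate_proportions()` tabulates the proportion of affected-first
   reports per distinct `u` (10 rows of 12 trials per posture under the
   standard design).
2. `probit_transform()` converts proportions to z-scores via the inverse
   normal CDF. Observed proportions of exactly 0 or 1 have infinite
   probits; the default rule clamps proportions into
   `[1/(2n), 1 - 1/(2n)]`. For count data this only ever changes rows with
   0 or n successes — no achievable interior proportion falls inside the
   clamped band — so it is equivalent to the common "replace 0 and 1"
   correction. The rule is configurable (`clip = "none"` or a numeric
   epsilon).
3. `fit_probit_line()` fits the best-fitting straight line
   `z = intercept + slope * u` by ordinary unweighted least squares
   (`stats::lm`). An unweighted line on probits — rather than a
   maximum-likelihood probit regression — is the estimator this analysis
   tradition uses, and is what the recovery harness validates.
4. `compute_pss()` returns `-intercept/slope`; `compute_jnd()` returns
   `0.675/slope` (signed) and its magnitude. The constant 0.675 is used
   verbatim rather than `qnorm(0.75) = 0.6745`, matching the convention of
   the analysis being reproduced; the two differ by less than 0.1%, which
   the test suite checks against the quartile-crossing formulation. Under
   the affected-frame axis the fitted slope is negative, so signed JNDs
   come out negative; magnitudes are reported alongside.

Because the probit of a cumulative normal is exactly linear, feeding exact
lapse-free model probabilities through steps 2–4 (with `clip = "none"`)
returns `pss_true` and `0.675 * sigma` to machine precision. The test suite
exercises this identity over PSS values up to ±120 ms and sigmas of 80–180
ms, keeping the model z-scores within ±4 at the extreme SOAs: beyond |z| of
about 5 the normal CDF saturates in double precision and the identity is no
longer numerically meaningful.

## Quality control and group statistics

`apply_exclusion()` implements the two a-priori filters: (1) |PSS| must be
below 400 ms (twice the largest SOA); (2) accuracy at the ±200 ms trials
must exceed 60% in *both* postures — a subject-level condition, so failing
it anywhere removes the subject's PSS in both postures. A separate
sensitivity flag marks |JND| ≤ 200 ms for re-analysis. Excluded rows are
kept and flagged, never dropped, so that `exclusion_chi_square()` can
compare the proportion of excluded values between postures with the 2×2
Pearson chi-square *without* continuity correction
(`chi_square_equal_prop()`); with 10 of 45 crossed and 0 of 45 uncrossed
exclusions this statistic is exactly 11.25, which pins down the uncorrected
form. `one_sample_t()`, `paired_t()` and `group_pss_tests()` cover the
group-level location tests (two-sided, alpha = 0.05), and
`t_from_summary()` reconstructs a t statistic from a published mean, 95% CI
and df by inverting the CI — useful for checking printed reports.
`build_analysis_table()` exports the tidy subject × posture table (with
covariates and group-median-imputed temperature differences via
`impute_temperature()`) ready for mixed-model tools; fitting those models
is outside this package's scope.

## The cohort simulator

`cohort_config()` fixes the study conditions: 14 CRPS, 15 shoulder and 16
wrist patients (45 subjects, 10,800 trials), sigma = 100 ms, crossed factor
2.2, lapse 0.02. Subject-level true PSS values follow a linear covariate
model with a random intercept (SD 50 ms):

* temperature difference (affected − unaffected limb, °C) shifts the wrist
  group's PSS by +12.25 ms/°C;
* in the shoulder group the temperature effect interacts with posture
  (−37.69 ms/°C added when crossed);
* pain duration contributes −0.74 ms/month in the wrist group.

Pain durations are log-normal with group means of roughly 10, 24 and 24
months; temperature differences are normal with small positive means; two
CRPS and three wrist subjects have their temperature difference withheld to
exercise the imputation path. These defaults emulate the statistical
structure the analysis assumes — cumulative-normal observers, posture-driven
sensitivity loss, covariate-linked bias — but they are generator choices,
not estimates: the simulator has no claim to the real data's lapse
behaviour, attention drifts, response-time structure or block-order effects,
so passing recovery tests shows the estimator works under its own model
assumptions, not that those assumptions hold empirically.

## The staircase

`match_hands()` reproduces the two-part intensity calibration: part 1
titrates the left hand against a maximum-power reference (0.21 W) on a 1–5
sensation scale; the selected left intensity then anchors part 2's 1–5
"equally strong" comparison for the right hand. Each part interleaves two
staircases (high and low start, 8 trials each) in seeded random order; a
rating above 3 lowers the active staircase one fixed step (10% of maximum
power), below 3 raises it, exactly 3 leaves it, and moves that would leave
`(0, max_power]` are not taken. `select_intensity()` averages ratings per
visited level and linearly interpolates between the two levels bracketing a
mean rating of 3 (an exact hit wins; ties go to the lowest level; with no
bracket the closest level is returned). The update and selection rules are
this package's own concretisation — the original procedure's source is not
fully specified — chosen for determinism: with any deterministic monotone
rating model the selected intensity converges to within one step of the
model's anchor from any admissible start.

## Validation by parameter recovery

`recovery_experiment()` simulates subjects at known parameters under the
standard design and reports bias, Monte-Carlo SE and RMSE of the PSS and
JND-magnitude estimates. Two properties are worth stating plainly:

* At `pss_true = 0` the estimator is unbiased (by the symmetry of the
  design) and the RMSE at sigma = 100 ms with 12 trials per SOA is about
  13–14 ms, falling by roughly 1/sqrt(2) when the repetitions double.
* Away from zero the estimator carries a small *outward* bias: at
  `pss_true = ±50` ms with sigma = 100 ms it is about ±3 ms (6% of the
  true value). The cause is the saturation of the ±200 ms rows: the true
  probability there is ≈0.994, the observed proportion is usually 12/12,
  and the clamped probit (1.73 instead of 2.5) flattens that end of the
  line asymmetrically. A semi-analytic check — fitting the line through the
  exact expected clamped probits — reproduces the effect (plug-in PSS 52.5
  at true 50), and no simple alternative handling of saturated rows
  (dropping them, or smoothed counts) removes it. This is a property of the
  probit-line estimator under this SOA design, not of the implementation;
  analyses that compare PSS values near ±50 ms should expect a few ms of
  attenuation-type distortion, and the acceptance test records this clause
  as failing by design rather than papering over it.

## Problem sizes and runtime choices

The test suite validates the chi-square implementation exhaustively over
all 2×2 tables with margins up to 20, the CI inversion on 1,000 random
datasets, recovery at 500 simulated subjects per condition, and the
crossed-posture JND effect over 200 simulated cohorts (45 subjects × 240
trials each); these sizes give Monte-Carlo errors comfortably below the
effects being checked while keeping a full run in the order of two minutes.

## Known limitations

* The estimator bias away from PSS = 0 described above.
* The simulator draws covariates independently; correlations between pain
  duration, intensity and temperature difference in real cohorts are not
  modelled.
* Lapse rate is generative only; the fitting stage has no asymptote
  parameters, as in the analysis tradition it reproduces.
* The staircase rating model is a convenience for simulation; no claim is
  made about psychophysical validity of linear Likert mappings.
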