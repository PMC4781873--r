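---
title: "Models and methods behind vtdual"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vtdual}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vtdual` simulates and analyses a dual-task psychophysics design that asks
two questions at once: do a visual search task and a tactile localization
task draw on shared or distinct attentional resources, and does attentional
load disturb optimal visuotactile cue integration? This vignette documents
the generative model, the analysis chain, the parameter choices and their
rationale, and what the synthetic cohort can and cannot establish.

## The design being emulated

A session comprises 21 blocks of 10 trials. Each block carries one of seven
conditions: localization alone with visual (`VI`), tactile (`TA`) or
redundant visuotactile (`VITA`) cues; visual search alone (`VS`); and the
three dual combinations. Every run of seven consecutive blocks contains all
seven conditions and no condition repeats across a block boundary
(`block_sequence()` enforces both).

Localization-only trials last 11 s and contain 4–5 location cues: 600-ms
position changes of a central reference toward one of eight equally spaced
directions, with at least 1 s between onsets. Responses are given on the
numeric keypad (8 = top, 6 = right, and so on). Search trials present 20
items of which one is a target on half the trials; the observer inspects
items until the target is found or declares it absent. In dual trials cues
keep arriving for as long as the search runs, and the cue count scales pro
rata with the realized search duration; once the search stops, cue delivery
and the localization task stop with it (we fix this convention rather than
exposing it as an option, since nothing downstream is sensitive to cues a
participant would never answer).

## The synthetic observer

The observer is deliberately minimal: each mechanism exists because some
downstream statistic consumes it, and each has a single interpretable
parameter.

**Angular responses.** The latent direction estimate for a cue is von Mises
around the true direction with concentration $\kappa_m$ per modality,
discretized to the nearest of the eight compass directions (bins of 45°).
A continuous latent plus binning gives one reliability parameter per
modality while producing the discrete 8-alternative responses the keypad
records. `kappa = 0` recovers uniform guessing; `kappa` large recovers
perfect responding.

**Fusion.** In the default `"mle"` mode the visuotactile concentration is
$\kappa_{VI} + \kappa_{TA}$ — precision additivity, the generative analogue
of reliability-weighted maximum-likelihood fusion, under which the fused
variance follows
$\sigma^2_{vt} = \sigma^2_v \sigma^2_t / (\sigma^2_v + \sigma^2_t)$.
Discretization distorts the three variances, but (as the end-to-end tests
verify) the distortions largely cancel in the ratio, so the binned
responses still satisfy the MLE prediction to within sampling error. The
`"pinned"` mode sets the bimodal concentration to
$\max(\kappa_{VI}, \kappa_{TA})$ — the better single cue, no fusion — and
serves as the negative control that the optimality assessment must reject.

**Dual-task costs.** Concurrent search costs detection probability an
additive penalty and concentration a multiplicative factor; both channels
are needed because load affects detection and localization accuracy
separately in this paradigm. Conversely, concurrent localization slows the
search by a per-item time penalty that depends on the localization
modality — the lever that produces modality-dependent interference.

**Search.** Serial self-terminating: per-item inspection times are
exponential with mean `base_item_time_s` plus the dual penalty; a present
target occupies a uniformly random position in the inspection order and is
overlooked with probability `p_miss_target` when inspected. Absent-target
searches exhaust the list, which makes them slower than present-target
searches on average — a structural property, not a tuned one. The task is
known to be serial and self-terminated, but no process-level model of it is
established; the simulator's only obligations are the qualitative orderings
the analysis consumes (present faster than absent; interference ordered by
the per-item penalties).

**Latencies and gaze.** Response latency is lognormal with moment
parameters `rt_mean_s`/`rt_sd_s` (plus a small additive dual-task penalty);
only ordering properties are consumed downstream. Per-trial median gaze
deviation is folded normal with location `gaze_mean_deg` and spread
`gaze_sd_deg`, feeding the one-degree screening test.

### Default parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `p_detect` (VI/TA/VITA) | 0.93 / 0.90 / 0.96 | prob. | high single-task detection; a small redundant-cue benefit, tactile hardest |
| `kappa` (VI/TA) | 8 / 4 | – | visual cues localized more reliably than tactile ones; yields realistic accuracies (~0.75 / ~0.57) and error variances of a few hundred deg² |
| `dual_detect_penalty` | 0.12 | prob. | a large, clearly detectable task effect on detection |
| `dual_kappa_factor` | 0.7 | – | load inflates error variance at both load levels without flooring accuracy |
| `base_item_time_s` | 0.4 | s | ~4 s present / ~8 s absent single-task searches |
| `dual_item_penalty_s` (VI/TA/VITA) | 0.30 / 0.20 / 0.20 | s/item | within-modality competition costs most; tactile and visuotactile cost equally |
| `p_miss_target` | 0.1 | prob. | search accuracy near 0.9–0.95 |
| `rt_mean_s`, `rt_sd_s` | 0.55, 0.15 | s | sub-second keypad latencies |
| `rt_dual_penalty_s` | 0.05 | s | slightly slower responses under load |
| `gaze_mean_deg`, `gaze_sd_deg` | 0.62, 0.15 | deg | median gaze well inside one visual degree |

`sample_observers()` jitters these per subject with multipliers shared
across modalities (a good localizer is good everywhere), preserving
within-subject orderings while giving the repeated-measures subject stratum
genuine variance.

**Seeding.** One master seed; each subject runs on an independent stream
derived by a fixed offset, so cohorts are bit-reproducible and single
subjects can be regenerated in isolation.

## Metrics: conventions and degenerate inputs

- **Hit assignment.** A key press between two consecutive cue onsets is a
  response to the earlier cue; the last cue's window extends to the end of
  the trial's active interval (trial end, or search termination in dual
  trials — no per-cue deadline exists in this design). Only the first press
  per window counts; presses before the first onset or after the active
  interval are discarded and counted.
- **Signed angular error** is clockwise-positive, wrapped to (−180°, 180°];
  exact opposition is +180° by convention so the variance stays
  well-defined. Errors take exactly the values {0, ±45, ±90, ±135, +180}.
- **Error variance** is the `n − 1` sample variance over *all* detected
  cues of a subject × condition cell (correct responses contribute 0°);
  misses are excluded rather than imputed. Cells with fewer than two
  detected cues are flagged missing, never zero-filled.
- **Detection performance** is hits over cues pooled across the cell's
  trials; **localization accuracy** divides correct responses by detected
  cues only (4 cues, 2 hits, 1 correct gives 0.5, not 0.25). Undefined
  cells (zero cues, zero hits) raise errors at the operation level and
  propagate as `NA` with a logged count in the aggregated table.
- **Search times** are summarized by cell medians (robust to the long right
  tail); even counts use midpoint interpolation. **Interference** is the
  dual-task median minus the single-task (`VS`) median, per subject, and
  may be negative. Reaction times for correct localizations are measured
  from cue onset (onset, not offset, is the information-bearing event).
- **Gaze screening** averages per-trial medians per cell and tests each
  search condition against the one-degree threshold, Holm-corrected. If the
  spread is exactly zero the limiting statistic is reported (0 when the
  mean equals the threshold, signed infinity otherwise) instead of failing.

## The inference engine

The ANOVA operates on a complete, balanced subject × cell table (one value
per cell; incomplete tables are rejected with the offending subject named,
since silent dropping changes the estimand).

1. **Normality gate.** A pooled Shapiro–Wilk test on cell-mean-centred
   residuals at α = 0.05; on rejection the dependent variable is
   transformed with the natural logarithm (requiring positive values —
   non-positive values produce an instructive error rather than a silent
   offset). Residual-based testing is the standard reading of "testing the
   dependent variable" for a factorial design.
2. **Sum-of-squares partition.** Classical balanced within-subject
   decomposition from cell and marginal means; each effect is tested
   against its own subject-by-effect stratum. The testthat suite verifies
   the partition against an independent orthogonal-contrast GLM and against
   `car::Anova`/`aov` to at least six significant figures.
3. **Sphericity.** Per effect with more than two levels, Mauchly's W from
   the covariance of orthonormal-contrast scores (sample `n − 1` divisor;
   this is the divisor convention throughout, matching `car`), with the
   chi-square approximation. When Mauchly rejects at α = 0.05, the
   Greenhouse–Geisser correction applies:
   $\hat\varepsilon = \mathrm{tr}(S)^2 / ((k-1)\,\mathrm{tr}(S^2))$,
   clipped to $[1/(k-1), 1]$, multiplying both degrees of freedom.
   Two-level effects are correction-free by construction (W = 1, ε = 1),
   which is why 2-level effects are conventionally reported with integer
   degrees of freedom. Corrected columns are reported for every effect;
   `correction_applied` marks where the conditional rule selects them.
4. **Post-hoc tests** are paired t-tests on marginal means (averaging over
   the other factor, as the omnibus effect does), two-sided, with the set
   of pairwise comparisons reported together forming one Holm family.
   `holm_bonferroni()` delegates to `stats::p.adjust(method = "holm")` and
   is pinned in the tests to a hand-computed step-down fixture.

The optimality report compares observed visuotactile variance with the MLE
prediction per subject and load; the group figure summarises per-subject
predictions with their standard error (rather than predicting from
group-mean variances, which would hide between-subject reliability
differences). The paired t-test of observed versus predicted is an
extension: the classical treatment of this comparison is descriptive, and
the test is labelled accordingly in the output.

## Numerical choices

- Direction binning uses `round(angle / 45)`, so bin edges at 22.5° + k·45°
  round half-to-even; with a continuous latent the edge set has measure
  zero and no bias is introduced.
- Cue onsets are drawn by the uniform-spacing construction (sorted uniforms
  plus mandatory gaps), which samples uniformly from the polytope of
  feasible schedules; infeasible forced counts are rejected with an error.
- The von Mises sampler is the Best–Fisher rejection algorithm with a
  uniform fallback below κ = 1e−10.
- Lognormal latency parameters are derived from the requested mean and SD
  by moment matching.

## Problem sizes and runtime

The test suite and the acceptance script run everything at the design's
native scale — 12 subjects × 21 blocks × 10 trials (≈ 4–5 cues per
localization trial) — which a single CPU simulates in well under a minute.
Property suites use 1,000 schedule draws, 5,000–10,000 simulated cues,
2,000 search trials per condition, and 1,000-replicate null calibrations of
the ANOVA engine; the full suite completes in about two minutes.

## What passing tests do and do not show

The generator produces exactly the statistical structure the analysis
assumes: independent trials, stationary parameters, von Mises angular
noise, exponential item times, no learning, fatigue, or serial dependence,
and congruent bimodal cues only (cue weights are deliberately not estimated
— with congruent cues they are unidentifiable). Recovery of optimal
integration from synthetic cohorts therefore validates the *pipeline* — the
estimators, their conventions, and the inference chain — not any empirical
claim about human observers. Real data in the same long-format schema can
be analysed with the identical chain via `read_trial_table()` and
`run_pipeline()`, and the per-trial event lists make the raw-to-summary
path fully auditable.

Known limitations: no eye-movement dynamics (gaze enters only as per-trial
medians), no vibromotor physics, no training/titration phase (difficulty is
a fixed parameter), and no trial-level mixed-effects modelling — the
analysis aggregates to subject × condition cells before inference, as is
conventional for this design.
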