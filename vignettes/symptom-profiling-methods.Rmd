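---
title: "Symptom profiling from passive sensing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symptom profiling from passive sensing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and rules at each pipeline stage, the parameters that matter and
their defaults, what the synthetic-cohort generator does and does not
emulate, the numerical conventions, and the design choices we made where
the design was genuinely open.

## 1. The pipeline

`run_pipeline()` executes a fixed stage order:

1. **EMA processing** — reliability filter, Speeder-Index filter, daily
   aggregation, per-item linear interpolation, severity classification,
   symptom binarisation.
2. **Sensor processing** — range cleaning, DBSCAN GPS cleaning, gap
   imputation for interval streams, per-participant Box–Cox transforms,
   daily feature extraction, feature pruning.
3. **First-month split** — each participant's first 30 calendar days form
   the profiling window; the rest is the prediction window.
4. **Profiling** — symptom significance vectors (SS) from first-month
   self-reports; nine symptom probability models trained on first-month
   features; symptom heterogeneity vectors (SH) predicted for the
   prediction window; symptom profiles SP = SH ⊙ SS.
5. **Severity classification** — leave-one-subject-out (LOSO) evaluation
   of three-class severity with (a) the pruned sensor features and (b) the
   SP vectors as input, across four model families, with weighted
   multi-class metrics, plus group-averaged profile summaries.

## 2. EMA rules and their conventions

* **Reliability (trap) filter.** The trap question paraphrases PHQ-9
  item 2; a response is voided iff |item2 − trap| **> 1** (strict). A
  one-point discrepancy is ordinary scale wobble and is kept.
* **Speeder Index.** `si = min(1, duration / median)`, the median pooled
  over all responses of all participants. The filter voids responses whose
  `si` falls strictly below the empirical 10% quantile of the `si`
  distribution. We read "10% of the lowest Speeder Index" as a percentile
  rule: the literal alternative (a fixed threshold at 0.1 × the minimum
  index) voids nothing whenever the minimum is attained, so the percentile
  reading is the only operable one. The median is computed once, on the
  reliability-filtered pool, and not recomputed after speeder removal.
* **Daily aggregation.** Per-item arithmetic means over a participant-day;
  the daily total is the sum of the (possibly fractional) item means.
* **Interpolation.** Per item, per participant, linear between observed
  days; no extrapolation beyond a participant's first and last observed
  day (leading/trailing unobserved days are dropped). The interpolated
  total is the sum of the interpolated items, which keeps the
  total/item-sum identity exact on every emitted record. Participants with
  fewer than two observed days cannot be interpolated and are excluded
  with a warning.
* **Severity bands.** Half-open: [0, 10) none/mild, [10, 20) moderate
  (merging the instrument's moderate and moderately-severe bands),
  [20, 27] severe. Exactly 10 → moderate, exactly 20 → severe.
* **Binarisation.** A symptom is present iff its daily score is strictly
  greater than 0. The same strict rule applies to fractional scores from
  averaging or interpolation: any non-zero evidence counts as presence.

## 3. Sensor conventions

* **Ranges.** Durations and counts are non-negative; coordinates must be
  on the globe; per-source bounds live in `field_ranges()`.
* **GPS cleaning.** DBSCAN on (lat, lon) with Euclidean distance in
  degrees, ε = 0.0005 (≈ 55 m at the equator) and
  `min_samples = ceiling(min_stay / cadence)` = 10 for a 2.5 h stay at a
  15-minute cadence, the point itself included. Noise points are removed;
  cluster labels feed the location features. The in-package DBSCAN is an
  exact implementation with a grid index (cells of width ε/√2 make
  same-cell points mutually reachable), validated in the test suite
  against a brute-force O(n²) oracle.
* **Imputation.** Interval-cadence streams get per-field linear
  interpolation of missing ticks between a participant's first and last
  observation; event streams are never imputed, because a missing event
  is indistinguishable from no event. Imputed GPS ticks have no cluster
  label; the location features assign them to the nearest cluster
  centroid within ε, otherwise they count as time at other places.
* **Box–Cox.** Fitted by profile maximum likelihood per participant ×
  source × field on the pooled series (the transform is a property of a
  person's measurement distribution, not of a single day), with a
  `1 − min` shift for non-positive series; λ is searched in [−2, 2] and
  every applied (λ, shift) is recorded. Latitude/longitude are never
  transformed (the location features need raw coordinates); constant
  series are skipped and flagged. The estimator is the closed-form
  profile likelihood of the intercept-only normal model; the test suite
  cross-checks it against the `MASS::boxcox` grid maximum.
* **Daily features.** Duration sources → mean and variance of episode
  durations per day; value sources → mean and variance of measurements;
  quantity sources → cumulative counts; GPS → time at home/work/other
  (dwell time apportioned by inter-sample interval), total travelled and
  maximum-from-home great-circle distance, visited places, displacement
  standard deviation; plus day of week, gender and age group. All
  "variance" columns use the population convention (divide by n). The
  pre-pruning schema is fixed: 68 columns on Android, 34 on iOS
  (`feature_schema()`).
* **Age bands.** ≤ 30, 31–45, ≥ 46; age exactly 30 goes to the first
  band.
* **Home and work.** Home is the cluster holding the most fixes between
  00:00 and 06:00 over the whole period; work is the different cluster
  with the most weekday fixes between 09:00 and 17:00. This is a
  deliberate, simple convention — published location-feature pipelines
  differ in detail here, and we treat the inference rule as an
  approximation rather than a canonical definition.
* **App categories.** The mapping of applications to
  social/finance/media/tools/work/study/lifestyle and to
  significant/non-significant is deployment-specific;
  `app_significance_map()` is an editable table whose default marks
  social, work and study as significant.
* **Pruning.** A feature is quasi-constant when its modal value covers
  more than 1 − 0.05 of the observed cells; those columns are dropped
  first, then columns more than 20% missing. We use the modal-frequency
  form of the low-variability test rather than a variance threshold on
  min–max-scaled values because the latter is not operable: a feature
  scaled to its own range has variance at most 1/12 ≈ 0.083 (uniform) and
  about 0.03 for a bell-shaped column, so a 0.05 cutoff would discard
  nearly every real-valued feature regardless of how informative it is.
  Identifier, demographic and calendar columns are exempt.

## 4. Profiling

* **SS.** `ss_j = |r(item_j, total)|` over the participant's first-month
  *observed* (non-interpolated) daily records — the significance of a
  symptom should come from what the person actually reported, not from
  values we manufactured between reports; a flag allows the dense series.
  Note the total includes item j itself; no part–whole correction is
  applied, matching the definition of the representation. Degenerate
  cases (constant item, constant total, fewer than three records) map to
  `ss_j = 0` — no evidence of significance — rather than to a missing
  value, so the profile stays well defined.
* **SH.** Nine binary gradient-boosted models (binary logistic objective,
  library defaults, 60 rounds, fixed seed) trained on the pooled
  first-month participant-days. The models are population-pooled: leakage
  control for the severity evaluation comes from the temporal split
  (profiles predict months 2–3 from models trained on month 1), not from
  excluding the profiled participant. A symptom with one class in month 1
  gets a constant-probability fallback and is flagged.
* **SP.** Element-wise product; every element is bounded by both factors,
  so a symptom that is either absent or personally uninformative
  contributes little.
* **Weighted SP.** The DSM-5 cardinal symptoms (depressed mood,
  diminished interest — items 2 and 1) can be given weight 2. For models
  with per-feature weight parameters the weight vector is passed through
  (feature sampling weights for the boosted trees and the random forest);
  for the margin/linear models the designated input columns are scaled.
  Tree models are invariant to monotone input scaling, which is why the
  two mechanisms differ.

## 5. Severity classification

* **Unit.** The prediction unit is the participant-day (the daily
  ground-truth unit); no smoothing across days. Severity labels for the
  prediction window use the dense (interpolated) daily series by default.
* **Models.** Four families behind one interface: `xgb` (gradient-boosted
  trees, softmax objective), `rf` (random forest), `svm` (RBF support
  vector machine, one-vs-one), `multinom` (ridge-penalised multinomial
  logistic). Hyperparameters are library defaults with fixed seeds; the
  package deliberately does no hyperparameter search.
* **LOSO.** One fold per held-out participant; missing feature cells are
  median-imputed inside each training fold and the fold's medians are
  applied to its test rows; for the per-symptom evaluation, SMOTE
  (k = 5 nearest minority neighbours, convex combinations, reduced k with
  a warning for tiny minorities) balances the training fold only.
* **Metrics.** One-vs-rest precision/recall/F1 per class, averaged with
  class-support weights; the weighted-average identity is asserted in the
  tests. Undefined 0/0 ratios are scored 0.
* **Imbalance screen.** A symptom enters the per-symptom evaluation only
  when the present/absent ratio lies within [1/4, 4] (boundary
  inclusive). The screen applies to the evaluation only; all nine
  probability models are always trained for profiling, with the fallback
  covering degenerate symptoms.

## 6. The synthetic cohort

The generator exists because cohorts of this kind are privacy-restricted:
it provides ground truth for every downstream stage.

* **Latent state.** Nine symptom intensities per participant-day on the
  0–3 item scale. Default: independent AR(1) per symptom
  (`symptom_ar_coefficient` 0.8, innovation SD 0.3) around a severity-group
  mean (0.50 / 1.55 / 2.40 per item, putting group totals near 4.5 / 14 /
  21.5), clipped to [0, 3]. An optional single-factor mode
  (`factor_loadings`) draws one AR(1) depression factor per participant
  and lets items load on it with item-specific unique noise — the
  configuration used by the planted-signal recovery experiments, where
  two "driver" symptoms carry the factor.
* **Severity groups.** Default fractions 0.6 / 0.3 / 0.1 — most
  participants not or mildly depressed, the severe group smallest, as in
  community cohorts. Ground-truth daily labels are the bucketed latent
  totals, using the same cutoffs as the EMA pipeline, so end-to-end
  recovery is well defined.
* **Demographics.** 63% female; age bands filled 65/25/10 so all three
  are populated.
* **EMA.** Every 3 days at three clock slots; item scores are latent
  intensities plus N(0, 0.25) discretisation noise rounded into {0..3};
  a planted fraction (default 3%) of trap answers sits ≥ 2 points from
  item 2; a planted fraction (default 5%) of durations is uniformly 3–15 s
  against a log-normal (median 60 s) background.
* **Sensors.** Interval sources at their registry cadences with
  contiguous missing spans; event sources as Poisson streams whose daily
  rate is `base · exp(loadingᵀ · min(intensities, cap))` — a monotone,
  optionally saturating response. The saturation point
  (`symptom_effect_cap`) models the floor effect of behavioural
  withdrawal: once someone largely stops going out, calling and walking,
  further symptom worsening changes behaviour little. Per-participant
  log-normal base-rate multipliers (`participant_rate_sd`, default 0.4)
  encode device/lifestyle heterogeneity, and daily mobility has a
  per-participant routine intercept (commuters vs home-workers) dampened
  by symptom load. GPS outliers are displaced 0.05–0.5° from every
  cluster; a planted fraction of duration records is negative.
* **What the generator does not emulate** — and hence what passing tests
  do *not* show about real data: real device telemetry formats and
  platform-specific loss patterns, response styles and scale-use habits
  in self-reports, non-stationary routines (travel, holidays), weekday
  structure beyond the work schedule, and any causal structure beyond the
  single latent symptom process. Results on the synthetic cohort
  demonstrate that the pipeline's machinery is correct and recovers
  planted structure; they are not evidence about predictive performance
  on real cohorts.

## 7. Problem sizes used by the checks

The end-to-end recovery experiment in the test suite uses 60 participants
× 90 days (the planted two-driver scenario of
`recovery_scenario_config()`); `scripts/acceptance.R` uses 50
participants × 90 days plus a 20-participant sub-cohort for the
per-symptom LOSO evaluation. Smaller worlds (4–12 participants, 31–90
days) back the stage-level tests. These sizes were chosen so the
statistics of interest (correlations, rank orders, F1 margins) are stable
at desk scale.

## 8. Known limitations

* **The profile input does not beat the raw sensor input on this
  generator.** On the planted-signal cohort the SP representation's
  weighted F1 clearly beats the majority-class baseline, but trails the
  direct sensor representation by roughly 0.1 across all four model
  families. In a transparent generator this is structural: the SH
  probabilities are functions of the very features the sensor models see,
  so the profile route cannot carry more information than the sensor
  route, and presence-thresholding at score > 0 discards the intensity
  information that separates the moderate from the severe band, while the
  significance factor estimated from roughly ten first-month reports adds
  person-level noise. Settings where profiling helps on real cohorts —
  weak and platform-fragmented sensor–symptom coupling, person-specific
  symptom expression, shared method variance between the self-report-
  derived profile and self-report-derived labels — are exactly the
  real-data properties a generic simulator does not reproduce, and we
  deliberately did not engineer the generator to manufacture the
  improvement.
* The group-profile summaries show the same pattern reported for this
  family of methods: the profile underestimates symptom magnitude for the
  more depressed groups, because their month-1 items saturate and their
  significance correlations degenerate toward zero.
* The home/work inference and the app significance map are conventions;
  both are exposed as data so deployments can substitute their own.
* Timestamps are naive local time; the design assumes a single-timezone
  study.
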