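---
title: "Predicting pediatric hemodynamic instability with abstaining boosted stumps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting pediatric hemodynamic instability with abstaining boosted stumps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiiboost)
```

## The prediction task

Children in intensive care compensate for circulatory failure remarkably
well — heart rate rises, vessels constrict, urine output falls — and blood
pressure often stays normal until deterioration is nearly irreversible. Two
facts shape any workable early-warning model for this population. First,
normal ranges are age-dependent: a heart rate of 140 bpm is ordinary in an
infant and alarming in an adolescent, so thresholds must move with age.
Second, ICU data are systematically incomplete: a lactate is drawn on a small
minority of patients, arterial lines exist only where someone chose to place
one, and a model that either discards sparse features or imputes them throws
away or fabricates exactly the information that matters most.

`hiiboost` defines hemodynamic instability by the clinical action it
provokes. An encounter is labeled **unstable** if the patient received a
qualifying intervention — a fluid bolus faster than 10 ml/kg/h, or initiation
of dopamine, dobutamine, epinephrine, norepinephrine, neosynephrine or
vasopressin — and **stable** if no such intervention occurred during the
stay. The *onset* is the time of the first qualifying intervention; it
anchors feature extraction and lead-time evaluation. Patients whose onset
falls within the first 6 hours of admission are excluded outright: their
instability predates the PICU record and is not a fair prediction target.
Only each patient's first admission contributes.

## From chart to feature vector

The pipeline reads three delimited tables (encounters, chart events,
interventions) and applies, in order:

1. **Canonicalization** — feature synonyms map onto the 36-name catalogue
   (`feature_catalogue()`); unknown names and unparseable rows are dropped
   and counted. FiO2 charted as a percentage is converted to a fraction.
2. **Plausibility filtering** — values outside a per-feature physiologic
   range (e.g. heart rate 20–350 bpm, pH 6.5–8.0) become missing. The bounds
   are documented, deliberately permissive defaults
   (`default_plausibility()`), overridable by configuration; the principle is
   that an impossible value is a charting artifact, not information.
3. **Blood-pressure reconciliation** — when a cuff (noninvasive) pressure is
   charted within 20 minutes of an arterial-line (invasive) measurement of
   the same component, the cuff value is discarded and the line value used.
   The 20-minute proximity window is the upper end of the plausible range and
   is configurable; invasive readings are never removed.
4. **Windowed extraction** — each example takes, per feature, the *last*
   measurement in the half-open 24-hour window `(t_ref − 24 h, t_ref]`; no
   measurement means missing. For unstable encounters `t_ref` is the onset
   during training, or `onset − L` for lead times `L` = 1–12 h during
   evaluation. For controls `t_ref` is drawn uniformly at random (seeded)
   over `[admission + 24 h, discharge]`, so a full window is available; stays
   too short for that fall back to `[admission + 6 h, discharge]`. The
   boundary conventions matter for leakage: a measurement exactly at `t_ref`
   is included, one exactly 24 h earlier is not, and nothing after the onset
   is ever visible to an unstable example.

Three composites are derived after extraction, with FiO2 as a fraction and
invasive systolic pressure preferred over noninvasive when both are present:

* shock index `SI = HR / SBP`,
* oxygenation index `OI = (MAP × FiO2 × 100) / PaO2`,
* oxygen saturation index `OSI = (MAP × FiO2 × 100) / SpO2`,

where MAP is the mean airway pressure. A composite is missing whenever any
constituent is missing, and a zero denominator yields missing rather than an
infinity.

At scoring time (as opposed to training-time extraction) a staleness gate
governs currency: blood pressures and ventilator parameters expire after
1 hour, laboratory values and the remaining vitals after 24 hours. The
source material states the 24 h/1 h pair for laboratory and blood-pressure
measurements; grouping ventilator parameters with the 1-hour class and the
remaining vitals with the 24-hour class is this package's documented choice —
ventilator settings change on the same timescale as pressures, while a
4-hour-old temperature is still a temperature.

## The learner

Weak classifiers are decision stumps conditioned on age. Age is partitioned
into five bins (1–12 months, 1–3, 3–6, 6–12, 12–20 years — the same strata
used for evaluation; configurable). A stump on feature `x` holds one
(threshold, direction) pair per bin and votes +1 (unstable), −1 (stable), or
0 — it *abstains* — when `x` is missing. Abstention is the mechanism that
lets an 86%-missing lactate still carry weight on the patients who have one.

Boosting proceeds as in discrete AdaBoost with a third vote value. With
normalized example weights, a candidate stump decomposes the weight into
`W+` (voted correctly), `W−` (voted incorrectly) and `W0` (abstained), and
the round selects the stump minimizing the normalizer

`Z = W0 + 2·sqrt(W+·W−)`,

assigning it `α = ½·log((W+ + ε)/(W− + ε))` with smoothing `ε = 1/(2N)`, then
reweighting by `exp(−α·y·h(x))` — abstained examples keep their weight — and
renormalizing. The abstaining variant is named in the source literature
without equations; this `Z`/`α` construction is the standard confidence-rated
one, and the package documents it as such. With `ε = 0` the usual guarantee
holds and is tested: the training exponential loss after `T` rounds is at
most `∏_t Z_t`.

Candidate thresholds sit at midpoints between consecutive distinct observed
in-bin values, capped at 64 per bin via a quantile grid; bins with fewer than
two distinct values inherit the nearest populated bin's candidates, so every
stump is defined over the whole age range. A useful structural fact makes the
search exact rather than heuristic: for a fixed feature, `W0` is fixed (it is
the missing weight) and `W+ + W−` is fixed, so minimizing `Z` over all
per-bin (threshold, direction) combinations is equivalent to maximizing the
weighted edge, which is additive over disjoint age bins — per-bin
maximization by cumulative sums over value-sorted examples *is* the global
minimizer. The test suite checks this against a brute-force enumeration of
the full candidate space on small instances. Ties resolve deterministically:
lowest feature index, then lowest threshold, then the high-is-unstable
direction (and, between a stump and its direction-mirrored twin, the
majority-voting version), so training is reproducible to the byte. Training
stops early when no candidate beats abstention-plus-chance
(`Z ≥ 1 − 10⁻⁶`); at the first round that is an error, since it means no
feature is informative at all.

Feature selection is emergent, not enforced: the trainer may use any of the
36 + 3 features, and sparsity comes from rounds concentrating on what
reduces `Z`.

### Probability and operating point

The hemodynamic instability indicator is the logistic map of the
(unnormalized) ensemble margin, `HII = 1/(1 + exp(−2F(x)))` — the
additive-logistic-regression view of boosting. The margin is *not*
renormalized by `Σα`, so the calibration is serialized with the model and
probability thresholds are model-specific quantities, not transferable
constants. The default operating threshold stored in the model is the
**break-even point**, where sensitivity equals precision, searched over
observed score cutpoints (exact equality is generally unattainable on a
finite sample, so the attained gap is reported, and a break-even landing on
the empty corner of the precision–recall curve is flagged degenerate). On
well-separated training data the stored training break-even saturates near
1.0; the evaluation functions therefore recompute the break-even on the
scores being evaluated by default.

Predictive values are prevalence-adjusted by Bayes' rule:
`PPV = sens·π / (sens·π + (1−spec)(1−π))` and
`NPV = spec·(1−π) / (spec·(1−π) + (1−sens)·π)`. One published operating
point reports a positive likelihood ratio of 5.22 alongside sensitivity 0.66
and specificity 0.78, which is inconsistent with the standard
`sens/(1−spec) = 3.0`; this package implements the standard formula and
flags the discrepancy here rather than reproducing it.

### Runtime

`score_stream()` replays an encounter's events on a fixed cadence (default
hourly here; bedside deployments run per minute). Each tick applies the
staleness gate, derives composites and scores; heart rate plus age is the
minimum input, and a tick without it emits an explicit no-output record with
a reason, never a silent skip. Scoring is strictly causal — truncating the
event stream at time *t* cannot change any output at or before *t*, and the
tests assert it. Per-feature contributions (`explain()`) sum exactly to the
margin; features whose stumps all abstain are flagged *missing* rather than
reported as zero, because "no information" and "actively reassuring" are
different clinical statements. Colors: green below `c1`, yellow in
`[c1, c2)`, red at and above `c2`; boundaries belong to the higher-risk side.
The deployed product's cutpoints are unpublished, so the defaults here place
`c2` at the model's operating threshold and `c1` 0.1 below it, both
configurable.

## The synthetic cohort generator

No patient-level data ship with the original work, so the simulator is a
first-class module: it generates the statistical structure the pipeline
assumes, making every downstream stage testable end to end.

Each of the 36 features has a built-in piecewise-linear reference curve of
(mean, SD) against age with knots at 1/12, 1, 5, 12 and 20 years —
pediatric-plausible values (infant heart rate ~140 falling to ~75 by
adulthood; systolic pressure rising 75→118; labs mostly age-flat), documented
as simulator defaults rather than normative ranges, and replaceable via
configuration. Patients draw an age (uniform within five strata, default
equal weights), an admission, a length of stay (log-normal; stable stays
average ~3.6 days, unstable considerably longer), a ventilation flag (56%
unstable / 28% stable), a mortality flag, and an arterial-line flag
(Bernoulli 0.5, label-independent). 42% of patients (configurable) receive
exactly one qualifying intervention — 70% fluid bolus with a rate drawn
above 10 ml/kg/h, 30% vasoactive — placed 12–72 hours after admission,
always clear of the 6-hour exclusion.

Feature streams are Poisson-like event sequences (exponential gaps at
per-feature mean intervals: roughly hourly vitals, 8-hourly blood gases,
daily chemistry) recorded with per-patient Bernoulli probabilities matching
the recording-percentage table the model was built around (heart rate 100%,
blood gas panel 63%, lactate 14%, ...). Values are Gaussian around the
age-interpolated reference mean, clamped into the plausibility range. For
unstable patients, feature means drift linearly toward the shock phenotype
over the 24 hours preceding onset — heart rate and lactate up; blood
pressures, pH, base excess and urine output down — scaled by standardized
effect sizes (`default_effect_sizes()`: +2 SD heart rate, −1.5 SD systolic
pressure and pH, and so on). The published work reports no effect sizes or
lead-time signal strength on real data, so these defaults are this package's
one-time choice of a clearly detectable but not trivial signal; they are
knobs for experimentation, not claims about nature. Event streams for
unstable patients stop 6 hours after onset — the post-intervention course is
out of scope.

Determinism is strict: all randomness flows from the config seed, each
patient from its own deterministically derived sub-stream, so identical
(config, seed) pairs reproduce identical tables regardless of patient count
or ordering.

**What the simulator deliberately does not emulate.** Real PICU data contain
confounds the generator omits by design. The most important: in real data the
*presence* of ventilator parameters and arterial lines correlates with the
outcome (sicker children are instrumented more), and a model can learn risk
from instrumentation patterns alone. In the simulator, recording is
label-independent for every feature — the arterial-line flag gates invasive
pressures but is itself drawn independently of the label — so that a
zero-effect-size cohort is a true null: any classifier's held-out AUROC must
sit at 0.5 within Monte-Carlo error, and the test suite checks exactly that.
Passing tests therefore demonstrate that the pipeline recovers *charted
physiology*, not presence artifacts; they say nothing about how large the
instrumentation signal is in real data. Other omissions: no terminology
noise (canonical names are used directly, exercising the alias map only
lightly), no pharmacokinetics or therapy response, no multi-intervention
sequences, no inter-feature correlation beyond the shared deterioration
ramp, and no age-varying missingness.

## Evaluation protocol

`auroc()` is the Mann–Whitney probability that a random unstable example
outscores a random stable one, ties at half credit (agreeing with an
all-pairs count and with trapezoidal ROC integration; both are tested).
`leadtime_curve()` evaluates vectors extracted 1–12 hours before onset
against the fixed control examples — with a deterioration ramp the AUROC
declines as lead time grows. `stratified_report()` covers the five age
groups, the ventilated flag, the first-intervention kind, and feature
subsets; subsets are evaluated by masking all other features to missing at
predict time, letting abstention absorb the change without retraining
(retraining is available as an option). `baseline_models()` fits the same
trainer restricted to systolic blood pressure or to the shock index — the
two bedside comparators — and the package's acceptance checks require the
full model to dominate both on the default synthetic cohort. Summary
statistics use the sample (n−1) standard deviation, which reproduces the
published five-age-group summary (SD 0.038 → printed 0.04) exactly.

## Numerical and design choices, collected

* Window boundary `(t_ref − 24 h, t_ref]`: half-open, inclusive at the
  reference instant.
* Stump votes at the threshold: a value equal to the threshold votes stable
  in both directions (thresholds sit at midpoints between observed values,
  so equality is rare by construction).
* `ε = 1/(2N)` keeps α finite on separable bins; `ε = 0` is available and
  used when testing the exponential-loss bound.
* Candidate cap 64 thresholds per bin via quantile midpoints: past that
  resolution, extra cutpoints refine weights by less than sampling noise.
* Ties in training resolve lexicographically (feature order, threshold,
  direction); ties between simultaneous duplicate measurements resolve to
  the last row read, and are logged.
* Serialization writes doubles as `%.17g` strings inside JSON, so a
  write/read cycle is bit-exact and byte-identical models produce
  byte-identical files; the loader rejects a catalogue-hash mismatch
  (plausibility bounds and staleness horizons are frozen into the model).
* Problem sizes in the test suite are chosen for resolution per check:
  enumerable fixtures (≤ 8 examples) for oracle equivalence, 1 000 patients
  with 10-fold cross-validation for the null-calibration band (pooled
  out-of-fold scores give the Monte-Carlo error needed to resolve
  [0.45, 0.55]), 2 000 patients for signal recovery and the age-threshold
  monotonicity check.

## Known limitations

Training on proxy labels inherits their circularity: the model predicts the
*decision to intervene*, and clinicians who intervene on the model's inputs
will look more predictable than the physiology warrants. Pre-admission
interventions are invisible (mitigated, as in the source protocol, by the
6-hour exclusion). The probability calibration is the logistic of an
unnormalized margin — fine for ranking and for model-specific thresholds,
not comparable across models of different sizes. The simulator's Gaussian,
conditionally independent features understate the correlation structure of
real charts, so absolute synthetic AUROCs should not be read as forecasts of
clinical performance; the published external-validation results on real
cohorts are not reproducible here because those datasets are not
distributed.
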