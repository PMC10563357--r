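---
title: "How baseline creatinine estimation shapes AKI labels and model benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How baseline creatinine estimation shapes AKI labels and model benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akibench)
```

## The problem

Acute kidney injury (AKI) in ICU patients is conventionally detected from
serum creatinine (sCr) dynamics: a rise of at least 0.3 mg/dL (26.5
umol/L) within 48 hours, or a value at least 1.5 times a *baseline*
creatinine within 7 days. The second criterion is only as good as the
baseline it is judged against, and there is no standard way to obtain one:
most ICU admissions arrive without a recent outpatient creatinine on
record. Prediction models trained on AKI labels therefore inherit whatever
baseline convention the labelling pipeline chose, and two models reporting
the same metric under different conventions are not comparable.

`akibench` implements that whole chain as testable components: six
baseline estimators, the KDIGO sCr labelling engine (with an independent
brute-force oracle), cohort construction, calibrated classifier training,
cross-baseline statistical comparison, and an attribution toolkit for
auditing false positives. A synthetic EHR generator with a *known*
injected AKI process makes every stage verifiable without access to any
restricted clinical database.

## The labelling engine

`detect_aki()` scans an admission's in-ICU creatinine series. At each
measurement time $t$ the absolute criterion compares $sCr(t)$ to the
rolling minimum over $(t - 48\mathrm{h},\ t]$; the ratio criterion
compares $sCr(t)/\text{baseline}$ to 1.5 within 7 days of admission. Both
thresholds are inclusive, implemented with a $10^{-9}$ numerical slack so
that exact-boundary cases (such as $0.9/0.6$) are not lost to floating
point. Several choices here were genuinely open and are fixed as follows:

* **Comparator for the 48-h rise.** The consensus definition does not say
  what the rise is measured *from*. We use the rolling 48-h minimum of the
  same admission's series (pre-ICU values excluded), the standard
  operationalisation; the brute-force oracle `detect_aki_oracle()`
  implements the identical semantics by exhaustive pair scanning and the
  two are required to agree exactly on fuzzed series.
* **Days.** "Day $d$" means offsets in $[24(d-1), 24d)$ hours from ICU
  admission, anchoring windows on admission time rather than calendar
  midnight, which would make day 1 a variable-length window.
* **Detection window.** Labels report a first-detection day of 1, 2 or 3:
  day 1 drives an exclusion, days 2-3 are the prediction outcome. The
  7-day ratio window is retained in the code but is non-binding once
  detection is restricted to the first three days.
* **Monotonicity.** Under a rolling-minimum comparator, raising a *single*
  creatinine value can in principle unflag an admission (when the raised
  value was the dip another measurement rose from). The property the
  engine does guarantee — and the tests assert — is that adding a common
  positive shift to all day-2/3 values never unflags, and that a larger
  baseline never flags an admission a smaller baseline would not.

## The six baseline estimators

| Method | Window | Aggregator | Fallback |
|---|---|---|---|
| `B1_min_first24h` | first 24 h in ICU | min | — (ineligible if no day-1 sCr) |
| `B2_mdrd_then_min24h` | first 24 h in ICU | min | — (MDRD value used as day-1 screen only) |
| `B3_mean_180to7_or_mdrd` | 180–7 days pre-ICU | mean | backward MDRD |
| `M1_min_180to7_or_mdrd` | 180–7 days pre-ICU | min | backward MDRD |
| `M2_min_180to0_or_mdrd` | 180–0 days pre-ICU | min | backward MDRD |
| `M3_mean_180to0_or_mdrd` | 180–0 days pre-ICU | mean | backward MDRD |

A pre-ICU draw $d$ days before admission is in window $[a, b]$ iff
$b \le d \le a$; "0 days before" includes same-day draws strictly before
ICU admission. We read the windows as strictly pre-ICU — in-ICU day-1
values never enter the 180-to-0 window — because the estimators exist
precisely to characterise the *pre-admission* kidney state; this is
flagged as a sensitivity-analysis point rather than settled fact.

`B2_mdrd_then_min24h` is deliberately two-stage, returned as an explicit
pair: the backward-MDRD value screens for day-1 AKI (driving exclusion),
after which the day-1 minimum becomes the working baseline for the
outcome labelling.

The backward MDRD calculation is implemented exactly as conventionally
printed,

$$sCr_{GFR\text{-}75} = \left(\frac{75}{186\,\cdot\,age^{-0.203}\,\cdot\,
(0.742\ \text{if female})}\right)^{-0.887},$$

even though $-0.887$ is not the exact algebraic inverse of the MDRD
creatinine exponent ($-1/1.154 \approx -0.867$). Fidelity to the printed
convention wins over algebraic purity; the exact inverse is available via
the `exponent` argument, and the tests document that the printed version
round-trips the assumed eGFR of 75 to within 0.7 units across the adult
age range while the exact inverse closes the loop to machine precision.
The CKD-EPI eGFR (2009 creatinine equation, no race coefficient) is used
only as a model feature, computed from the day-1 *minimum* creatinine —
the source convention does not say which day-1 value feeds it, and the
minimum is the value most plausibly reflecting pre-insult function.

## The synthetic generator

`generate_population()` emulates the structure the pipeline needs, not ICU
physiology. Each subject has a piecewise-constant true baseline
(log-normal across subjects, median 0.9 mg/dL, `sdlog` 0.35 — a typical
adult creatinine spread) observed with i.i.d. Gaussian noise (sd 0.05
mg/dL); creatinine is sampled every 12 h over days 1-7 (the sampling
frequency of the emulated cohort is unpublished, so it is a parameter).
AKI trajectories are sustained step rises planted so the chosen criterion
fires *first on the target day, never earlier*, with a margin of at least
4 noise standard deviations above threshold so that measurement noise
cannot de-flag them. The targeted criterion cannot always be the *only*
one to fire: for baselines above ~0.6 mg/dL any 1.5× rise reached within
48 h necessarily also exceeds 0.3 mg/dL, so the untargeted criterion may
co-fire at the same instant. The flag and the detection day — the
quantities the ground truth records — are unaffected.

Default condition knobs, set once:

* day-2/3 AKI injection rate 0.1732 (the prevalence regime of the
  emulated cohort) and day-1 rate 0.20 (the emulated cohort's labelled
  day-1 exclusion fractions sit between ~20% and ~29% depending on the
  baseline definition; the latent truth rate is set at the lower edge
  because estimated baselines over-flag day 1 relative to truth);
* 64.19% of admissions lose their entire pre-ICU creatinine history;
* per-variable first-24h missingness includes albumin at 68.37% and
  bilirubin at 50.85%, deliberately above the 20% filter, with the rest
  between 1% and 10%;
* demographics, comorbidity prevalences and the urine-output scale follow
  the emulated cohort's characteristics table;
* 30% of admissions with pre-ICU history have draws only within 7 days of
  admission, so the 180-to-7 and 180-to-0 windows genuinely disagree; and
  15% of non-AKI admissions carry a sub-threshold (×1.25) creatinine
  elevation on day 1 and in recent pre-ICU draws — the "looks like AKI
  but is not" phenotype that drives false-positive audits.

What the generator does *not* model: physiological coupling between
non-creatinine variables, treatment effects, urine-output-driven AKI, and
informative (non-random) missingness. Passing tests therefore demonstrate
that the *machinery* is correct under known ground truth — they do not
certify performance numbers on real ICU data, where label noise,
confounding and missingness structure are all harder.

## Cohort, models, evaluation

Cohort construction applies the exclusion steps in a fixed, audited
order (adults → first ICU stay → no maintenance RRT → sCr on days 1-3 →
no day-1 AKI; the order is a package choice — the per-step counts are
logged so any order-dependence is visible), aggregates first-24h events
to per-variable min/max plus mean urine output, drops columns strictly
above 20% missingness, and imputes the rest by chained equations. The
imputer is a deterministic regression-based chained-equations sweep
(initialise at training means, iterate per-column least squares with a
small Gram-scaled ridge for the exactly collinear one-hot block) fitted
on the training partition only; a single completed dataset is produced
because the downstream classifiers consume one matrix —
multiple-imputation pooling is out of scope. Min-max scaling is likewise
train-fitted; out-of-range validation/test values are clipped to $[0,1]$
to keep the stated feature-range contract.

Model training uses a stratified 60/20/20 split and 5-fold
cross-validation optimising f1, with positive-class up-sampling (random
duplication to 1:1 — the simplest scheme consistent with "up-sampling")
applied strictly inside each fold's training part. Calibration is
parametric sigmoid (Platt) scaling fitted on the validation partition —
no calibration method is prescribed by the source convention, and the
sigmoid is the low-variance default for moderate validation sizes;
isotonic regression is available behind a flag. The decision threshold
maximises f1 over all distinct validation probabilities, ties broken
toward the larger threshold (fewer alerts). The artificial neural network
is a single-hidden-layer perceptron sized by the same CV objective. The
gradient-boosting grid includes a configuration mapped from a reported
leaf-wise parameterisation (`num_leaves` → `max_leaves` with loss-guided
growth; `min_child_samples` has no exact equivalent here and is
approximated by `min_child_weight`).

Evaluation reports AUC (rank statistic with tie midpoints),
precision/recall/f1 at the selected threshold (0/0 → 0 convention), ECE
over 10 equal-width bins (bin count configurable), the Brier score, and
the calibration slope (logistic regression of outcome on the logit of the
probability, clipped at $10^{-6}$). Cross-baseline comparison bootstraps
the test-set f1 — 500 replicates of full-size with-replacement resamples;
"a subset of data (n = 500)" admits both a replicate-count and a
subset-size reading, so both knobs are exposed and the replicate reading
is the default — and compares the distributions by one-way ANOVA with
Tukey HSD at $p \le 0.05$.

## Error auditing

`breakdown_attribution()` computes sequential conditional contributions
along one feature ordering, with the value function defined as the
marginal (interventional) expectation over a background sample — chosen
over conditional estimation because it is well defined and exactly
checkable against enumeration. `shapley_attribution()` averages
break-down contributions over sampled orderings; additivity (intercept
plus contributions equals the prediction) holds exactly for both, and for
five or fewer features the sampled estimate is tested against the
exhaustive all-orderings average. The recommended background is a seeded
subsample of the training partition (capped around 1000 rows), and the
default audit examines 10 randomly chosen false-positive predictions from
the validation partition. `relabel_experiment()` closes the loop: it
relabels the data under the modified baseline definitions, retrains and
re-evaluates, and reports how many of the original false positives the
new labelling converts to positives.

## Verification scale and numerical choices

The shipped test suite runs the labeller-versus-oracle equivalence on
10,000 fuzzed series, prevalence recovery on a 2,000-patient population,
calibration-slope recovery on $10^5$ simulated outcomes, the Tukey null
false-flag rate over 200 repetitions, and a full end-to-end comparison of
the three primary baselines on a 2,000-patient synthetic population —
sizes chosen so the whole suite completes in a couple of minutes while
keeping Monte-Carlo tolerances tight. Degenerate inputs fail loudly by
design: empty series, non-positive baselines, single-class partitions and
constant probability vectors raise errors or explicit warnings rather
than returning silently wrong numbers.

## Limitations

The synthetic ground truth makes correctness testable but easy: signal
strength, class balance and missingness are all friendlier than real ICU
data, so absolute metric values produced here say nothing about clinical
performance. The urine-output arm of the consensus AKI definition, AKI
severity staging, recurrent episodes, and ICD-code-derived comorbidity
extraction are out of scope. The chained-equations imputer is a
single-imputation regression scheme — adequate for point prediction, not
for imputation-uncertainty inference.
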