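# akibench

Tools for studying how the choice of **baseline serum creatinine (sCr)**
changes KDIGO acute-kidney-injury (AKI) labelling — and, through the
labels, the measured performance of clinical prediction models. The
package is aimed at clinical-ML researchers who want the labelling
pipeline, not just the classifier, under test.

## Why

KDIGO flags AKI on either of two sCr criteria, both evaluated over an
ICU admission's irregular creatinine series:

- **absolute**: a rise of ≥ 0.3 mg/dL (26.5 µmol/L) within 48 h, measured
  against the rolling 48-h minimum;
- **ratio**: a value ≥ 1.5 × the *baseline* creatinine within 7 days.

The ratio criterion needs a baseline, and most ICU admissions have no
recent outpatient creatinine. The common fallback is the backward MDRD
calculation at an assumed eGFR of 75 ml/min/1.73 m²:

```
sCr_GFR-75 = ( 75 / (186 · age^-0.203 · [0.742 if female]) )^-0.887
```

Different baseline conventions produce different labels from the same
data, and models trained on them are not comparable. `akibench`
implements six estimators — the first-24h minimum (`B1`), an
MDRD-screened day-1 minimum (`B2`), the mean of pre-ICU values 180–7 days
before admission with MDRD fallback (`B3`), and three modified window
variants (`M1`–`M3`, min/mean over 180–7 or 180–0 days) — together with:

- the KDIGO sCr labelling engine plus an independent brute-force oracle
  (`detect_aki()` / `detect_aki_oracle()`);
- a synthetic ICU EHR generator with a *known, injected* AKI process, so
  every downstream stage is testable without restricted data
  (`generate_population()`), plus a thin CSV adapter for MIMIC-like
  long-format tables;
- cohort construction with an audited exclusion pipeline, first-24h
  aggregation, a strict-20% missingness filter, train-only
  chained-equations imputation and train-only min–max scaling
  (`build_cohort()`);
- calibrated classifier training (LR / random forest / gradient boosting
  / single-hidden-layer ANN) with up-sampling confined to
  cross-validation training folds, Platt calibration and f1-optimal
  thresholding (`tune_and_train()`, `calibrate()`, `select_threshold()`);
- discrimination + calibration metrics (AUC, precision/recall/f1, ECE,
  Brier, calibration slope) and a bootstrap + ANOVA/Tukey-HSD
  cross-baseline comparison (`compare_baselines()`);
- break-down and ordering-averaged Shapley attributions for auditing the
  false-positive cohort, and a relabel-and-retrain experiment
  (`shapley_attribution()`, `relabel_experiment()`).

## Worked example

```r
library(akibench)

backward_mdrd(60, "female")
#> [1] 0.8217718      # mg/dL — the MDRD fallback baseline for a 60-year-old woman

detect_aki(c(6, 18, 30, 42), c(0.9, 0.95, 1.28, 1.31), baseline = 0.9)
#> AKI flagged: day 2, criterion absolute (offset 30.0 h)
# (1.28 - 0.9 = 0.38 >= 0.3 within 48 h; the ratio 1.28/0.9 = 1.42 stays below 1.5)

bundle <- apply_missingness(generate_population(sim_config(n_patients = 600, seed = 42)))
bundle
#> Synthetic EHR bundle: 600 patients, 632 admissions, 35122 ICU events, 718 pre-ICU creatinine draws
#> Latent AKI truth: none 375, day1 136, day2 62, day3 59

cmp <- compare_baselines(bundle, family = "XGB", seed = 1, n_boot = 200)
cmp
#> Cross-baseline comparison
#>                  method   n prevalence    auc precision recall     f1     ece
#>         B1_min_first24h 458     0.2489 0.9427    0.9231 0.5217 0.6667 0.07187
#>     B2_mdrd_then_min24h 390     0.2487 0.9776    0.9000 0.9000 0.9000 0.07375
#>  B3_mean_180to7_or_mdrd 410     0.2610 0.9583    0.9474 0.8182 0.8780 0.04828
#>    brier  slope threshold
#>  0.07882 0.7203    0.8662
#>  0.05007 0.8048    0.6514
#>  0.05853 0.8945    0.7401
#> ANOVA F = 703.18 (p = 1.13e-157); Tukey HSD pairs:
#>                                        pair     diff      lwr       upr     p_adj significant
#>         B2_mdrd_then_min24h-B1_min_first24h  0.23222  0.21602  0.248426 4.649e-10        TRUE
#>      B3_mean_180to7_or_mdrd-B1_min_first24h  0.21468  0.19847  0.230878 4.649e-10        TRUE
#>  B3_mean_180to7_or_mdrd-B2_mdrd_then_min24h -0.01755 -0.03375 -0.001345 3.006e-02        TRUE
```

Three cohorts built from the *same* synthetic admissions end up with
different sizes, prevalences and f1 scores purely because the baseline
definition changed; the Tukey table quantifies which pairwise differences
the bootstrap distinguishes. On this synthetic population the first-24h
minimum baseline (`B1`) costs the classifier most of its recall — the
same direction of effect that motivates auditing baseline conventions in
real cohorts.

The vignette (`vignettes/baseline-creatinine-benchmark.Rmd`) documents
the model, the generator's assumptions and every numerical choice.

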