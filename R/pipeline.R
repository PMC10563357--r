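# End-to-end orchestration: one labelled cohort -> trained, calibrated,
# thresholded classifier -> metric report; and the cross-baseline
# comparison with bootstrap + ANOVA/Tukey HSD.

#' Run the full pipeline for one baseline method
#'
#' Builds the cohort under `method` ([build_cohort()]), tunes and trains
#' the classifier on the training partition ([tune_and_train()]),
#' calibrates on validation ([calibrate()]), selects the f1-optimal
#' threshold on validation ([select_threshold()]), evaluates
#' discrimination and calibration on the held-out test partition, and
#' bootstraps the test-set f1. The false-positive cohort is recorded on
#' the validation partition (the audit target).
#'
#' @param bundle An `ehr_bundle`.
#' @param method One of [baseline_methods()].
#' @param family Classifier family (`"LR"`, `"RF"`, `"XGB"`, `"ANN"`).
#' @param seed Seed shared by partitioning, tuning and the bootstrap.
#' @param grid Optional hyperparameter grid override.
#' @param n_boot Bootstrap replicates. Default 500.
#' @param calibration `"platt"` or `"isotonic"`.
#' @return An `aki_run` list: `method`, `family`, `seed`, `cohort`,
#'   `model`, `calibrated`, `threshold`, `metrics` (test), `ece`, `brier`,
#'   `slope` (test), `boot_f1`, `fp_ids`, `val_metrics`.
#' @export
run_aki_pipeline <- function(bundle, method, family = "XGB", seed = 1L,
                             grid = NULL, n_boot = 500,
                             calibration = "platt") {
  cohort <- build_cohort(bundle, method, seed = seed)
  x <- cohort$features
  y <- cohort$outcome
  part <- cohort$partition
  tr <- part == "train"; va <- part == "validation"; te <- part == "test"

  model <- tune_and_train(x[tr, , drop = FALSE], y[tr], family = family,
                          grid = grid, seed = seed)
  cal <- calibrate(model, x[va, , drop = FALSE], y[va], method = calibration)
  p_va <- predict(cal, x[va, , drop = FALSE])
  threshold <- select_threshold(p_va, y[va])
  cal$threshold <- threshold

  p_te <- predict(cal, x[te, , drop = FALSE])
  metrics <- discriminative_metrics(p_te, y[te], threshold)
  test_ece <- ece(p_te, y[te])
  test_brier <- brier(p_te, y[te])
  test_slope <- tryCatch(calibration_slope(p_te, y[te]),
                         error = function(e) NA_real_)
  boot <- bootstrap_f1(p_te, threshold, y[te], n_boot = n_boot, seed = seed)

  val_metrics <- discriminative_metrics(p_va, y[va], threshold)
  cp <- confusion_partition(p_va, y[va], ids = cohort$admission_id[va],
                            threshold = threshold)

  structure(list(method = method, family = family, seed = seed,
                 cohort = cohort, model = model, calibrated = cal,
                 threshold = threshold, metrics = metrics,
                 ece = test_ece, brier = test_brier, slope = test_slope,
                 boot_f1 = boot, fp_ids = cp$fp,
                 val_metrics = val_metrics),
            class = "aki_run")
}

#' @export
print.aki_run <- function(x, ...) {
  cat(sprintf("%s / %s: test ", x$method, x$family))
  print(x$metrics)
  cat(sprintf("calibration: ECE %.4f | Brier %.4f | slope %.4f\n",
              x$ece, x$brier, x$slope))
  invisible(x)
}

#' Compare classifier performance across baseline methods
#'
#' Runs [run_aki_pipeline()] for each method on the same bundle and split
#' seed, then compares the bootstrap f1 distributions with one-way ANOVA
#' and Tukey HSD pairwise tests at `alpha`.
#'
#' @inheritParams run_aki_pipeline
#' @param methods Baseline methods to compare.
#' @param alpha Significance level for the pairwise flags. Default 0.05.
#' @return A `baseline_comparison` list: `summary` (per-method metric
#'   data.frame), `tests` ([anova_tukey()] output), `runs`.
#' @export
compare_baselines <- function(bundle,
                              methods = c("B1_min_first24h",
                                          "B2_mdrd_then_min24h",
                                          "B3_mean_180to7_or_mdrd"),
                              family = "XGB", seed = 1L, grid = NULL,
                              n_boot = 500, alpha = 0.05) {
  runs <- lapply(methods, function(m) {
    run_aki_pipeline(bundle, m, family = family, seed = seed, grid = grid,
                     n_boot = n_boot)
  })
  names(runs) <- methods
  summary <- do.call(rbind, lapply(runs, function(r) {
    data.frame(method = r$method, n = length(r$cohort$admission_id),
               prevalence = mean(r$cohort$outcome),
               auc = r$metrics$auc, precision = r$metrics$precision,
               recall = r$metrics$recall, f1 = r$metrics$f1,
               ece = r$ece, brier = r$brier, slope = r$slope,
               threshold = r$threshold)
  }))
  rownames(summary) <- NULL
  tests <- anova_tukey(lapply(runs, `[[`, "boot_f1"), alpha = alpha)
  structure(list(summary = summary, tests = tests, runs = runs),
            class = "baseline_comparison")
}

#' @export
print.baseline_comparison <- function(x, ...) {
  cat("Cross-baseline comparison\n")
  print(x$summary, row.names = FALSE, digits = 4)
  cat(sprintf("ANOVA F = %.2f (p = %.3g); Tukey HSD pairs:\n",
              x$tests$f_statistic, x$tests$f_p_value))
  print(x$tests$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}
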