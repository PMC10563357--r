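# Error auditing: confusion partition, additive break-down attributions,
# ordering-averaged (Shapley) attributions, and the relabel-and-retrain
# experiment over the modified baseline definitions.
#
# The value function v(S) is the marginal (interventional) expectation:
# the mean model output over a background sample with the features in S
# fixed to the instance's values. Break-down contributions are the
# sequential conditional differences along one ordering; Shapley
# attributions average them over (sampled) orderings, so additivity
# (intercept + sum of contributions = prediction) holds exactly for both.

#' Partition predictions into TP / FP / TN / FN cohorts
#'
#' @param predicted 0/1 predicted classes (or probabilities with
#'   `threshold`).
#' @param labels 0/1 observed outcomes.
#' @param ids Optional instance identifiers (defaults to indices).
#' @param threshold When supplied, `predicted` is taken as probabilities
#'   and thresholded at `predicted >= threshold`.
#' @return A `confusion_partition` list of the four disjoint, exhaustive id
#'   sets plus `counts`.
#' @export
confusion_partition <- function(predicted, labels, ids = NULL,
                                threshold = NULL) {
  stopifnot(length(predicted) == length(labels))
  if (!is.null(threshold)) predicted <- as.integer(predicted >= threshold)
  ids <- ids %||% seq_along(labels)
  out <- list(tp = ids[predicted == 1 & labels == 1],
              fp = ids[predicted == 1 & labels == 0],
              tn = ids[predicted == 0 & labels == 0],
              fn = ids[predicted == 0 & labels == 1])
  out$counts <- lengths(out[c("tp", "fp", "tn", "fn")])
  structure(out, class = "confusion_partition")
}

#' @noRd
check_attr_inputs <- function(predict_fun, instance, background, ordering) {
  background <- as.data.frame(background)
  stopifnot(nrow(background) > 0)
  instance <- as.data.frame(instance)
  stopifnot(nrow(instance) == 1)
  features <- colnames(background)
  if (!all(ordering %in% features)) {
    stop("ordering contains unknown feature(s): ",
         paste(setdiff(ordering, features), collapse = ", "), call. = FALSE)
  }
  list(background = background, instance = instance, features = features)
}

#' Break-down attribution for one prediction
#'
#' Sequential conditional contributions along one feature ordering:
#' the contribution of the j-th feature is `v(S_j + {j}) - v(S_j)`, where
#' `S_j` holds the features already fixed and `v(S)` is the mean model
#' output over the background sample with the features in `S` set to the
#' instance's values. Contributions depend on the ordering whenever the
#' model has interactions; they always sum to `prediction - intercept`.
#'
#' @param predict_fun Function mapping a feature data.frame to numeric
#'   model outputs.
#' @param instance A single-row data.frame (or named list) of feature
#'   values.
#' @param background Background sample data.frame (e.g. a training-set
#'   subsample).
#' @param ordering Character vector of feature names; defaults to the
#'   background column order.
#' @return An `attribution_report`: `intercept` (mean model output over the
#'   background), `contributions` (named, in `ordering` order),
#'   `prediction`, `ordering`.
#' @export
breakdown_attribution <- function(predict_fun, instance, background,
                                  ordering = NULL) {
  ordering <- ordering %||% colnames(as.data.frame(background))
  ci <- check_attr_inputs(predict_fun, instance, background, ordering)
  cur <- ci$background
  intercept <- mean(predict_fun(cur))
  v_prev <- intercept
  contributions <- stats::setNames(numeric(length(ordering)), ordering)
  for (f in ordering) {
    cur[[f]] <- ci$instance[[f]]
    v <- mean(predict_fun(cur))
    contributions[[f]] <- v - v_prev
    v_prev <- v
  }
  structure(list(intercept = intercept, contributions = contributions,
                 prediction = v_prev, ordering = ordering,
                 order_averaged = FALSE),
            class = "attribution_report")
}

#' Ordering-averaged (Shapley) attribution for one prediction
#'
#' Averages [breakdown_attribution()] contributions over uniformly random
#' feature orderings — the Monte-Carlo estimate of the Shapley values under
#' the marginal value function. Additivity is preserved exactly (each
#' ordering is additive, so their mean is).
#'
#' @inheritParams breakdown_attribution
#' @param n_orderings Number of sampled orderings (>= 1).
#' @param seed RNG seed; fixed seed gives identical attributions.
#' @return An `attribution_report` with order-averaged `contributions`
#'   (named in background column order).
#' @export
shapley_attribution <- function(predict_fun, instance, background,
                                n_orderings = 50, seed = 1L) {
  stopifnot(n_orderings >= 1)
  background <- as.data.frame(background)
  features <- colnames(background)
  set.seed(seed)
  acc <- stats::setNames(numeric(length(features)), features)
  intercept <- NA_real_; prediction <- NA_real_
  for (k in seq_len(n_orderings)) {
    ord <- sample(features)
    bd <- breakdown_attribution(predict_fun, instance, background, ord)
    acc <- acc + bd$contributions[features]
    intercept <- bd$intercept; prediction <- bd$prediction
  }
  structure(list(intercept = intercept, contributions = acc / n_orderings,
                 prediction = prediction, ordering = features,
                 order_averaged = TRUE, n_orderings = n_orderings),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat(sprintf("%s attribution: intercept %.4f, prediction %.4f\n",
              if (isTRUE(x$order_averaged)) "Shapley" else "Break-down",
              x$intercept, x$prediction))
  print(round(sort(x$contributions, decreasing = TRUE), 4))
  invisible(x)
}

#' Global feature importance by mean absolute Shapley attribution
#'
#' @inheritParams shapley_attribution
#' @param instances Data.frame of instances to attribute (e.g. the audited
#'   false-positive cohort).
#' @return Data.frame `feature`, `mean_abs_contribution`, sorted
#'   descending.
#' @export
global_importance <- function(predict_fun, instances, background,
                              n_orderings = 50, seed = 1L) {
  instances <- as.data.frame(instances)
  stopifnot(nrow(instances) > 0)
  features <- colnames(as.data.frame(background))
  acc <- matrix(0, nrow(instances), length(features),
                dimnames = list(NULL, features))
  for (i in seq_len(nrow(instances))) {
    sh <- shapley_attribution(predict_fun, instances[i, , drop = FALSE],
                              background, n_orderings, seed = seed + i)
    acc[i, ] <- sh$contributions[features]
  }
  imp <- colMeans(abs(acc))
  data.frame(feature = names(sort(imp, decreasing = TRUE)),
             mean_abs_contribution = unname(sort(imp, decreasing = TRUE)))
}

#' Relabel-and-retrain experiment over modified baseline definitions
#'
#' Relabels the full synthetic dataset under each modified baseline
#' specification, rebuilds the cohort, retrains / calibrates / thresholds /
#' evaluates the classifier, and reports the metric deltas against the
#' reference run together with the fraction of the reference run's
#' false-positive admissions that become KDIGO-positive under each
#' relabelling (among those still included).
#'
#' @param bundle The `ehr_bundle` the reference run was built on.
#' @param reference An [run_aki_pipeline()] result (provides the FP cohort
#'   and the metrics to compare against).
#' @param methods Modified baseline methods to evaluate.
#' @param family Classifier family. Default the reference's family.
#' @param seed Partition/training seed (defaults to the reference's, so
#'   the split policy is shared).
#' @param ... Passed through to [run_aki_pipeline()].
#' @return A list: `summary` data.frame (per-method metrics, f1 delta and
#'   FP-relabelled fraction) and `runs` (the full per-method pipeline
#'   results).
#' @export
relabel_experiment <- function(bundle, reference,
                               methods = c("M1_min_180to7_or_mdrd",
                                           "M2_min_180to0_or_mdrd",
                                           "M3_mean_180to0_or_mdrd"),
                               family = reference$family,
                               seed = reference$seed, ...) {
  stopifnot(inherits(reference, "aki_run"))
  fp_ids <- reference$fp_ids
  runs <- list()
  rows <- list()
  for (m in methods) {
    run <- run_aki_pipeline(bundle, m, family = family, seed = seed, ...)
    labs <- run$cohort$labels
    fp_now <- labs[labs$admission_id %in% fp_ids &
                     labs$admission_id %in% run$cohort$admission_id, ]
    frac <- if (nrow(fp_now) == 0) NA_real_ else mean(fp_now$outcome_day23)
    rows[[m]] <- data.frame(
      method = m, auc = run$metrics$auc, precision = run$metrics$precision,
      recall = run$metrics$recall, f1 = run$metrics$f1,
      ece = run$ece, brier = run$brier, slope = run$slope,
      f1_delta = run$metrics$f1 - reference$metrics$f1,
      fp_relabelled_positive = frac)
    runs[[m]] <- run
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       runs = runs)
}
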