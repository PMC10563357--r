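# Discrimination metrics, calibration-error metrics and the cross-baseline
# statistical comparison (bootstrap f1 + one-way ANOVA + Tukey HSD).

#' Discriminative metrics at a decision threshold
#'
#' AUC is the rank statistic with tie midpoints (via pROC); precision,
#' recall and f1 are computed at the supplied threshold (predicted positive
#' iff `prob >= threshold`) with the 0/0 -> 0 convention for empty
#' numerators.
#'
#' @param probs Predicted probabilities.
#' @param labels 0/1 outcomes.
#' @param threshold Decision threshold.
#' @return A `metric_report` list: `auc` (NA with a warning when only one
#'   class is present), `precision`, `recall`, `f1`, `threshold` and the
#'   confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
discriminative_metrics <- function(probs, labels, threshold) {
  stopifnot(length(probs) == length(labels))
  auc <- if (length(unique(labels)) < 2) {
    warning("single-class labels: AUC undefined")
    NA_real_
  } else {
    as.numeric(pROC::auc(pROC::roc(response = labels, predictor = probs,
                                   levels = c(0, 1), direction = "<",
                                   quiet = TRUE)))
  }
  pred <- probs >= threshold
  tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1); tn <- sum(!pred & labels == 0)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  structure(list(auc = auc, precision = precision, recall = recall,
                 f1 = f1_from_counts(tp, fp, fn), threshold = threshold,
                 tp = tp, fp = fp, tn = tn, fn = fn),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("AUC %.4f | precision %.4f | recall %.4f | f1 %.4f (threshold %.4f)\n",
              x$auc, x$precision, x$recall, x$f1, x$threshold))
  invisible(x)
}

#' Estimated calibration error
#'
#' Equal-width binning of [0, 1]: `ECE = sum_b (n_b / n) * |mean prob_b -
#' positive fraction_b|`; empty bins contribute 0. Probabilities of exactly
#' 1 fall in the last bin.
#'
#' @param probs Predicted probabilities in [0, 1].
#' @param labels 0/1 outcomes.
#' @param n_bins Number of bins. Default 10.
#' @return ECE in [0, 1].
#' @export
ece <- function(probs, labels, n_bins = 10) {
  stopifnot(all(probs >= 0 & probs <= 1), length(probs) == length(labels))
  bin <- pmin(floor(probs * n_bins) + 1L, n_bins)
  n <- length(probs)
  err <- 0
  for (b in unique(bin)) {
    in_b <- bin == b
    err <- err + sum(in_b) / n * abs(mean(probs[in_b]) - mean(labels[in_b]))
  }
  err
}

#' Brier score
#'
#' Mean squared difference between predicted probability and the 0/1
#' outcome.
#'
#' @inheritParams ece
#' @return Brier score in [0, 1].
#' @export
brier <- function(probs, labels) {
  stopifnot(all(probs >= 0 & probs <= 1), length(probs) == length(labels))
  mean((probs - labels)^2)
}

#' Calibration slope
#'
#' Maximum-likelihood slope of a univariate logistic regression of the
#' outcome on the logit of the predicted probability (probabilities are
#' epsilon-clipped at 1e-6 to keep logits finite). A slope of 1 indicates
#' calibrated spread; < 1 indicates overconfidence.
#'
#' @inheritParams ece
#' @param eps Clipping bound for the logit transform.
#' @return The fitted slope (> 0 for any informative prediction).
#' @export
calibration_slope <- function(probs, labels, eps = 1e-6) {
  stopifnot(length(probs) == length(labels))
  if (length(unique(labels)) < 2) {
    stop("calibration slope requires both classes", call. = FALSE)
  }
  l <- stats::qlogis(clip_prob(probs, eps))
  if (stats::sd(l) == 0) {
    stop("calibration slope undefined for constant probabilities",
         call. = FALSE)
  }
  fit <- suppressWarnings(stats::glm(labels ~ l, family = stats::binomial()))
  if (!fit$converged) warning("calibration-slope fit did not converge")
  unname(stats::coef(fit)[2])
}

#' Bootstrap distribution of the f1 score
#'
#' Resamples the test set with replacement `n_boot` times (default 500
#' replicates, the comparison regime used throughout the package) and
#' computes the f1 at the fixed threshold on each replicate. Both the
#' replicate count and the subsample size are exposed because "a subset of
#' data (n = 500)" admits either reading; the default is 500 replicates of
#' full-size resamples.
#'
#' @param probs Predicted probabilities on the test set.
#' @param threshold Decision threshold.
#' @param labels 0/1 test outcomes.
#' @param n_boot Number of bootstrap replicates. Default 500.
#' @param size Rows drawn per replicate (with replacement). Default
#'   `length(labels)`.
#' @param seed RNG seed.
#' @return Numeric vector of `n_boot` f1 values (replicates with no
#'   predicted or no true positives contribute f1 = 0).
#' @export
bootstrap_f1 <- function(probs, threshold, labels, n_boot = 500,
                         size = NULL, seed = 1L) {
  stopifnot(length(probs) == length(labels), length(labels) > 0, n_boot >= 2)
  size <- size %||% length(labels)
  set.seed(seed)
  vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(length(labels), size, replace = TRUE)
    f1_at(probs[idx], labels[idx], threshold)
  }, numeric(1))
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Fits a one-way ANOVA across the supplied groups (unequal lengths
#' permitted) and runs Tukey's honestly-significant-difference test on all
#' pairs, flagging adjusted p-values at or below `alpha`.
#'
#' @param groups Named list of numeric vectors (e.g. bootstrap f1
#'   distributions per baseline method), each of length >= 2.
#' @param alpha Significance level. Default 0.05.
#' @return A list: `f_statistic`, `f_p_value` and `pairwise` (data.frame
#'   with `pair`, `diff`, `lwr`, `upr`, `p_adj`, `significant`).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2, alpha > 0, alpha < 1)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  if (any(lengths(groups) < 2)) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (any(vapply(groups, stats::sd, numeric(1)) == 0)) {
    warning("zero-variance group(s) present")
  }
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), lengths(groups)),
                                  levels = names(groups)))
  fit <- stats::aov(value ~ group, data = df)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  pairwise <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                         lwr = tk[, "lwr"], upr = tk[, "upr"],
                         p_adj = tk[, "p adj"],
                         significant = tk[, "p adj"] <= alpha,
                         row.names = NULL)
  list(f_statistic = s[["F value"]][1], f_p_value = s[["Pr(>F)"]][1],
       pairwise = pairwise)
}
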