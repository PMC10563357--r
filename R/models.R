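# Classifier training per baseline-labelled cohort: stratified 60/20/20
# split, 5-fold CV tuned for f1 with positive-class up-sampling confined to
# the training part of each fold, Platt calibration on the validation
# partition, and an f1-optimal decision threshold selected on validation.

#' Stratified train/validation/test partition tags
#'
#' @param y Outcome vector (used for stratification).
#' @param ratios Named or ordered fractions for train, validation, test;
#'   must sum to 1. Default 60/20/20.
#' @param seed RNG seed; identical seed implies identical tags.
#' @param stratified Stratify on `y`. Default TRUE.
#' @return Character vector of `"train"`, `"validation"`, `"test"` tags.
#' @export
split_data <- function(y, ratios = c(train = 0.6, validation = 0.2,
                                     test = 0.2),
                       seed = 1L, stratified = TRUE) {
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-8)
  n <- length(y)
  stopifnot(n >= 5)
  tags <- character(n)
  set.seed(seed)
  groups <- if (stratified) split(seq_len(n), y) else list(seq_len(n))
  for (idx in groups) {
    idx <- idx[sample.int(length(idx))]
    m <- length(idx)
    n_tr <- round(m * ratios[[1]])
    n_va <- min(round(m * ratios[[2]]), m - n_tr)
    tags[idx[seq_len(n_tr)]] <- "train"
    if (n_va > 0) tags[idx[n_tr + seq_len(n_va)]] <- "validation"
    if (m - n_tr - n_va > 0) tags[idx[(n_tr + n_va + 1):m]] <- "test"
  }
  for (p in c("train", "validation", "test")) {
    if (length(unique(y[tags == p])) < 2) {
      warning("partition '", p, "' is degenerate in the outcome")
    }
  }
  tags
}

# duplicate positive rows (with replacement) until classes are 1:1;
# never touches negatives and never removes rows
#' @noRd
upsample_rows <- function(idx, y) {
  pos <- idx[y[idx] == 1]
  neg <- idx[y[idx] == 0]
  need <- length(neg) - length(pos)
  if (need <= 0 || length(pos) == 0) return(idx)
  c(idx, sample(pos, need, replace = TRUE))
}

#' Default hyperparameter grids
#'
#' Small published-default grids per family. The gradient-boosting grid
#' includes a configuration mapped from a reported leaf-wise
#' parameterisation (`num_leaves` -> `max_leaves` with loss-guided growth,
#' `min_child_samples` approximated by `min_child_weight`, which is the
#' nearest equivalent this boosting implementation exposes).
#'
#' @param family One of `"LR"`, `"RF"`, `"XGB"`, `"ANN"`.
#' @return A list of named parameter lists.
#' @export
default_grid <- function(family = c("LR", "RF", "XGB", "ANN")) {
  family <- match.arg(family)
  switch(family,
    LR = list(list()),
    RF = list(list(num_trees = 300, mtry = NULL),
              list(num_trees = 300, mtry_frac = 0.4)),
    XGB = list(
      list(eta = 0.1, max_depth = 3, nrounds = 100, subsample = 1,
           min_child_weight = 1, alpha = 0, lambda = 1),
      list(eta = 0.1, max_depth = 6, nrounds = 100, subsample = 1,
           min_child_weight = 1, alpha = 0, lambda = 1),
      list(eta = 0.1, max_depth = 0, nrounds = 200, subsample = 0.2,
           min_child_weight = 1, alpha = 50, lambda = 0,
           grow_policy = "lossguide", max_leaves = 10)),
    ANN = list(list(size = 4, decay = 0.1, maxit = 150),
               list(size = 8, decay = 0.01, maxit = 150)))
}

#' @noRd
fit_family <- function(family, x, y, params, seed) {
  switch(family,
    LR = {
      df <- as.data.frame(x)
      df$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = df,
                                  family = stats::binomial()))
    },
    RF = {
      mtry <- params$mtry
      if (!is.null(params$mtry_frac)) {
        mtry <- max(1L, floor(params$mtry_frac * ncol(x)))
      }
      ranger::ranger(x = as.data.frame(x), y = factor(y, levels = c(0, 1)),
                     probability = TRUE,
                     num.trees = params$num_trees %||% 300,
                     mtry = mtry, seed = seed, num.threads = 1)
    },
    XGB = {
      p <- list(objective = "binary:logistic", eta = params$eta %||% 0.1,
                max_depth = params$max_depth %||% 6,
                subsample = params$subsample %||% 1,
                min_child_weight = params$min_child_weight %||% 1,
                alpha = params$alpha %||% 0, lambda = params$lambda %||% 1,
                nthread = 1)
      if (!is.null(params$grow_policy)) {
        p$grow_policy <- params$grow_policy
        p$max_leaves <- params$max_leaves
        p$tree_method <- "hist"
      }
      dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1)
      xgboost::xgb.train(params = p, data = dtrain,
                         nrounds = params$nrounds %||% 100, verbose = 0)
    },
    ANN = {
      set.seed(seed)
      nnet::nnet(x = as.matrix(x), y = y, size = params$size %||% 4,
                 decay = params$decay %||% 0.1,
                 maxit = params$maxit %||% 150,
                 entropy = TRUE, trace = FALSE, MaxNWts = 5000)
    },
    stop("unknown model family: ", family, call. = FALSE))
}

#' @noRd
predict_family <- function(family, fit, x) {
  switch(family,
    LR = as.numeric(suppressWarnings(
      stats::predict(fit, newdata = as.data.frame(x), type = "response"))),
    RF = ranger::predictions(stats::predict(fit,
                                            data = as.data.frame(x)))[, "1"],
    XGB = as.numeric(stats::predict(fit, as.matrix(x))),
    ANN = as.numeric(stats::predict(fit, as.matrix(x))))
}

#' Tune and train a classifier with fold-internal up-sampling
#'
#' Grid search by stratified 5-fold cross-validation on the training
#' partition: within each fold, positive rows are up-sampled to 1:1 in the
#' fold's training part ONLY (fold validation parts are never duplicated),
#' the candidate configuration is fitted, and its f1 at probability 0.5 on
#' the fold's held-out part is recorded. The configuration with the best
#' mean fold f1 is refitted on the up-sampled full training partition.
#'
#' @param x Feature matrix or data.frame (training partition rows).
#' @param y 0/1 outcome aligned with `x`; both classes required.
#' @param family One of `"LR"`, `"RF"`, `"XGB"`, `"ANN"`.
#' @param grid List of parameter lists; default [default_grid()].
#' @param folds Number of CV folds. Default 5.
#' @param seed RNG seed controlling folds, up-sampling and stochastic fits.
#' @return An `aki_model`: `family`, `fit`, `params`, `cv` (mean fold f1
#'   per configuration), `feature_names`.
#' @export
tune_and_train <- function(x, y, family = c("LR", "RF", "XGB", "ANN"),
                           grid = NULL, folds = 5, seed = 1L) {
  family <- match.arg(family)
  x <- as.data.frame(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    stop("training data contains a single class", call. = FALSE)
  }
  grid <- grid %||% default_grid(family)

  set.seed(seed)
  fold_id <- integer(length(y))
  for (cl in unique(y)) {
    rows <- which(y == cl)
    fold_id[rows] <- sample(rep_len(seq_len(folds), length(rows)))
  }

  mean_f1 <- numeric(length(grid))
  for (g in seq_along(grid)) {
    f1s <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- which(fold_id != f)
      va <- which(fold_id == f)
      set.seed(seed * 100 + f)
      up <- upsample_rows(tr, y)
      fit <- fit_family(family, x[up, , drop = FALSE], y[up], grid[[g]],
                        seed = seed + f)
      p <- predict_family(family, fit, x[va, , drop = FALSE])
      f1s[f] <- f1_at(p, y[va], 0.5)
    }
    mean_f1[g] <- mean(f1s)
  }
  best <- which.max(mean_f1)
  set.seed(seed * 100)
  up <- upsample_rows(seq_along(y), y)
  fit <- fit_family(family, x[up, , drop = FALSE], y[up], grid[[best]],
                    seed = seed)
  structure(list(family = family, fit = fit, params = grid[[best]],
                 cv = data.frame(config = seq_along(grid),
                                 mean_f1 = mean_f1),
                 feature_names = colnames(x)),
            class = "aki_model")
}

#' @export
predict.aki_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)[object$feature_names]
  predict_family(object$family, object$fit, newdata)
}

#' Calibrate a fitted classifier on the validation partition
#'
#' Fits a monotone map from raw classifier scores to calibrated
#' probabilities using validation data only. The default is parametric
#' sigmoid (Platt) scaling — a univariate logistic regression of the
#' outcome on the score logit; `"isotonic"` (pool-adjacent-violators) is
#' available behind the flag. A constant-score classifier yields a
#' degenerate identity map with a warning.
#'
#' @param model An [tune_and_train()] `aki_model`.
#' @param x_val,y_val Validation features and 0/1 outcomes (both classes
#'   required).
#' @param method `"platt"` (default) or `"isotonic"`.
#' @return A `calibrated_model` wrapping the classifier and the calibration
#'   map; the decision threshold slot is filled by [select_threshold()].
#' @export
calibrate <- function(model, x_val, y_val, method = c("platt", "isotonic")) {
  method <- match.arg(method)
  if (length(unique(y_val)) < 2) {
    stop("validation partition must contain both classes", call. = FALSE)
  }
  s <- predict(model, x_val)
  if (stats::sd(s) == 0) {
    warning("constant classifier scores; calibration map degenerates to identity")
    map <- list(type = "identity")
  } else if (method == "platt") {
    l <- stats::qlogis(clip_prob(s))
    fit <- suppressWarnings(stats::glm(y_val ~ l, family = stats::binomial()))
    map <- list(type = "platt", a = unname(stats::coef(fit)[1]),
                b = unname(stats::coef(fit)[2]))
  } else {
    ord <- order(s)
    iso <- stats::isoreg(s[ord], y_val[ord])
    map <- list(type = "isotonic", x = iso$x, yf = iso$yf)
  }
  structure(list(model = model, map = map, threshold = NA_real_),
            class = "calibrated_model")
}

#' Calibrated probabilities
#'
#' @param object A `calibrated_model`.
#' @param newdata Feature rows.
#' @param ... Unused.
#' @return Calibrated probabilities in [0, 1].
#' @export
predict.calibrated_model <- function(object, newdata, ...) {
  s <- predict(object$model, newdata)
  apply_calibration(object, s)
}

#' @rdname predict.calibrated_model
#' @param raw_scores Raw classifier scores to map (alternative entry point
#'   when scores are already in hand).
#' @export
apply_calibration <- function(object, raw_scores) {
  map <- object$map
  switch(map$type,
    identity = raw_scores,
    platt = stats::plogis(map$a + map$b * stats::qlogis(clip_prob(raw_scores))),
    isotonic = {
      yf <- stats::approx(map$x, map$yf, xout = raw_scores, rule = 2,
                          ties = "ordered")$y
      pmin(pmax(yf, 0), 1)
    })
}

#' Select the f1-optimal decision threshold
#'
#' Exhaustive sweep over all distinct probability values; among thresholds
#' attaining the maximal f1 the largest is returned (ties broken toward
#' fewer positive calls).
#'
#' @param probs Calibrated probabilities (validation partition).
#' @param labels 0/1 outcomes; both classes are expected for a meaningful
#'   optimum but the sweep itself is defined whenever positives exist.
#' @return The selected threshold.
#' @export
select_threshold <- function(probs, labels) {
  stopifnot(length(probs) == length(labels), length(probs) > 0)
  cand <- sort(unique(probs))
  f1s <- vapply(cand, function(t) f1_at(probs, labels, t), numeric(1))
  max(cand[f1s == max(f1s)])
}
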