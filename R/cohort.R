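# Cohort construction: exclusions, first-24h aggregation, missingness
# filtering, chained-equations imputation and [0,1] normalisation.

#' Apply the ordered exclusion pipeline
#'
#' Filters admissions in a fixed, logged order: (1) adults only (age >= 18);
#' (2) first ICU admission per patient; (3) no maintenance renal
#' replacement therapy; (4) at least one creatinine measurement on each of
#' days 1, 2 and 3; (5) no AKI detected on day 1 (the screen recorded by
#' [label_admissions()]). Each step's exclusion count is recorded so any
#' order-dependence is visible.
#'
#' @param bundle An `ehr_bundle`.
#' @param labels A [label_admissions()] table for the active baseline
#'   method (used by step 5).
#' @return A list: `included_ids` (admission ids surviving all steps) and
#'   `audit` (data.frame with `step`, `n_before`, `n_excluded`, `n_after`).
#' @export
apply_exclusions <- function(bundle, labels) {
  adm <- bundle$admissions
  pat <- bundle$patients
  scr <- bundle$icu_events[bundle$icu_events$variable == "creatinine", ]

  steps <- character(0); n_before <- integer(0); n_excl <- integer(0)
  keep <- adm$admission_id
  log_step <- function(name, kept) {
    steps <<- c(steps, name)
    n_before <<- c(n_before, length(keep))
    n_excl <<- c(n_excl, length(keep) - length(kept))
    keep <<- kept
  }

  age <- pat$age[match(adm$patient_id, pat$patient_id)]
  log_step("age >= 18", keep[age[match(keep, adm$admission_id)] >= 18])

  sub <- adm[adm$admission_id %in% keep, ]
  sub <- sub[order(sub$patient_id, sub$icu_intime_day, sub$admission_id), ]
  first <- sub$admission_id[!duplicated(sub$patient_id)]
  log_step("first ICU admission", keep[keep %in% first])

  rrt <- adm$rrt[match(keep, adm$admission_id)]
  log_step("no maintenance RRT", keep[!rrt])

  day <- findInterval(scr$offset_h, c(0, 24, 48, 72))
  covered <- tapply(day, scr$admission_id,
                    function(d) all(1:3 %in% d))
  ok_ids <- as.numeric(names(covered))[covered]
  log_step("sCr on days 1-3", keep[keep %in% ok_ids])

  d1 <- labels$day1_aki[match(keep, labels$admission_id)]
  log_step("no day-1 AKI", keep[!is.na(d1) & !d1])

  audit <- data.frame(step = steps, n_before = n_before,
                      n_excluded = n_excl,
                      n_after = n_before - n_excl)
  list(included_ids = keep, audit = audit)
}

#' Aggregate first-24h events into a per-admission feature table
#'
#' Builds the model-ready predictor roster: per-variable minimum and
#' maximum over first-24h events, mean urine output, demographics with
#' one-hot ethnicity (no reference category dropped), binary comorbidity /
#' history flags, and the CKD-EPI eGFR computed from the day-1 minimum
#' creatinine with age and sex.
#'
#' @param bundle An `ehr_bundle`.
#' @param included_ids Admissions to aggregate (from [apply_exclusions()]).
#' @return A data.frame keyed by `admission_id`; unmeasured variables are
#'   `NA`.
#' @export
aggregate_features <- function(bundle, included_ids) {
  stopifnot(length(included_ids) > 0)
  adm <- bundle$admissions[match(included_ids, bundle$admissions$admission_id), ]
  pat <- bundle$patients[match(adm$patient_id, bundle$patients$patient_id), ]

  ev <- bundle$icu_events
  ev <- ev[ev$admission_id %in% included_ids & ev$offset_h >= 0 &
             ev$offset_h < 24, ]
  fa <- factor(ev$admission_id, levels = included_ids)
  fv <- factor(ev$variable)
  mins <- tapply(ev$value, list(fa, fv), min)
  maxs <- tapply(ev$value, list(fa, fv), max)
  colnames(mins) <- paste0(colnames(mins), "_min")
  colnames(maxs) <- paste0(colnames(maxs), "_max")

  uo <- bundle$urine_output
  uo <- uo[uo$admission_id %in% included_ids & uo$offset_h < 24, ]
  urine_mean <- tapply(uo$volume_ml, factor(uo$admission_id,
                                            levels = included_ids), mean)

  eth_levels <- sort(unique(bundle$patients$ethnicity))
  eth <- vapply(eth_levels,
                function(e) as.numeric(pat$ethnicity == e),
                numeric(nrow(pat)))
  colnames(eth) <- paste0("ethnicity_", eth_levels)

  com <- bundle$comorbidities[
    match(included_ids, bundle$comorbidities$admission_id),
    setdiff(names(bundle$comorbidities), "admission_id"), drop = FALSE]

  scr_min <- mins[, "creatinine_min"]
  feats <- data.frame(admission_id = included_ids,
                      age = pat$age,
                      sex_female = as.numeric(pat$sex == "female"),
                      eth, mins, maxs,
                      urine_output_mean = as.numeric(urine_mean),
                      egfr_ckdepi = ckdepi_egfr(scr_min, pat$age, pat$sex),
                      com,
                      check.names = FALSE)
  rownames(feats) <- NULL
  feats
}

#' Drop columns exceeding a missingness threshold
#'
#' Removes feature columns whose missing fraction is strictly greater than
#' `threshold` (so a column at exactly the threshold is retained).
#'
#' @param features Feature data.frame (the `admission_id` column is never
#'   dropped).
#' @param threshold Missing-fraction cutoff in (0, 1). Default 0.20.
#' @return A list: `features` (reduced) and `dropped` (named numeric vector
#'   of the removed columns' missing fractions).
#' @export
filter_missing_columns <- function(features, threshold = 0.20) {
  stopifnot(threshold > 0, threshold < 1)
  cand <- setdiff(names(features), "admission_id")
  frac <- vapply(features[cand], function(x) mean(is.na(x)), numeric(1))
  gone <- frac[frac > threshold]
  list(features = features[, !names(features) %in% names(gone), drop = FALSE],
       dropped = gone)
}

#' Chained-equations imputation with a train-only fit
#'
#' Deterministic chained-equations imputation: missing cells are
#' initialised to the fit-partition column means, then each incomplete
#' column is repeatedly regressed (ordinary least squares) on all other
#' feature columns using the fit rows only, and its missing cells are
#' replaced by the regression predictions. The fitted per-column models
#' from the final sweep are then applied, with the same sweep structure, to
#' the non-fit rows, so no information flows from validation/test rows into
#' the imputation model.
#'
#' @param features Feature data.frame (numeric columns; `admission_id`
#'   passed through untouched).
#' @param fit_rows Logical or integer index of the rows (training
#'   partition) the imputation models are fitted on.
#' @param iterations Number of sweeps. Default 5.
#' @param seed Kept for interface stability; the regression imputer is
#'   fully deterministic and does not consume random numbers.
#' @return A list: `features` (completed), `models` (per-column fitted
#'   coefficient vectors), `imputed_fraction` (per column).
#' @export
impute_chained <- function(features, fit_rows, iterations = 5, seed = NULL) {
  id <- features$admission_id
  x <- as.data.frame(features[setdiff(names(features), "admission_id")])
  if (is.logical(fit_rows)) fit_rows <- which(fit_rows)
  miss <- vapply(x, function(col) mean(is.na(col)), numeric(1))
  incomplete <- names(miss)[miss > 0]
  for (cn in incomplete) {
    if (all(is.na(x[fit_rows, cn]))) {
      stop("column with zero observed fit-partition values: ", cn,
           call. = FALSE)
    }
  }
  na_mask <- lapply(x, is.na)
  # initialise with fit-partition means
  for (cn in incomplete) {
    x[[cn]][na_mask[[cn]]] <- mean(x[fit_rows, cn], na.rm = TRUE)
  }
  models <- list()
  if (length(incomplete) > 0) {
    xm <- as.matrix(x)
    preds <- setdiff(colnames(xm), incomplete)
    for (it in seq_len(iterations)) {
      for (cn in incomplete) {
        others <- setdiff(colnames(xm), cn)
        obs <- intersect(fit_rows, which(!na_mask[[cn]]))
        X <- cbind(1, xm[obs, others, drop = FALSE])
        # least squares with a small ridge (scaled to the Gram diagonal)
        # so exactly collinear one-hot blocks stay solvable
        XtX <- crossprod(X)
        XtX <- XtX + diag(1e-6 * mean(diag(XtX)), ncol(X))
        beta <- solve(XtX, crossprod(X, xm[obs, cn]))
        models[[cn]] <- stats::setNames(as.numeric(beta), c("(Intercept)", others))
        # fill fit-partition holes in their own batch so the training-side
        # numerics are bit-for-bit independent of the held-out rows
        hole <- which(na_mask[[cn]])
        for (h in list(intersect(hole, fit_rows), setdiff(hole, fit_rows))) {
          if (length(h) > 0) {
            xm[h, cn] <- cbind(1, xm[h, others, drop = FALSE]) %*% beta
          }
        }
      }
    }
    x <- as.data.frame(xm)
  }
  out <- cbind(data.frame(admission_id = id), x)
  names(out) <- names(features)
  list(features = out, models = models, imputed_fraction = miss)
}

#' Min-max normalisation fitted on the training partition
#'
#' Scales each numeric feature column to [0, 1] using the fit-partition
#' minimum and range; out-of-range values in other partitions are clipped
#' to [0, 1] so the feature-range contract holds everywhere.
#' Zero-variance columns are mapped to 0 with a warning.
#'
#' @inheritParams impute_chained
#' @return A list: `features` (scaled) and `params` (data.frame of
#'   per-column `min` and `range`).
#' @export
normalize_features <- function(features, fit_rows) {
  if (is.logical(fit_rows)) fit_rows <- which(fit_rows)
  cols <- setdiff(names(features), "admission_id")
  mins <- vapply(features[fit_rows, cols, drop = FALSE], min, numeric(1))
  maxs <- vapply(features[fit_rows, cols, drop = FALSE], max, numeric(1))
  rng <- maxs - mins
  if (any(rng == 0)) {
    warning("zero-variance column(s) mapped to 0: ",
            paste(cols[rng == 0], collapse = ", "))
  }
  for (j in seq_along(cols)) {
    cn <- cols[j]
    if (rng[j] == 0) {
      features[[cn]] <- 0
    } else {
      features[[cn]] <- pmin(pmax((features[[cn]] - mins[j]) / rng[j], 0), 1)
    }
  }
  list(features = features,
       params = data.frame(column = cols, min = mins, range = rng,
                           row.names = NULL))
}

#' Build a model-ready labelled cohort for one baseline method
#'
#' Runs the full construction chain: KDIGO labelling under `method`,
#' ordered exclusions, first-24h aggregation, outcome attachment (AKI first
#' detected on day 2 or 3), stratified 60/20/20 partitioning, the
#' strict-20% missingness filter, train-only chained-equations imputation
#' and train-only min-max scaling.
#'
#' @param bundle An `ehr_bundle`.
#' @param method One of [baseline_methods()].
#' @param seed Partition seed.
#' @param split_ratios Train/validation/test fractions (sum to 1).
#' @param missing_threshold Column-wise missingness cutoff. Default 0.20.
#' @param impute_iterations Chained-equation sweeps. Default 5.
#' @param thresholds [kdigo_thresholds()].
#' @return An `aki_cohort`: `features` (normalised numeric data.frame, no
#'   id column), `admission_id`, `outcome` (0/1), `partition`
#'   (train/validation/test), `labels`, `audit`, `dropped_columns`,
#'   `scaler`, `imputer`, `method`.
#' @export
build_cohort <- function(bundle, method, seed = 1L,
                         split_ratios = c(train = 0.6, validation = 0.2,
                                          test = 0.2),
                         missing_threshold = 0.20, impute_iterations = 5,
                         thresholds = kdigo_thresholds()) {
  labels <- label_admissions(bundle, method, thresholds)
  excl <- apply_exclusions(bundle, labels)
  if (length(excl$included_ids) == 0L) {
    warning("no admissions survive the exclusion pipeline")
    return(structure(list(features = NULL, admission_id = integer(0),
                          outcome = integer(0), partition = character(0),
                          labels = labels, audit = excl$audit,
                          method = method),
                     class = "aki_cohort"))
  }
  feats <- aggregate_features(bundle, excl$included_ids)
  lab_row <- labels[match(excl$included_ids, labels$admission_id), ]
  outcome <- as.integer(lab_row$outcome_day23)

  partition <- split_data(outcome, ratios = split_ratios, seed = seed)
  filt <- filter_missing_columns(feats, missing_threshold)
  imp <- impute_chained(filt$features, fit_rows = partition == "train",
                        iterations = impute_iterations)
  scl <- normalize_features(imp$features, fit_rows = partition == "train")

  features <- scl$features[setdiff(names(scl$features), "admission_id")]
  structure(list(features = features,
                 admission_id = excl$included_ids,
                 outcome = outcome, partition = partition,
                 labels = labels, audit = excl$audit,
                 dropped_columns = filt$dropped,
                 scaler = scl$params, imputer = imp$models,
                 method = method),
            class = "aki_cohort")
}

#' @export
print.aki_cohort <- function(x, ...) {
  cat(sprintf("AKI cohort (%s): %d admissions, %d features, %.2f%% AKI\n",
              x$method, length(x$admission_id),
              if (is.null(x$features)) 0 else ncol(x$features),
              100 * mean(x$outcome)))
  print(x$audit, row.names = FALSE)
  invisible(x)
}
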