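# Six baseline serum-creatinine estimators.
#
# B1: minimum sCr in the first 24 h of ICU admission.
# B2: MDRD backward value as a day-1 AKI screen, then the day-1 minimum as
#     the working baseline (explicit two-stage contract).
# B3: mean of pre-ICU sCr in the 180-to-7-days-before window, falling back
#     to the MDRD backward value when the window is empty.
# M1/M2/M3: the modified variants (min 180->7, min 180->0, mean 180->0),
#     all with the same formula fallback.

#' Baseline estimation method names
#' @return Character vector of the six supported method identifiers.
#' @export
baseline_methods <- function() {
  c("B1_min_first24h", "B2_mdrd_then_min24h", "B3_mean_180to7_or_mdrd",
    "M1_min_180to7_or_mdrd", "M2_min_180to0_or_mdrd", "M3_mean_180to0_or_mdrd")
}

#' Baseline estimation specification
#'
#' The method name fully determines the pre-ICU window and the aggregator.
#' A pre-ICU measurement taken `d` days before ICU admission is in window
#' `[start, end]` iff `end <= d <= start` (so "180 to 0 days" includes
#' same-day draws strictly before ICU admission, while "180 to 7 days"
#' excludes the final week).
#'
#' @param method One of [baseline_methods()].
#' @return A `baseline_spec` with fields `method`, `window`
#'   (`c(start, end)` in days before admission, or `NULL` for the first-24h
#'   methods) and `aggregator` (`"min"`, `"mean"` or `NA`).
#' @export
baseline_spec <- function(method = baseline_methods()) {
  method <- match.arg(method)
  spec <- switch(method,
    B1_min_first24h        = list(window = NULL,        aggregator = NA_character_),
    B2_mdrd_then_min24h    = list(window = NULL,        aggregator = NA_character_),
    B3_mean_180to7_or_mdrd = list(window = c(180, 7),   aggregator = "mean"),
    M1_min_180to7_or_mdrd  = list(window = c(180, 7),   aggregator = "min"),
    M2_min_180to0_or_mdrd  = list(window = c(180, 0),   aggregator = "min"),
    M3_mean_180to0_or_mdrd = list(window = c(180, 0),   aggregator = "mean"))
  structure(c(list(method = method), spec), class = "baseline_spec")
}

#' Estimate the baseline serum creatinine for one admission
#'
#' Applies the requested estimation method to one admission's ICU
#' creatinine series, pre-ICU creatinine history and demographics. The
#' windowed methods aggregate the pre-ICU values whose offsets fall in the
#' spec's window and fall back to [backward_mdrd()] iff that set is empty.
#' The first-24h methods require at least one day-1 in-ICU creatinine;
#' when none exists the admission is signalled ineligible (`value = NA`,
#' `source = "ineligible"`) rather than silently imputed.
#'
#' For `B2_mdrd_then_min24h` the result carries both stages: the returned
#' `value` is the working baseline (day-1 minimum) and `screening_value`
#' holds the backward-MDRD creatinine used only to flag day-1 AKI for
#' exclusion.
#'
#' @param spec A [baseline_spec()] (or a method name).
#' @param icu_offset_h,icu_scr In-ICU creatinine offsets (hours from ICU
#'   admission) and values (mg/dL).
#' @param preicu_days_before,preicu_scr Pre-ICU creatinine history: offsets
#'   in days before ICU admission (>= 0) and values (mg/dL).
#' @param age,sex Demographics for the formula fallback.
#' @return A `baseline_result`: `value` (mg/dL), `source` (one of
#'   `"observed_preicu"`, `"formula_imputed"`, `"first24h_min"`,
#'   `"ineligible"`), `n_values_used`, `screening_value` (B2 only) and
#'   `method`.
#' @export
estimate_baseline <- function(spec, icu_offset_h = numeric(0),
                              icu_scr = numeric(0),
                              preicu_days_before = numeric(0),
                              preicu_scr = numeric(0),
                              age = NULL, sex = NULL) {
  if (is.character(spec)) spec <- baseline_spec(spec)
  stopifnot(inherits(spec, "baseline_spec"))
  res <- function(value, source, n, screening = NULL) {
    structure(list(value = value, source = source, n_values_used = n,
                   screening_value = screening, method = spec$method),
              class = "baseline_result")
  }

  if (spec$method %in% c("B1_min_first24h", "B2_mdrd_then_min24h")) {
    d1 <- icu_scr[icu_offset_h >= 0 & icu_offset_h < 24]
    if (length(d1) == 0L) return(res(NA_real_, "ineligible", 0L))
    working <- min(d1)
    if (spec$method == "B1_min_first24h") {
      return(res(working, "first24h_min", length(d1)))
    }
    return(res(working, "first24h_min", length(d1),
               screening = backward_mdrd(age, sex)))
  }

  w <- spec$window
  keep <- preicu_days_before >= w[2] & preicu_days_before <= w[1]
  vals <- preicu_scr[keep]
  if (length(vals) == 0L) {
    return(res(backward_mdrd(age, sex), "formula_imputed", 0L))
  }
  agg <- if (spec$aggregator == "mean") mean(vals) else min(vals)
  res(agg, "observed_preicu", length(vals))
}

#' Label every admission of a bundle under one baseline method
#'
#' Estimates each admission's baseline under `method`, runs the KDIGO
#' labeller against it, and computes the day-1 AKI screen (for
#' `B2_mdrd_then_min24h` the screen uses the backward-MDRD value; for all
#' other methods it is the labeller's own day-1 detection).
#'
#' @param bundle An [generate_population()] EHR bundle.
#' @param method One of [baseline_methods()], or `"truth"` to label against
#'   the generator's latent true baselines (test/diagnostic use).
#' @param thresholds A [kdigo_thresholds()] object.
#' @return A data.frame with one row per admission: `admission_id`,
#'   `baseline_value`, `baseline_source`, `n_values_used`, `flagged`,
#'   `first_day`, `criterion`, `day1_aki` and `outcome_day23`.
#' @export
label_admissions <- function(bundle, method, thresholds = kdigo_thresholds()) {
  stopifnot(inherits(bundle, "ehr_bundle"))
  adm <- bundle$admissions
  pat <- bundle$patients[match(adm$patient_id, bundle$patients$patient_id), ]
  scr_ev <- bundle$icu_events[bundle$icu_events$variable == "creatinine", ]
  scr_by_adm <- split(scr_ev[c("offset_h", "value")], scr_ev$admission_id)
  pre_by_adm <- split(bundle$preicu_labs[c("days_before", "scr")],
                      bundle$preicu_labs$admission_id)
  truth_base <- if (identical(method, "truth")) {
    bundle$truth$true_baseline[match(adm$admission_id, bundle$truth$admission_id)]
  }

  n <- nrow(adm)
  out <- data.frame(admission_id = adm$admission_id,
                    baseline_value = NA_real_,
                    baseline_source = NA_character_,
                    n_values_used = NA_integer_,
                    flagged = NA, first_day = NA_integer_,
                    criterion = NA_character_, day1_aki = NA,
                    outcome_day23 = NA)
  for (i in seq_len(n)) {
    id <- as.character(adm$admission_id[i])
    s <- scr_by_adm[[id]]
    if (is.null(s) || nrow(s) == 0L) next
    # renal equations are adult-only; minors are excluded from cohorts anyway
    if (!identical(method, "truth") && pat$age[i] < 18) next
    p <- pre_by_adm[[id]]
    if (identical(method, "truth")) {
      est <- structure(list(value = truth_base[i], source = "truth",
                            n_values_used = NA_integer_,
                            screening_value = NULL, method = "truth"),
                       class = "baseline_result")
    } else {
      est <- estimate_baseline(baseline_spec(method),
                               icu_offset_h = s$offset_h, icu_scr = s$value,
                               preicu_days_before = p$days_before %||% numeric(0),
                               preicu_scr = p$scr %||% numeric(0),
                               age = pat$age[i], sex = pat$sex[i])
    }
    out$baseline_source[i] <- est$source
    out$n_values_used[i] <- est$n_values_used
    if (est$source == "ineligible") next
    out$baseline_value[i] <- est$value
    lab <- detect_aki(s$offset_h, s$value, est$value, thresholds)
    out$flagged[i] <- lab$flagged
    out$first_day[i] <- lab$first_detection_day
    out$criterion[i] <- lab$criterion
    out$day1_aki[i] <- if (!is.null(est$screening_value)) {
      day1_aki_flag(s$offset_h, s$value, est$screening_value, thresholds)
    } else {
      isTRUE(lab$first_detection_day == 1L)
    }
    out$outcome_day23[i] <- lab$flagged && lab$first_detection_day %in% c(2L, 3L)
  }
  out
}
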