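# KDIGO serum-creatinine AKI detection over irregular measurement series.
#
# Two criteria, both inclusive:
#   absolute: a rise of >= 0.3 mg/dL relative to the rolling minimum of the
#             preceding 48 h within the same admission;
#   ratio:    a value >= 1.5x the admission's baseline creatinine within
#             7 days of ICU admission.
# Detection is restricted to triggering offsets in days 1-3 (the label
# window: the day-1 flag drives exclusion, days 2-3 are the outcome).

# shared numeric slack so exact-threshold cases (e.g. 0.9/0.6) are inclusive
.KDIGO_TOL <- 1e-9

#' KDIGO serum-creatinine thresholds
#'
#' @param absolute_rise Absolute rise threshold, mg/dL. Default 0.3.
#' @param absolute_window Rolling window for the absolute criterion, hours.
#'   Default 48.
#' @param ratio_rise Ratio threshold relative to baseline. Default 1.5.
#' @param ratio_window Ratio criterion window, days from ICU admission.
#'   Default 7.
#' @return An object of class `kdigo_thresholds`.
#' @export
kdigo_thresholds <- function(absolute_rise = 0.3, absolute_window = 48,
                             ratio_rise = 1.5, ratio_window = 7) {
  stopifnot(absolute_rise > 0, absolute_window > 0,
            ratio_rise > 1, ratio_window > 0)
  structure(list(absolute_rise = absolute_rise,
                 absolute_window = absolute_window,
                 ratio_rise = ratio_rise,
                 ratio_window = ratio_window),
            class = "kdigo_thresholds")
}

#' Detect AKI from a creatinine series under the KDIGO sCr criteria
#'
#' The absolute criterion fires at a measurement time t iff
#' `scr(t) - min{scr(u): t - 48h < u <= t}` is at least 0.3 mg/dL, with the
#' rolling minimum taken over in-ICU measurements of the same admission.
#' The ratio criterion fires at t iff t is within 7 days of ICU admission
#' and `scr(t) / baseline >= 1.5`. Both thresholds are inclusive. "Day d"
#' means offsets in `[24*(d-1), 24*d)` hours from ICU admission; the label
#' reports the day block of the earliest firing measurement within days
#' 1 to `detection_days`.
#'
#' @param offset_h Measurement offsets in hours from ICU admission (>= 0).
#' @param scr Serum creatinine values, mg/dL, aligned with `offset_h`.
#' @param baseline Baseline creatinine, mg/dL, > 0 (a number or a
#'   [estimate_baseline()] result).
#' @param thresholds A [kdigo_thresholds()] object.
#' @param detection_days Last day block eligible to trigger a label.
#'   Default 3.
#' @return An `aki_label` list: `flagged`, `first_detection_day` (integer or
#'   `NA`), `criterion` (`"absolute"`, `"ratio"`, `"both"` or `"none"`) and
#'   `trigger_offset_h`.
#' @examples
#' detect_aki(c(2, 30), c(1.0, 1.3), baseline = 1.0) # absolute, day 2
#' @export
detect_aki <- function(offset_h, scr, baseline,
                       thresholds = kdigo_thresholds(),
                       detection_days = 3L) {
  if (inherits(baseline, "baseline_result")) baseline <- baseline$value
  if (length(scr) == 0L) stop("empty creatinine series", call. = FALSE)
  if (length(offset_h) != length(scr)) {
    stop("offset_h and scr lengths differ", call. = FALSE)
  }
  if (!is.finite(baseline) || baseline <= 0) {
    stop("baseline must be finite and > 0", call. = FALSE)
  }
  ord <- order(offset_h)
  t <- offset_h[ord]
  v <- scr[ord]
  n <- length(v)
  horizon <- 24 * detection_days

  abs_fire <- logical(n)
  ratio_fire <- logical(n)
  for (i in seq_len(n)) {
    if (t[i] >= horizon) break
    in_win <- t > t[i] - thresholds$absolute_window & t <= t[i]
    abs_fire[i] <- v[i] - min(v[in_win]) >= thresholds$absolute_rise - .KDIGO_TOL
    ratio_fire[i] <- t[i] <= thresholds$ratio_window * 24 &&
      v[i] / baseline >= thresholds$ratio_rise - .KDIGO_TOL
  }
  fire <- (abs_fire | ratio_fire) & t < horizon
  if (!any(fire)) {
    return(structure(list(flagged = FALSE, first_detection_day = NA_integer_,
                          criterion = "none", trigger_offset_h = NA_real_),
                     class = "aki_label"))
  }
  i0 <- which(fire)[1L]
  criterion <- if (abs_fire[i0] && ratio_fire[i0]) "both"
               else if (abs_fire[i0]) "absolute" else "ratio"
  structure(list(flagged = TRUE,
                 first_detection_day = as.integer(floor(t[i0] / 24)) + 1L,
                 criterion = criterion,
                 trigger_offset_h = t[i0]),
            class = "aki_label")
}

#' Brute-force reference labeller (test oracle)
#'
#' Exhaustive O(n^2) scan over all ordered measurement pairs for the 48-h
#' criterion and all single measurements for the ratio criterion. Written
#' independently of [detect_aki()]; intended as the correctness oracle for
#' fuzzed series, not for production use.
#'
#' @inheritParams detect_aki
#' @return An `aki_label`, with semantics identical to [detect_aki()].
#' @export
detect_aki_oracle <- function(offset_h, scr, baseline,
                              thresholds = kdigo_thresholds(),
                              detection_days = 3L) {
  if (inherits(baseline, "baseline_result")) baseline <- baseline$value
  if (length(scr) == 0L) stop("empty creatinine series", call. = FALSE)
  if (!is.finite(baseline) || baseline <= 0) {
    stop("baseline must be finite and > 0", call. = FALSE)
  }
  tol <- 1e-9
  horizon <- 24 * detection_days
  hits <- data.frame(time = numeric(0), crit = character(0))
  for (i in seq_along(scr)) {
    ti <- offset_h[i]
    if (ti >= horizon) next
    for (j in seq_along(scr)) {
      tj <- offset_h[j]
      if (tj <= ti && tj > ti - thresholds$absolute_window &&
          scr[i] - scr[j] >= thresholds$absolute_rise - tol) {
        hits <- rbind(hits, data.frame(time = ti, crit = "absolute"))
        break
      }
    }
    if (ti <= thresholds$ratio_window * 24 &&
        scr[i] >= thresholds$ratio_rise * baseline - tol) {
      hits <- rbind(hits, data.frame(time = ti, crit = "ratio"))
    }
  }
  if (nrow(hits) == 0L) {
    return(structure(list(flagged = FALSE, first_detection_day = NA_integer_,
                          criterion = "none", trigger_offset_h = NA_real_),
                     class = "aki_label"))
  }
  t0 <- min(hits$time)
  crits <- unique(hits$crit[hits$time == t0])
  criterion <- if (length(crits) == 2L) "both" else crits
  structure(list(flagged = TRUE,
                 first_detection_day = as.integer(floor(t0 / 24)) + 1L,
                 criterion = criterion,
                 trigger_offset_h = t0),
            class = "aki_label")
}

#' Day-1 AKI flag for exclusion screening
#'
#' TRUE iff either KDIGO criterion fires with a triggering offset in
#' `[0, 24)` h, with the ratio criterion judged against
#' `screening_baseline`. This is the screen used to drop admissions already
#' in AKI on day 1 (for the MDRD-screened baseline the screening value is
#' the backward-calculated creatinine, not the working baseline).
#'
#' @inheritParams detect_aki
#' @param screening_baseline Baseline used for the day-1 ratio screen.
#' @export
day1_aki_flag <- function(offset_h, scr, screening_baseline,
                          thresholds = kdigo_thresholds()) {
  if (!any(offset_h >= 0 & offset_h < 24)) {
    stop("no day-1 measurements", call. = FALSE)
  }
  lab <- detect_aki(offset_h, scr, screening_baseline, thresholds,
                    detection_days = 1L)
  lab$flagged
}

#' @export
print.aki_label <- function(x, ...) {
  if (x$flagged) {
    cat(sprintf("AKI flagged: day %d, criterion %s (offset %.1f h)\n",
                x$first_detection_day, x$criterion, x$trigger_offset_h))
  } else {
    cat("AKI not flagged\n")
  }
  invisible(x)
}
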