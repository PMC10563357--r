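# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
match_sex <- function(sex) {
  s <- tolower(as.character(sex))
  bad <- !s %in% c("male", "female")
  if (any(bad)) stop("sex must be 'male' or 'female'", call. = FALSE)
  s
}

# probabilities clipped away from {0,1} so logits stay finite
#' @noRd
clip_prob <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

# f1 with the 0/0 -> 0 convention (no predicted or no true positives)
#' @noRd
f1_from_counts <- function(tp, fp, fn) {
  if (tp == 0) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

#' @noRd
f1_at <- function(probs, labels, threshold) {
  pred <- probs >= threshold
  f1_from_counts(sum(pred & labels == 1), sum(pred & labels == 0),
                 sum(!pred & labels == 1))
}
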