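#' Backward MDRD calculation of baseline serum creatinine
#'
#' Solves the four-variable MDRD eGFR equation for serum creatinine under an
#' assumed eGFR of 75 ml/min/1.73 m^2, the standard fallback when no
#' pre-admission creatinine is on record:
#' \deqn{sCr_{GFR-75} = \left(\frac{75}{186 \cdot age^{-0.203} \cdot
#'   (0.742\ if\ female)}\right)^{-0.887}}
#'
#' The outer exponent is kept at its conventional printed value of -0.887,
#' which is not the exact algebraic inverse of the MDRD creatinine exponent
#' (-1/1.154 = -0.8666...). Both are supported via `exponent` so the
#' sensitivity of downstream labelling to this choice can be examined; the
#' round-trip through [forward_mdrd()] recovers 75 to within about 0.7
#' ml/min/1.73 m^2 under the printed exponent.
#'
#' @param age Age in years, >= 18. Vectorised.
#' @param sex `"male"` or `"female"` (recycled against `age`).
#' @param assumed_egfr Assumed eGFR, ml/min/1.73 m^2. Default 75.
#' @param exponent Outer exponent; default `-0.887` (printed convention).
#'   Use `-1/1.154` for the exact algebraic inverse.
#' @return Baseline serum creatinine in mg/dL (positive, finite).
#' @examples
#' backward_mdrd(60, "female") # ~0.822 mg/dL
#' @export
backward_mdrd <- function(age, sex, assumed_egfr = 75, exponent = -0.887) {
  sex <- match_sex(sex)
  if (any(!is.finite(age)) || any(age < 18)) {
    stop("age must be finite and >= 18 years", call. = FALSE)
  }
  denom <- 186 * age^(-0.203) * ifelse(sex == "female", 0.742, 1)
  (assumed_egfr / denom)^exponent
}

#' Forward four-variable MDRD eGFR
#'
#' eGFR = 186 * sCr^-1.154 * age^-0.203 * (0.742 if female), i.e. the
#' race-free four-variable form whose factors match [backward_mdrd()].
#'
#' @param scr Serum creatinine, mg/dL, > 0.
#' @inheritParams backward_mdrd
#' @return eGFR in ml/min/1.73 m^2.
#' @export
forward_mdrd <- function(scr, age, sex) {
  sex <- match_sex(sex)
  if (any(!is.finite(scr)) || any(scr <= 0)) {
    stop("scr must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(age)) || any(age < 18)) {
    stop("age must be finite and >= 18 years", call. = FALSE)
  }
  186 * scr^(-1.154) * age^(-0.203) * ifelse(sex == "female", 0.742, 1)
}

#' CKD-EPI (2009) creatinine eGFR
#'
#' The 2009 CKD-EPI creatinine equation without the race coefficient,
#' used in this package purely as a model input feature:
#' eGFR = 141 * min(sCr/k, 1)^alpha * max(sCr/k, 1)^-1.209 * 0.993^age
#' * (1.018 if female), with k = 0.7 / alpha = -0.329 for females and
#' k = 0.9 / alpha = -0.411 for males.
#'
#' @inheritParams forward_mdrd
#' @return eGFR in ml/min/1.73 m^2.
#' @export
ckdepi_egfr <- function(scr, age, sex) {
  sex <- match_sex(sex)
  if (any(!is.finite(scr)) || any(scr <= 0)) {
    stop("scr must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(age)) || any(age < 18)) {
    stop("age must be finite and >= 18 years", call. = FALSE)
  }
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  141 * pmin(scr / kappa, 1)^alpha * pmax(scr / kappa, 1)^(-1.209) *
    0.993^age * ifelse(female, 1.018, 1)
}

#' Creatinine unit conversion
#'
#' mg/dL to umol/L (and back) using the creatinine molar mass of
#' 113.12 g/mol, so `x` mg/dL = `x * 10000 / 113.12` umol/L
#' (0.3 mg/dL = 26.5 umol/L).
#'
#' @param x Creatinine concentration.
#' @return Converted concentration.
#' @export
mgdl_to_umoll <- function(x) {
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  x * 10000 / 113.12
}

#' @rdname mgdl_to_umoll
#' @export
umoll_to_mgdl <- function(x) {
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  x * 113.12 / 10000
}
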