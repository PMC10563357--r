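# Synthetic MIMIC-like ICU admissions with a known, injected AKI process.
#
# The creatinine model is deliberately simple so labelling ground truth is
# analytically known: each subject has a piecewise-constant true baseline
# (log-normal across subjects, median 0.9 mg/dL) observed with i.i.d.
# Gaussian measurement noise; AKI trajectories are sustained step rises
# planted with a >= 4*sd margin above the chosen KDIGO threshold so that
# measurement noise cannot de-flag them.

# first-24h continuous variable roster: event means/sds, events per 24 h,
# and the mean shift applied to admissions carrying a day-2/3 AKI trajectory
.VAR_ROSTER <- local({
  v <- rbind(
    heart_rate       = c(88, 14, 3, 6),
    systolic_bp      = c(125, 18, 3, -4),
    diastolic_bp     = c(70, 12, 3, -2),
    respiratory_rate = c(19, 5, 3, 2),
    temperature      = c(37.0, 0.5, 2, 0.1),
    spo2             = c(96, 2.5, 3, -2),
    sodium           = c(139, 4, 2, 0),
    potassium        = c(4.2, 0.5, 2, 0.2),
    chloride         = c(104, 5, 2, 0),
    bicarbonate      = c(24, 3.5, 2, -2),
    anion_gap        = c(13, 3, 2, 1.5),
    bun              = c(18, 8, 2, 6),
    calcium          = c(8.5, 0.7, 2, -0.2),
    hemoglobin       = c(11, 2, 2, -0.5),
    hematocrit       = c(33, 5, 2, -1.5),
    platelets        = c(220, 80, 2, -20),
    wbc              = c(11, 5, 2, 2),
    prothrombin_time = c(14, 3, 2, 2),
    albumin          = c(3.4, 0.6, 1, -0.3),
    bilirubin        = c(1.0, 0.8, 1, 0.3),
    weight           = c(80, 20, 1, 0))
  colnames(v) <- c("mean", "sd", "n_events", "aki_shift")
  v
})

.COMORBIDITIES <- c(obesity = 0.0671, mild_liver_disease = 0.0825,
                    sepsis = 0.0892, peripheral_vascular_disease = 0.1024,
                    chronic_heart_failure = 0.1206,
                    chronic_kidney_disease = 0.0947, hypertension = 0.4885,
                    severe_liver_disease = 0.033,
                    myocardial_infarction = 0.1523,
                    congestive_heart_failure = 0.2042,
                    diabetes_type2 = 0.2435, chronic_pulmonary_disease = 0.2346,
                    supplemental_oxygen = 0.4266)

.ETHNICITIES <- c(White = 0.3073, African_American = 0.077,
                  Hispanic_Latino = 0.0335, Asian = 0.0299, Other = 0.1669,
                  Unknown = 0.3854)

#' Simulation configuration for the synthetic EHR generator
#'
#' Defaults emulate the study regime the package is built around: a
#' day-2/3 AKI prevalence of 17.32%, 64.19% of admissions without any
#' pre-ICU creatinine history, and demographic / comorbidity frequencies
#' drawn from the cohort characteristics table.
#'
#' @param n_patients Number of patients.
#' @param aki_day2or3_rate Fraction of admissions given an AKI trajectory
#'   first detectable on day 2 or 3. Default 0.1732.
#' @param aki_day1_rate Fraction given a day-1 trajectory (these admissions
#'   are excluded downstream by the day-1 screen). Default 0.20.
#' @param preicu_baseline_missing_rate Fraction of admissions whose pre-ICU
#'   creatinine history is removed entirely. Default 0.6419.
#' @param missing_rates Named vector, variable -> fraction of admissions
#'   missing that first-24h variable.
#' @param age_mean,age_sd,age_min,age_max Age distribution (years; truncated
#'   normal, rounded). The lower bound of 16 deliberately admits a few
#'   minors so the adult-only exclusion step is exercised.
#' @param p_female Probability of female sex.
#' @param ethnicity_probs Named category probabilities (must sum to 1).
#' @param comorbidity_prevalence Named Bernoulli prevalences.
#' @param scr_noise_sd Creatinine measurement noise sd, mg/dL. Default 0.05.
#' @param scr_interval_h In-ICU creatinine sampling interval, hours
#'   (exposed as a parameter; the source cohort's sampling frequency is not
#'   published). Default 12.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   subject-level true baseline (median `exp(meanlog)` = 0.9 mg/dL).
#' @param p_ratio_mode Probability an injected trajectory targets the ratio
#'   criterion rather than the absolute-rise criterion.
#' @param p_second_admission Fraction of patients given a second ICU stay
#'   (excluded downstream by the first-admission rule).
#' @param p_rrt Prevalence of the maintenance renal-replacement flag.
#' @param p_recent_only Among admissions with pre-ICU history, the fraction
#'   whose draws all fall within 7 days of admission (so the 180-to-7 and
#'   180-to-0 windows genuinely differ).
#' @param p_recent_elevation Fraction of admissions given a sub-threshold
#'   creatinine elevation (x1.25) on day 1 and in recent pre-ICU draws:
#'   the "looks like AKI but is not" phenotype behind false-positive audits.
#' @param seed Integer RNG seed; a fixed config is byte-reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 2000,
                       aki_day2or3_rate = 0.1732,
                       aki_day1_rate = 0.20,
                       preicu_baseline_missing_rate = 0.6419,
                       missing_rates = c(albumin = 0.6837, bilirubin = 0.5085,
                                         prothrombin_time = 0.10,
                                         weight = 0.10, calcium = 0.05,
                                         anion_gap = 0.05, temperature = 0.05,
                                         platelets = 0.04, hematocrit = 0.03,
                                         hemoglobin = 0.03, wbc = 0.03,
                                         bicarbonate = 0.03, bun = 0.03,
                                         sodium = 0.02, potassium = 0.02,
                                         chloride = 0.02, spo2 = 0.02,
                                         respiratory_rate = 0.02,
                                         heart_rate = 0.01,
                                         systolic_bp = 0.01,
                                         diastolic_bp = 0.01),
                       age_mean = 66, age_sd = 15, age_min = 16, age_max = 95,
                       p_female = 0.5575,
                       ethnicity_probs = .ETHNICITIES,
                       comorbidity_prevalence = .COMORBIDITIES,
                       scr_noise_sd = 0.05,
                       scr_interval_h = 12,
                       baseline_meanlog = log(0.9), baseline_sdlog = 0.35,
                       p_ratio_mode = 0.3,
                       p_second_admission = 0.05,
                       p_rrt = 0.02,
                       p_recent_only = 0.3,
                       p_recent_elevation = 0.15,
                       seed = 1L) {
  fracs <- c(aki_day2or3_rate = aki_day2or3_rate, aki_day1_rate = aki_day1_rate,
             preicu_baseline_missing_rate = preicu_baseline_missing_rate,
             p_female = p_female, p_ratio_mode = p_ratio_mode,
             p_second_admission = p_second_admission, p_rrt = p_rrt,
             p_recent_only = p_recent_only,
             p_recent_elevation = p_recent_elevation, missing_rates)
  if (any(fracs < 0 | fracs > 1)) {
    stop("all rate/fraction parameters must lie in [0, 1]", call. = FALSE)
  }
  if (aki_day1_rate + aki_day2or3_rate > 1) {
    stop("aki_day1_rate + aki_day2or3_rate must not exceed 1", call. = FALSE)
  }
  if (abs(sum(ethnicity_probs) - 1) > 1e-8) {
    stop("ethnicity_probs must sum to 1", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic ICU EHR bundle
#'
#' Produces patients, admissions, pre-ICU creatinine history, in-ICU
#' measurement events over days 1-7, urine-output epochs, comorbidity flags
#' and a latent-truth sidecar recording which admissions received an
#' injected AKI trajectory, on which day, and in which mode. Every
#' admission carries creatinine measurements on each of days 1-3 by
#' construction, so the inclusion rule "at least one sCr on days 1, 2 and
#' 3" is satisfiable before [apply_missingness()] (which never deletes
#' them).
#'
#' @param config A [sim_config()].
#' @return An `ehr_bundle`: list of data.frames `patients`, `admissions`,
#'   `preicu_labs`, `icu_events`, `urine_output`, `comorbidities`, `truth`,
#'   plus the generating `config`.
#' @export
generate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients

  # demographics
  age <- round(stats::rnorm(n, config$age_mean, config$age_sd))
  age <- pmin(pmax(age, config$age_min), config$age_max)
  sex <- ifelse(stats::runif(n) < config$p_female, "female", "male")
  ethnicity <- sample(names(config$ethnicity_probs), n, replace = TRUE,
                      prob = config$ethnicity_probs)
  patients <- data.frame(patient_id = seq_len(n), age = age, sex = sex,
                         ethnicity = ethnicity, stringsAsFactors = FALSE)

  # admissions: one first ICU stay per patient plus occasional second stays
  second <- which(stats::runif(n) < config$p_second_admission)
  admissions <- data.frame(
    admission_id = seq_len(n + length(second)),
    patient_id = c(seq_len(n), second),
    icu_intime_day = c(stats::runif(n, 0, 365),
                       stats::runif(length(second), 400, 700)),
    rrt = stats::runif(n + length(second)) < config$p_rrt)
  n_adm <- nrow(admissions)

  # subject-level true baseline, shared across a patient's admissions
  base_pat <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  base_adm <- base_pat[admissions$patient_id]

  # latent AKI truth per admission
  u <- stats::runif(n_adm)
  aki_day <- integer(n_adm)
  aki_day[u < config$aki_day1_rate] <- 1L
  aki_day[u >= config$aki_day1_rate &
          u < config$aki_day1_rate + config$aki_day2or3_rate] <-
    sample(c(2L, 3L), sum(u >= config$aki_day1_rate &
                          u < config$aki_day1_rate + config$aki_day2or3_rate),
           replace = TRUE)
  mode <- ifelse(stats::runif(n_adm) < config$p_ratio_mode,
                 "ratio_rise", "absolute_rise")
  mode[aki_day == 0L] <- NA_character_
  recent_elev <- aki_day == 0L & stats::runif(n_adm) < config$p_recent_elevation

  truth <- data.frame(admission_id = admissions$admission_id,
                      aki_day = aki_day, mode = mode,
                      true_baseline = base_adm,
                      recent_elevation = recent_elev)

  # in-ICU creatinine series over days 1-7 (matrix: admissions x time grid)
  sd0 <- config$scr_noise_sd
  times <- seq(config$scr_interval_h / 2, 7 * 24 - config$scr_interval_h / 2,
               by = config$scr_interval_h)
  nt <- length(times)
  scr_mat <- matrix(base_adm + stats::rnorm(n_adm * nt, 0, sd0),
                    nrow = n_adm, ncol = nt)
  d1_cols <- which(times < 24)
  for (i in which(recent_elev)) {
    scr_mat[i, d1_cols] <- base_adm[i] * 1.25 +
      stats::rnorm(length(d1_cols), 0, sd0)
  }
  for (i in which(aki_day > 0L)) {
    scr_mat[i, ] <- inject_aki_trajectory(times, scr_mat[i, ], base_adm[i],
                                          aki_day[i], mode[i], noise_sd = sd0)
  }
  scr_events <- data.frame(
    admission_id = rep(admissions$admission_id, each = nt),
    offset_h = rep(times, n_adm),
    variable = "creatinine",
    value = pmax(as.vector(t(scr_mat)), 0.1))

  # other first-24h continuous variables, vectorised per variable
  aki23 <- aki_day %in% c(2L, 3L)
  var_rows <- lapply(rownames(.VAR_ROSTER), function(vn) {
    r <- .VAR_ROSTER[vn, ]
    k <- r[["n_events"]]
    mu <- r[["mean"]] + ifelse(aki23, r[["aki_shift"]], 0)
    data.frame(admission_id = rep(admissions$admission_id, each = k),
               offset_h = stats::runif(n_adm * k, 0, 24),
               variable = vn,
               value = stats::rnorm(n_adm * k, rep(mu, each = k), r[["sd"]]))
  })
  icu_events <- rbind(scr_events, do.call(rbind, var_rows))
  icu_events <- icu_events[order(icu_events$admission_id, icu_events$variable,
                                 icu_events$offset_h), ]
  rownames(icu_events) <- NULL

  # urine output: six 4-h epochs in the first 24 h, reduced under AKI
  uo_mu <- ifelse(aki23, 140, 220)
  urine_output <- data.frame(
    admission_id = rep(admissions$admission_id, each = 6),
    offset_h = rep(seq(2, 22, by = 4), n_adm),
    volume_ml = pmax(stats::rnorm(n_adm * 6, rep(uo_mu, each = 6), 80), 0))

  # pre-ICU creatinine history (availability thinned by apply_missingness)
  n_draws <- 1 + stats::rpois(n_adm, 2)
  recent_only <- stats::runif(n_adm) < config$p_recent_only
  adm_rep <- rep(seq_len(n_adm), n_draws)
  days_before <- ifelse(recent_only[adm_rep],
                        stats::runif(length(adm_rep), 0, 7),
                        stats::runif(length(adm_rep), 7, 180))
  lvl <- base_adm[adm_rep] *
    ifelse(recent_elev[adm_rep] & days_before <= 7, 1.25, 1)
  preicu_labs <- data.frame(
    admission_id = admissions$admission_id[adm_rep],
    days_before = days_before,
    scr = pmax(lvl + stats::rnorm(length(adm_rep), 0, sd0), 0.1))

  # independent Bernoulli comorbidity flags + AKI-correlated ventilation
  com <- vapply(config$comorbidity_prevalence,
                function(p) as.integer(stats::runif(n_adm) < p),
                integer(n_adm))
  comorbidities <- data.frame(admission_id = admissions$admission_id, com)
  comorbidities$invasive_ventilation <-
    as.integer(stats::runif(n_adm) < ifelse(aki23, 0.55, 0.25))

  structure(list(patients = patients, admissions = admissions,
                 preicu_labs = preicu_labs, icu_events = icu_events,
                 urine_output = urine_output, comorbidities = comorbidities,
                 truth = truth, config = config),
            class = "ehr_bundle")
}

#' Inject an AKI trajectory into a creatinine series
#'
#' Replaces the series from a measurement within `target_day` onward with a
#' sustained elevated level chosen so that the requested KDIGO criterion
#' fires first on `target_day` (never earlier) against the subject's true
#' pre-noise baseline, with a margin of at least `4 * noise_sd` above the
#' threshold so measurement noise cannot de-flag the trajectory. The step
#' is placed at a measurement that has at least one earlier measurement
#' within 48 h, so the absolute-rise comparator is well defined. The
#' non-targeted criterion may co-fire at the same instant (for typical
#' baselines a >= 1.5x rise within 48 h necessarily also exceeds
#' 0.3 mg/dL); the detection day is unaffected.
#'
#' @param offset_h,scr The series to modify (hours from ICU admission,
#'   mg/dL).
#' @param true_baseline The subject's pre-noise baseline, mg/dL.
#' @param target_day 1, 2 or 3.
#' @param mode `"absolute_rise"` or `"ratio_rise"`.
#' @param noise_sd Measurement noise sd used for the safety margin.
#' @param margin Extra elevation above `threshold + 4 * noise_sd`; drawn
#'   uniformly from `[0.02, 0.15]` mg/dL when `NULL`.
#' @return The modified creatinine vector.
#' @export
inject_aki_trajectory <- function(offset_h, scr, true_baseline, target_day,
                                  mode = c("absolute_rise", "ratio_rise"),
                                  noise_sd = 0.05, margin = NULL) {
  mode <- match.arg(mode)
  stopifnot(target_day %in% 1:3)
  day_lo <- 24 * (target_day - 1)
  day_hi <- 24 * target_day
  in_day <- which(offset_h >= day_lo & offset_h < day_hi)
  if (length(in_day) == 0L) {
    stop("series has no measurement on the target day", call. = FALSE)
  }
  # need a predecessor within 48 h for the rise comparator
  ok <- in_day[vapply(in_day, function(i) {
    any(offset_h < offset_h[i] & offset_h > offset_h[i] - 48)
  }, logical(1))]
  if (length(ok) == 0L) {
    stop("no target-day measurement has a 48-h predecessor", call. = FALSE)
  }
  step_at <- if (length(ok) == 1L) ok else sample(ok, 1L)
  margin <- margin %||% stats::runif(1, 0.02, 0.15)
  level <- if (mode == "absolute_rise") {
    true_baseline + 0.3 + 4 * noise_sd + margin
  } else {
    true_baseline * 1.5 + 4 * noise_sd + margin
  }
  elevate <- offset_h >= offset_h[step_at]
  scr[elevate] <- level + stats::rnorm(sum(elevate), 0, noise_sd)
  scr
}

#' Apply configured missingness to a bundle
#'
#' For each entry of `config$missing_rates` the named first-24h variable is
#' removed for a Bernoulli-selected fraction of admissions; the pre-ICU
#' creatinine history is removed entirely for
#' `config$preicu_baseline_missing_rate` of admissions. Day-1/2/3
#' creatinine is never deleted (the inclusion criterion is preserved), so a
#' `creatinine` entry in the rate map is ignored with a warning.
#'
#' @param bundle An `ehr_bundle`.
#' @param config The [sim_config()] holding the rates (the deletion RNG is
#'   seeded from `config$seed + 1` so generation and thinning are
#'   independently reproducible).
#' @return The thinned `ehr_bundle`.
#' @export
apply_missingness <- function(bundle, config = bundle$config) {
  stopifnot(inherits(bundle, "ehr_bundle"))
  rates <- config$missing_rates
  if ("creatinine" %in% names(rates)) {
    warning("creatinine missingness is not applied; days 1-3 sCr is protected")
    rates <- rates[names(rates) != "creatinine"]
  }
  set.seed(config$seed + 1L)
  ids <- bundle$admissions$admission_id
  ev <- bundle$icu_events
  drop <- logical(nrow(ev))
  for (vn in names(rates)) {
    gone <- ids[stats::runif(length(ids)) < rates[[vn]]]
    drop <- drop | (ev$variable == vn & ev$admission_id %in% gone)
  }
  bundle$icu_events <- ev[!drop, ]
  rownames(bundle$icu_events) <- NULL

  no_pre <- ids[stats::runif(length(ids)) < config$preicu_baseline_missing_rate]
  bundle$preicu_labs <-
    bundle$preicu_labs[!bundle$preicu_labs$admission_id %in% no_pre, ]
  rownames(bundle$preicu_labs) <- NULL
  bundle
}

#' @export
print.ehr_bundle <- function(x, ...) {
  cat(sprintf(paste0("Synthetic EHR bundle: %d patients, %d admissions, ",
                     "%d ICU events, %d pre-ICU creatinine draws\n"),
              nrow(x$patients), nrow(x$admissions), nrow(x$icu_events),
              nrow(x$preicu_labs)))
  tt <- table(factor(x$truth$aki_day, levels = 0:3))
  cat(sprintf("Latent AKI truth: none %d, day1 %d, day2 %d, day3 %d\n",
              tt[1], tt[2], tt[3], tt[4]))
  invisible(x)
}

#' Read/write a bundle as long-format CSV tables
#'
#' Thin adapter for MIMIC-like long-format data: one directory holding
#' `patients.csv`, `admissions.csv`, `preicu_labs.csv`, `icu_events.csv`,
#' `urine_output.csv`, `comorbidities.csv` and (if present) the
#' latent-truth sidecar `truth.csv`. Real extracts with the same column
#' rosters can be read straight into the pipeline.
#'
#' @param bundle An `ehr_bundle`.
#' @param dir Directory path.
#' @return `write_ehr_csv` returns `dir` invisibly; `read_ehr_csv` returns
#'   an `ehr_bundle` (with `config = NULL` and `truth = NULL` when the
#'   sidecar is absent).
#' @export
write_ehr_csv <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ehr_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tb in c("patients", "admissions", "preicu_labs", "icu_events",
               "urine_output", "comorbidities", "truth")) {
    if (!is.null(bundle[[tb]])) {
      utils::write.csv(bundle[[tb]], file.path(dir, paste0(tb, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname write_ehr_csv
#' @export
read_ehr_csv <- function(dir) {
  rd <- function(nm, required = TRUE) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f)) {
      if (required) stop("missing table: ", nm, call. = FALSE)
      return(NULL)
    }
    utils::read.csv(f, stringsAsFactors = FALSE)
  }
  structure(list(patients = rd("patients"), admissions = rd("admissions"),
                 preicu_labs = rd("preicu_labs"), icu_events = rd("icu_events"),
                 urine_output = rd("urine_output"),
                 comorbidities = rd("comorbidities"),
                 truth = rd("truth", required = FALSE), config = NULL),
            class = "ehr_bundle")
}
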