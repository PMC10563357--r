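# Shared fixtures and independent oracles used across test files.

# random creatinine series over days 1-7 for fuzzing the labeller
fuzz_series <- function() {
  n <- sample(5:15, 1)
  list(t = sort(stats::runif(n, 0, 7 * 24)),
       v = pmax(0.2, stats::rnorm(n, stats::runif(1, 0.5, 1.5),
                                  stats::runif(1, 0.05, 0.4))),
       baseline = stats::runif(1, 0.4, 1.5))
}

label_identical <- function(a, b) {
  identical(a$flagged, b$flagged) &&
    identical(a$first_detection_day, b$first_detection_day) &&
    identical(a$criterion, b$criterion)
}

# small generated bundle for pipeline-level tests
tiny_bundle <- function(n = 250, seed = 11, ...) {
  apply_missingness(generate_population(sim_config(n_patients = n,
                                                   seed = seed, ...)))
}

# independent AUC oracle: rank statistic with tie midpoints
rank_auc <- function(probs, labels) {
  r <- rank(probs)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# independent f1 from explicit confusion counts
hand_f1 <- function(probs, labels, thr) {
  pred <- as.integer(probs >= thr)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  if (tp == 0) return(0)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

# all permutations of a vector (exhaustive Shapley oracle, p <= 5)
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# hand-built minimal EHR bundle exercising each exclusion step
manual_bundle <- function() {
  patients <- data.frame(
    patient_id = 1:6,
    age = c(17, 45, 60, 70, 50, 55),
    sex = c("male", "female", "male", "female", "male", "female"),
    ethnicity = c("White", "Asian", "White", "Other", "White", "Asian"))
  admissions <- data.frame(
    admission_id = 1:7,
    patient_id = c(1, 2, 3, 4, 5, 6, 5),   # patient 5 has two stays
    icu_intime_day = c(10, 20, 30, 40, 50, 60, 200),
    rrt = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  scr <- function(id, base, day2 = base, day3 = base, skip_day2 = FALSE) {
    t <- c(6, 18, 30, 42, 54, 66)
    v <- c(base, base, day2, day2, day3, day3)
    if (skip_day2) { t <- t[-(3:4)]; v <- v[-(3:4)] }
    data.frame(admission_id = id, offset_h = t, variable = "creatinine",
               value = v)
  }
  icu_events <- rbind(
    scr(1, 0.9),                       # minor -> step 1
    scr(2, 0.8, day3 = 1.3),           # day-3 AKI -> included, outcome 1
    scr(3, 0.9),                       # RRT -> step 3
    scr(4, 0.9, skip_day2 = TRUE),     # no day-2 sCr -> step 4
    scr(5, 0.6, day2 = 0.6),           # clean negative
    rbind(scr(6, 0.7)[1, ],            # day-1 AKI: 0.7 -> 1.2 within day 1
          data.frame(admission_id = 6, offset_h = c(18, 30, 42, 54, 66),
                     variable = "creatinine",
                     value = c(1.2, 1.2, 1.2, 1.2, 1.2))),
    scr(7, 0.6))                       # second stay -> step 2
  hr <- data.frame(admission_id = rep(1:7, each = 3),
                   offset_h = rep(c(3, 12, 20), 7), variable = "heart_rate",
                   value = rep(c(80, 99, 91), 7))
  icu_events <- rbind(icu_events, hr)
  urine <- data.frame(admission_id = rep(1:7, each = 2),
                      offset_h = rep(c(4, 12), 7),
                      volume_ml = rep(c(100, 300), 7))
  com <- data.frame(admission_id = 1:7,
                    chronic_kidney_disease = c(0, 1, 0, 0, 0, 0, 0),
                    invasive_ventilation = c(0, 1, 0, 0, 0, 1, 0))
  preicu <- data.frame(admission_id = c(2, 2, 5),
                       days_before = c(30, 10, 3),
                       scr = c(1.0, 1.2, 0.65))
  structure(list(patients = patients, admissions = admissions,
                 preicu_labs = preicu, icu_events = icu_events,
                 urine_output = urine, comorbidities = com,
                 truth = NULL, config = NULL),
            class = "ehr_bundle")
}
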