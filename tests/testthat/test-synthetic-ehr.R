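test_that("generation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_patients = 100, seed = 7)
  b1 <- generate_population(cfg)
  b2 <- generate_population(cfg)
  expect_identical(b1, b2)
  expect_identical(apply_missingness(b1), apply_missingness(b2))
})

test_that("zero injection rates produce no latent trajectories", {
  b <- generate_population(sim_config(n_patients = 120, seed = 3,
                                      aki_day2or3_rate = 0, aki_day1_rate = 0))
  expect_true(all(b$truth$aki_day == 0L))
  b <- generate_population(sim_config(n_patients = 120, seed = 3,
                                      aki_day2or3_rate = 0))
  expect_false(any(b$truth$aki_day %in% 2:3))
})

test_that("config validation rejects out-of-range fractions", {
  expect_error(sim_config(aki_day1_rate = -0.1), "\\[0, 1\\]")
  expect_error(sim_config(aki_day1_rate = 0.7, aki_day2or3_rate = 0.5),
               "exceed")
  expect_error(sim_config(missing_rates = c(albumin = 1.2)), "\\[0, 1\\]")
})

test_that("injected trajectories clear their threshold with the noise margin", {
  t <- seq(6, 162, by = 12)
  sd0 <- 0.05
  # absolute rise from a flat 0.8 series, target day 2
  set.seed(1)
  v <- inject_aki_trajectory(t, rep(0.8, length(t)), 0.8, target_day = 2,
                             mode = "absolute_rise", noise_sd = sd0)
  d2 <- v[t >= 24 & t < 48]
  expect_gte(max(d2), 0.8 + 0.3 + 4 * sd0 - 3 * sd0)  # level minus noise
  # ratio rise from a flat 0.6 series, target day 3
  v <- inject_aki_trajectory(t, rep(0.6, length(t)), 0.6, target_day = 3,
                             mode = "ratio_rise", noise_sd = sd0)
  d3 <- v[t >= 48 & t < 72]
  expect_gte(max(d3), 0.9 + 4 * sd0 - 3 * sd0)
  expect_error(inject_aki_trajectory(c(6, 18), c(0.8, 0.8), 0.8, 3,
                                     "absolute_rise"),
               "target day")
})

test_that("injected series are recovered by the labeller on the target day", {
  set.seed(5)
  t <- seq(6, 162, by = 12)
  sd0 <- 0.05
  hit <- 0L
  n <- 300L
  for (i in seq_len(n)) {
    base <- stats::rlnorm(1, log(0.9), 0.35)
    day <- sample(1:3, 1)
    mode <- sample(c("absolute_rise", "ratio_rise"), 1)
    v <- base + stats::rnorm(length(t), 0, sd0)
    v <- inject_aki_trajectory(t, v, base, day, mode, noise_sd = sd0)
    lab <- detect_aki(t, v, base)
    if (lab$flagged && lab$first_detection_day == day) hit <- hit + 1L
  }
  expect_gte(hit / n, 0.99)
})

test_that("missingness is realised at the configured per-variable rates", {
  cfg <- sim_config(n_patients = 3000, seed = 13,
                    missing_rates = c(albumin = 0.6837))
  b <- apply_missingness(generate_population(cfg))
  has_alb <- unique(b$icu_events$admission_id[b$icu_events$variable == "albumin"])
  realised <- 1 - length(has_alb) / nrow(b$admissions)
  # binomial 99% tolerance around 0.6837 at n ~ 3000
  expect_gt(realised, 0.66)
  expect_lt(realised, 0.71)
  # days 1-3 creatinine is never deleted
  expect_warning(
    apply_missingness(generate_population(
      sim_config(n_patients = 50, seed = 1,
                 missing_rates = c(creatinine = 0.5)))),
    "protected")
})

test_that("zero missingness is the identity and full pre-ICU loss forces the formula", {
  b0 <- generate_population(sim_config(n_patients = 80, seed = 2,
                                       missing_rates = numeric(0),
                                       preicu_baseline_missing_rate = 0))
  expect_identical(apply_missingness(b0)$icu_events, b0$icu_events)
  expect_identical(apply_missingness(b0)$preicu_labs, b0$preicu_labs)

  b1 <- apply_missingness(generate_population(
    sim_config(n_patients = 80, seed = 2, preicu_baseline_missing_rate = 1)))
  expect_identical(nrow(b1$preicu_labs), 0L)
  labs <- label_admissions(b1, "B3_mean_180to7_or_mdrd")
  src <- labs$baseline_source[!is.na(labs$baseline_source)]
  expect_true(all(src == "formula_imputed"))
})

test_that("every admission carries creatinine on days 1, 2 and 3", {
  b <- tiny_bundle(n = 150, seed = 4)
  scr <- b$icu_events[b$icu_events$variable == "creatinine", ]
  for (d in 1:3) {
    in_day <- scr$admission_id[scr$offset_h >= 24 * (d - 1) &
                                 scr$offset_h < 24 * d]
    expect_setequal(unique(in_day), b$admissions$admission_id)
  }
  expect_true(all(scr$value > 0))
  expect_true(all(b$preicu_labs$days_before >= 0))
})

test_that("CSV round-trip preserves the bundle tables", {
  b <- tiny_bundle(n = 40, seed = 6)
  dir <- withr::local_tempdir()
  write_ehr_csv(b, dir)
  b2 <- read_ehr_csv(dir)
  for (tb in c("patients", "admissions", "preicu_labs", "icu_events",
               "urine_output", "comorbidities")) {
    expect_equal(b2[[tb]], b[[tb]], ignore_attr = TRUE)
  }
  # labelling agrees on the round-tripped bundle (CSV carries ~15 digits)
  expect_equal(label_admissions(b2, "B1_min_first24h"),
               label_admissions(b, "B1_min_first24h"), tolerance = 1e-9)
})
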