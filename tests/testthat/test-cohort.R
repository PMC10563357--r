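test_that("exclusion pipeline filters in order with a consistent audit", {
  b <- manual_bundle()
  labs <- label_admissions(b, "M3_mean_180to0_or_mdrd")
  excl <- apply_exclusions(b, labs)
  expect_setequal(excl$included_ids, c(2, 5))
  a <- excl$audit
  expect_identical(a$step, c("age >= 18", "first ICU admission",
                             "no maintenance RRT", "sCr on days 1-3",
                             "no day-1 AKI"))
  expect_identical(a$n_excluded, rep(1L, 5))
  # counts telescope: n_input - sum(excluded) = n_output
  expect_identical(a$n_before[1] - sum(a$n_excluded),
                   a$n_after[nrow(a)])
  expect_identical(length(excl$included_ids), a$n_after[nrow(a)])
})

test_that("feature aggregation takes first-24h extrema, one-hot ethnicity and mean urine", {
  b <- manual_bundle()
  f <- aggregate_features(b, c(2, 5))
  expect_equal(f$heart_rate_min, c(80, 80))
  expect_equal(f$heart_rate_max, c(99, 99))
  expect_equal(f$urine_output_mean, c(200, 200))
  eth <- f[, grep("^ethnicity_", names(f)), drop = FALSE]
  expect_true(all(rowSums(eth) == 1))
  expect_equal(f$ethnicity_Asian, c(1, 0))
  # eGFR feature comes from the day-1 minimum creatinine
  expect_equal(f$egfr_ckdepi[1],
               ckdepi_egfr(f$creatinine_min[1], f$age[1], "female"))
  expect_equal(f$chronic_kidney_disease, c(1, 0))
})

test_that("missingness filter drops strictly above the threshold only", {
  df <- data.frame(admission_id = 1:100,
                   high = replace(rnorm(100), 1:69, NA),    # 69% missing
                   boundary = replace(rnorm(100), 1:20, NA), # exactly 20%
                   clean = rnorm(100))
  out <- filter_missing_columns(df, threshold = 0.20)
  expect_identical(names(out$dropped), "high")
  expect_equal(unname(out$dropped), 0.69)
  expect_setequal(names(out$features),
                  c("admission_id", "boundary", "clean"))
  # a complete table passes through untouched
  full <- data.frame(admission_id = 1:10, a = 1:10, b = 10:1)
  expect_identical(filter_missing_columns(full)$features, full)
})

test_that("chained-equations imputation is deterministic, train-fitted and unbiased under MCAR", {
  set.seed(31)
  n <- 400
  x1 <- rnorm(n, 5, 2)
  x2 <- 0.8 * x1 + rnorm(n, 0, 0.5)
  df <- data.frame(admission_id = 1:n, x1 = x1, x2 = x2)
  pre_mean <- mean(df$x2)
  holes <- sample(n, 40)
  df$x2[holes] <- NA
  fit_rows <- 1:300
  imp1 <- impute_chained(df, fit_rows)
  imp2 <- impute_chained(df, fit_rows)
  expect_identical(imp1$features, imp2$features)
  expect_false(any(is.na(imp1$features$x2)))
  # MCAR deletion of a correlated Gaussian column: imputed-column mean
  # within 3 standard errors of the pre-deletion mean
  se <- sd(x2) / sqrt(n)
  expect_lt(abs(mean(imp1$features$x2) - pre_mean), 3 * se)
  # complete table is returned unchanged
  full <- data.frame(admission_id = 1:5, a = rnorm(5), b = rnorm(5))
  expect_identical(impute_chained(full, 1:5)$features, full)
  # a column with no observed fit-partition values is an error
  bad <- data.frame(admission_id = 1:10, a = rnorm(10),
                    b = c(rep(NA, 8), 1, 2))
  expect_error(impute_chained(bad, 1:8), "zero observed")
})

test_that("min-max scaling is train-fitted, clipped, and keeps binaries intact", {
  df <- data.frame(admission_id = 1:4, v = c(2, 4, 6, 8),
                   flag = c(0, 1, 0, 1))
  out <- normalize_features(df, fit_rows = 1:3)
  expect_equal(out$features$v, c(0, 0.5, 1, 1))  # 8 clipped to 1
  expect_equal(out$features$flag, c(0, 1, 0, 1))
  expect_warning(
    z <- normalize_features(data.frame(admission_id = 1:3, c = c(5, 5, 5)),
                            fit_rows = 1:3),
    "zero-variance")
  expect_equal(z$features$c, rep(0, 3))
})

test_that("built cohorts satisfy their structural invariants", {
  b <- tiny_bundle(n = 250, seed = 11)
  ch <- build_cohort(b, "B3_mean_180to7_or_mdrd", seed = 2)
  expect_s3_class(ch, "aki_cohort")
  # disjoint, exhaustive partitions
  expect_setequal(unique(ch$partition), c("train", "validation", "test"))
  expect_identical(length(ch$partition), length(ch$admission_id))
  # outcome prevalence equals the labeller's day-2/3 rate on included ids
  lab <- ch$labels[match(ch$admission_id, ch$labels$admission_id), ]
  expect_identical(ch$outcome, as.integer(lab$outcome_day23))
  # every feature within [0,1] and complete
  expect_true(all(vapply(ch$features, function(c) all(c >= 0 & c <= 1),
                         logical(1))))
  expect_false(anyNA(ch$features))
  # the high-missingness lab columns fell to the 20% filter
  expect_true(any(grepl("albumin", names(ch$dropped_columns))))
  expect_true(any(grepl("bilirubin", names(ch$dropped_columns))))
})

test_that("imputer and scaler fits are invariant to test-row permutation", {
  b <- tiny_bundle(n = 250, seed = 12)
  labs <- label_admissions(b, "B1_min_first24h")
  excl <- apply_exclusions(b, labs)
  feats <- aggregate_features(b, excl$included_ids)
  part <- split_data(rep(0:1, length.out = nrow(feats)), seed = 5)
  filt <- filter_missing_columns(feats)$features
  te <- which(part == "test")

  scrambled <- filt
  set.seed(99)
  scrambled[te, -1] <- filt[sample(te), -1]

  imp_a <- impute_chained(filt, part == "train")
  imp_b <- impute_chained(scrambled, part == "train")
  expect_identical(imp_a$models, imp_b$models)
  scl_a <- normalize_features(imp_a$features, part == "train")
  scl_b <- normalize_features(imp_b$features, part == "train")
  expect_identical(scl_a$params, scl_b$params)
})
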