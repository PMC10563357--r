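test_that("60/20/20 split has the right sizes, determinism and stratification", {
  y <- rbinom(1000, 1, 0.17)
  tags <- split_data(y, seed = 3)
  sizes <- as.integer(table(tags)[c("train", "validation", "test")])
  expect_true(all(abs(sizes - c(600, 200, 200)) <= 1))  # within rounding
  expect_identical(tags, split_data(y, seed = 3))
  expect_false(identical(tags, split_data(y, seed = 4)))
  prev <- vapply(c("train", "validation", "test"),
                 function(p) mean(y[tags == p]), numeric(1))
  expect_lt(max(prev) - min(prev), 0.02)
})

test_that("up-sampling duplicates positives only, to a 1:1 ratio", {
  y <- c(rep(0, 80), rep(1, 20))
  set.seed(1)
  idx <- akibench:::upsample_rows(seq_along(y), y)
  expect_equal(sum(y[idx] == 0), 80)   # negatives untouched
  expect_equal(sum(y[idx] == 1), 80)   # positives duplicated to parity
  expect_true(all(seq_along(y) %in% idx))  # no row removed
})

test_that("a linearly separable cohort yields fold f1 of 1 for logistic regression", {
  set.seed(7)
  x <- data.frame(a = c(rnorm(100, -3), rnorm(100, 3)), b = rnorm(200))
  y <- rep(0:1, each = 100)
  m <- tune_and_train(x, y, family = "LR", seed = 1)
  expect_equal(m$cv$mean_f1, 1)
  expect_equal(f1_sep <- hand_f1(predict(m, x), y, 0.5), 1)
})

test_that("a grid with one configuration returns that configuration", {
  set.seed(8)
  x <- data.frame(a = rnorm(120), b = rnorm(120))
  y <- rbinom(120, 1, 0.4)
  g <- list(list(num_trees = 50, mtry = 1))
  m <- tune_and_train(x, y, family = "RF", grid = g, seed = 2)
  expect_identical(m$params, g[[1]])
  expect_error(tune_and_train(x, rep(1, 120), family = "LR"), "single class")
})

test_that("training is deterministic under a fixed seed for LR, RF and XGB", {
  set.seed(9)
  x <- data.frame(a = rnorm(150), b = rnorm(150), c = rnorm(150))
  y <- rbinom(150, 1, plogis(x$a))
  xt <- data.frame(a = rnorm(40), b = rnorm(40), c = rnorm(40))
  for (fam in c("LR", "RF", "XGB")) {
    g <- default_grid(fam)[1]
    m1 <- tune_and_train(x, y, family = fam, grid = g, seed = 5)
    m2 <- tune_and_train(x, y, family = fam, grid = g, seed = 5)
    expect_equal(predict(m1, xt), predict(m2, xt), tolerance = 1e-12)
  }
})

test_that("Platt calibration recovers an identity map for calibrated scores", {
  set.seed(10)
  n <- 5000
  x <- data.frame(a = rnorm(n))
  y <- rbinom(n, 1, plogis(1.2 * x$a - 0.3))
  tr <- 1:2500; va <- 2501:5000
  m <- tune_and_train(x[tr, , drop = FALSE], y[tr], family = "LR", seed = 1)
  cal <- calibrate(m, x[va, , drop = FALSE], y[va])
  expect_identical(cal$map$type, "platt")
  # a well-specified model's scores are already calibrated: slope near 1
  expect_gt(cal$map$b, 0.9)
  expect_lt(cal$map$b, 1.1)
  # monotone calibration leaves the ranking (AUC) unchanged
  p_raw <- predict(m, x[va, , drop = FALSE])
  p_cal <- predict(cal, x[va, , drop = FALSE])
  expect_equal(discriminative_metrics(p_cal, y[va], 0.5)$auc,
               rank_auc(p_raw, y[va]))
})

test_that("a constant classifier degrades to an identity calibration map with warning", {
  probe <- structure(list(), class = "probe_model")
  registerS3method("predict", "probe_model",
                   function(object, newdata, ...) rep(0.4, nrow(newdata)))
  expect_warning(cal <- calibrate(probe, data.frame(a = rnorm(50)),
                                  rbinom(50, 1, 0.5)),
                 "constant")
  expect_identical(cal$map$type, "identity")
  expect_equal(apply_calibration(cal, c(0.2, 0.9)), c(0.2, 0.9))
})

test_that("threshold selection maximises f1 with ties toward the larger threshold", {
  expect_equal(select_threshold(c(0.1, 0.4, 0.8, 0.9), c(0, 0, 1, 1)), 0.8)
  expect_equal(f1_at_sel <- hand_f1(c(0.1, 0.4, 0.8, 0.9), c(0, 0, 1, 1), 0.8), 1)
  # all labels positive: predicting everything positive is optimal
  p <- c(0.3, 0.6, 0.9)
  expect_lte(select_threshold(p, c(1, 1, 1)), min(p))
  # agreement with a brute-force scan on a dense grid
  set.seed(11)
  for (i in 1:20) {
    probs <- runif(60)
    labs <- rbinom(60, 1, probs)
    if (sum(labs) == 0) next
    thr <- select_threshold(probs, labs)
    grid <- seq(0, 1, by = 1e-4)
    best_grid <- max(vapply(grid, function(t) hand_f1(probs, labs, t),
                            numeric(1)))
    expect_equal(hand_f1(probs, labs, thr), best_grid, tolerance = 1e-12)
  }
})

test_that("isotonic calibration is monotone and available behind the flag", {
  set.seed(12)
  n <- 800
  x <- data.frame(a = rnorm(n))
  y <- rbinom(n, 1, plogis(2 * x$a))
  m <- tune_and_train(x[1:400, , drop = FALSE], y[1:400], family = "LR",
                      seed = 1)
  cal <- calibrate(m, x[401:800, , drop = FALSE], y[401:800],
                   method = "isotonic")
  expect_identical(cal$map$type, "isotonic")
  s <- seq(0.01, 0.99, by = 0.01)
  out <- apply_calibration(cal, s)
  expect_true(all(diff(out) >= -1e-12))
  expect_true(all(out >= 0 & out <= 1))
})
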