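test_that("confusion partition is exhaustive, disjoint and threshold-aware", {
  labels <- c(1, 0, 1, 0, 1)
  cp <- confusion_partition(c(1, 0, 1, 0, 1), labels)
  expect_length(cp$fp, 0)
  expect_length(cp$fn, 0)
  expect_equal(sum(cp$counts), 5)
  # threshold 0: everything predicted positive
  cp <- confusion_partition(runif(5), labels, threshold = 0)
  expect_length(cp$tn, 0)
  expect_length(cp$fn, 0)
  expect_equal(sum(cp$counts), 5)
  cp <- confusion_partition(c(0.9, 0.2, 0.4, 0.8, 0.6), labels,
                            ids = letters[1:5], threshold = 0.5)
  expect_setequal(c(cp$tp, cp$fp, cp$tn, cp$fn), letters[1:5])
  expect_identical(cp$fp, "d")
})

test_that("break-down contributions have the linear-model closed form", {
  set.seed(23)
  bg <- data.frame(x1 = rnorm(200, 2), x2 = rnorm(200, -1), x3 = rnorm(200))
  f <- function(d) 2 * d$x1 - 3 * d$x2 + 0.5 * d$x3 + 1
  inst <- data.frame(x1 = 4, x2 = 0, x3 = -2)
  for (ord in list(c("x1", "x2", "x3"), c("x3", "x2", "x1"))) {
    bd <- breakdown_attribution(f, inst, bg, ordering = ord)
    expect_equal(bd$contributions[["x1"]], 2 * (4 - mean(bg$x1)))
    expect_equal(bd$contributions[["x2"]], -3 * (0 - mean(bg$x2)))
    expect_equal(bd$contributions[["x3"]], 0.5 * (-2 - mean(bg$x3)))
    expect_equal(bd$intercept + sum(bd$contributions), bd$prediction)
  }
  # instance at the background mean: all contributions vanish
  inst0 <- data.frame(x1 = mean(bg$x1), x2 = mean(bg$x2), x3 = mean(bg$x3))
  bd <- breakdown_attribution(f, inst0, bg)
  expect_equal(unname(bd$contributions), c(0, 0, 0), tolerance = 1e-12)
  expect_error(breakdown_attribution(f, inst, bg, ordering = c("x1", "zz")),
               "unknown feature")
})

test_that("orderings matter for interacting models; the Shapley average does not", {
  set.seed(24)
  bg <- data.frame(x1 = rnorm(100), x2 = rnorm(100))
  f <- function(d) d$x1 * d$x2
  inst <- data.frame(x1 = 2, x2 = 3)
  b12 <- breakdown_attribution(f, inst, bg, c("x1", "x2"))
  b21 <- breakdown_attribution(f, inst, bg, c("x2", "x1"))
  expect_false(isTRUE(all.equal(b12$contributions[["x1"]],
                                b21$contributions[["x1"]])))
  # both orderings remain additive
  expect_equal(b12$intercept + sum(b12$contributions), b12$prediction)
  expect_equal(b21$intercept + sum(b21$contributions), b21$prediction)
})

test_that("sampled Shapley matches the exhaustive all-orderings average (p <= 5)", {
  set.seed(25)
  p <- 4
  bg <- as.data.frame(matrix(rnorm(50 * p), 50,
                             dimnames = list(NULL, paste0("x", 1:p))))
  f <- function(d) d$x1 * d$x2 + 2 * d$x3 - d$x4^2
  inst <- as.data.frame(as.list(setNames(c(1.5, -0.5, 2, 1), paste0("x", 1:p))))
  # exhaustive oracle: mean of break-down over all p! orderings
  perms <- all_perms(paste0("x", 1:p))
  acc <- setNames(numeric(p), paste0("x", 1:p))
  for (o in perms) {
    acc <- acc + breakdown_attribution(f, inst, bg, o)$contributions[names(acc)]
  }
  exact <- acc / length(perms)
  sh <- shapley_attribution(f, inst, bg, n_orderings = 2000, seed = 2)
  expect_equal(sh$contributions[names(exact)], exact, tolerance = 0.02)
  expect_equal(sh$intercept + sum(sh$contributions), sh$prediction,
               tolerance = 1e-8)
  # determinism under a fixed seed
  sh2 <- shapley_attribution(f, inst, bg, n_orderings = 50, seed = 9)
  expect_identical(sh2$contributions,
                   shapley_attribution(f, inst, bg, n_orderings = 50,
                                       seed = 9)$contributions)
})

test_that("Shapley axioms: symmetry for exchangeable features, null feature gets zero", {
  bg <- data.frame(x1 = c(1, 2, 3, 4), x2 = c(1, 2, 3, 4),
                   x3 = c(0, 1, 0, 1))
  f <- function(d) d$x1 + d$x2   # x3 ignored
  inst <- data.frame(x1 = 5, x2 = 5, x3 = 1)
  sh <- shapley_attribution(f, inst, bg, n_orderings = 40, seed = 3)
  expect_equal(sh$contributions[["x1"]], sh$contributions[["x2"]])
  expect_equal(sh$contributions[["x3"]], 0)
})

test_that("global importance ranks a dominant feature first and a null feature last", {
  set.seed(26)
  bg <- data.frame(big = rnorm(60), small = rnorm(60), none = rnorm(60))
  f <- function(d) 5 * d$big + 0.2 * d$small
  inst <- data.frame(big = rnorm(8), small = rnorm(8), none = rnorm(8))
  imp <- global_importance(f, inst, bg, n_orderings = 30, seed = 4)
  expect_identical(imp$feature[1], "big")
  expect_lt(imp$mean_abs_contribution[imp$feature == "none"], 1e-12)
})

test_that("Monte-Carlo error shrinks roughly as 1/sqrt(orderings)", {
  set.seed(27)
  bg <- data.frame(x1 = rnorm(40), x2 = rnorm(40), x3 = rnorm(40))
  f <- function(d) d$x1 * d$x2 + d$x3 * d$x1
  inst <- data.frame(x1 = 2, x2 = -1, x3 = 1)
  est <- function(m, reps) vapply(seq_len(reps), function(r) {
    shapley_attribution(f, inst, bg, n_orderings = m,
                        seed = 1000 + r)$contributions[["x1"]]
  }, numeric(1))
  se_small <- sd(est(8, 40))
  se_big <- sd(est(32, 40))
  ratio <- se_small / se_big   # expected ~2 for a 4x budget
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3.1)
})

test_that("relabelling with the reference's own specification is a fixed point", {
  b <- tiny_bundle(n = 250, seed = 14)
  ref <- run_aki_pipeline(b, "M3_mean_180to0_or_mdrd", family = "LR",
                          seed = 2, n_boot = 50)
  out <- relabel_experiment(b, ref, methods = "M3_mean_180to0_or_mdrd",
                            family = "LR", n_boot = 50)
  expect_equal(out$summary$f1_delta, 0)
  expect_equal(out$summary$auc, ref$metrics$auc)
  # the FP fraction is computed over the reference FP admissions only
  expect_true(is.na(out$summary$fp_relabelled_positive) ||
                (out$summary$fp_relabelled_positive >= 0 &&
                   out$summary$fp_relabelled_positive <= 1))
})
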