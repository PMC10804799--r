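test_that("MSE and CC agree with closed-form recomputation to 1e-12", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    y <- rnorm(n, sd = 2)
    p <- 0.7 * y + rnorm(n)
    # independent closed forms: crossprod for MSE, covariance ratio for CC
    expect_equal(mse_metric(y, p),
                 as.numeric(crossprod(y - p)) / n, tolerance = 1e-12)
    expect_equal(cc_metric(y, p),
                 stats::cov(y, p) / (sd(y) * sd(p)), tolerance = 1e-12)
  }
  expect_equal(mse_metric(c(2, 4), c(1, 3)), 1.0)
  expect_equal(cc_metric(1:10, 2 * (1:10) + 1), 1.0)  # affine invariance
  expect_equal(mse_metric(1:5, 1:5), 0)
  expect_equal(cc_metric(1:5, 1:5), 1)
})

test_that("correlation with a constant vector is flagged undefined, not zero", {
  expect_true(is.na(cc_metric(rep(1, 5), rnorm(5))))
  rep <- evaluate_predictions(c(1, 1, 2, 3), c(1, 1, 1.5, 2.5),
                              group = c("a", "a", "b", "b"))
  expect_false(rep$per_group$cc_defined[rep$per_group$group == "a"])
  expect_true(rep$per_group$cc_defined[rep$per_group$group == "b"])
})

test_that("overall MSE is the record-weighted mean of squared errors", {
  y <- c(0, 0, 0, 10)
  p <- c(1, 1, 1, 12)
  rep <- evaluate_predictions(y, p, group = c("a", "a", "a", "b"))
  expect_equal(rep$overall$mse,
               sum(rep$per_group$mse * rep$per_group$n) / length(y))
})

test_that("stacked ensemble beats or ties its best base model out of fold", {
  ds <- small_synth()
  fm <- assemble_synth(ds)
  idx <- sample(nrow(fm$x), 150)
  fit <- stack_ensemble(fm$x[idx, ], fm$labels[idx], specs = fast_specs(),
                        folds = 3L, seed = 3L)
  base_mse <- apply(fit$oof_predictions, 2,
                    function(p) mean((fit$y_train - p)^2))
  expect_lte(fit$oof_mse, min(base_mse) + 1e-12)
  expect_equal(sum(fit$weights), 1)
  expect_true(all(fit$weights >= 0))
})

test_that("identical seed and specs reproduce weights and predictions", {
  ds <- small_synth()
  fm <- assemble_synth(ds)
  x <- fm$x[1:120, ]; y <- fm$labels[1:120]
  f1 <- stack_ensemble(x, y, specs = fast_specs(), folds = 3L, seed = 9L)
  f2 <- stack_ensemble(x, y, specs = fast_specs(), folds = 3L, seed = 9L)
  expect_identical(f1$weights, f2$weights)
  newx <- fm$x[121:150, ]
  expect_identical(predict(f1, newx), predict(f2, newx))
  # prediction is a pure function: repeated calls identical
  expect_identical(predict(f1, newx), predict(f1, newx))
})

test_that("noise-free linear labels are fit almost perfectly", {
  set.seed(14)
  n <- 500L
  x <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("v", 1:6)))
  y <- 0.8 * x[, 1] - 0.5 * x[, 3] + 0.2 * x[, 6]
  tr <- 1:400; va <- 401:500
  fit <- stack_ensemble(x[tr, ], y[tr],
                        specs = default_learners(c("gbdt_a",
                                                   "feedforward_net")),
                        folds = 5L, seed = 2L)
  val_mse <- mean((y[va] - predict(fit, x[va, ]))^2)
  # a plain linear fit is the oracle for the attainable error
  lm_mse <- mean((y[va] - predict(lm(y ~ ., data.frame(y = y[tr], x[tr, ])),
                                  data.frame(x[va, ])))^2)
  expect_lt(lm_mse, 1e-20)
  expect_lt(val_mse, 0.01)
})

test_that("a failing base learner is excluded with a warning", {
  ds <- small_synth()
  fm <- assemble_synth(ds)
  x <- fm$x[1:60, ]; y <- fm$labels[1:60]
  specs <- fast_specs()
  specs[[2]]$family <- "no_such_family"
  expect_warning(fit <- stack_ensemble(x, y, specs = specs, folds = 3L,
                                       seed = 1L), "failed to fit")
  expect_length(fit$weights, 1L)
})

test_that("multitask model predicts for receptors unseen in training", {
  ds <- small_synth()
  parts <- split_orphan_receptors(ds$records, 8L)
  split <- stratified_split(parts$modelled, 0.8, seed = 4L,
                            orphan_test = parts$orphan)
  fm <- assemble_synth(ds)
  mtl <- train_multitask(fm, split, "merged", specs = fast_specs(),
                         folds = 3L, seed = 4L)
  # orphan receptor absent from training: prediction defined and finite
  expect_gt(nrow(split$orphan_test), 0L)
  orp <- subset_records(fm, split$orphan_test$record_id)
  expect_true(all(is.finite(predict(mtl, orp))))
  expect_false(any(split$orphan_test$receptor_id %in%
                     split$train$receptor_id))
})

test_that("mode filters subset the task records and reject empty tasks", {
  ds <- small_synth()
  parts <- split_orphan_receptors(ds$records, 8L)
  split <- stratified_split(parts$modelled, 0.8, seed = 4L)
  fm <- assemble_synth(ds)
  ag <- train_multitask(fm, split, "agonist", specs = fast_specs(),
                        folds = 3L, seed = 4L)
  expect_equal(ag$mode_filter, "agonist")
  expect_equal(ag$ensemble$n_train, sum(split$train$mode == "agonist"))
  empty <- split
  empty$train <- split$train[split$train$mode == "neither", ]
  expect_error(train_multitask(fm, empty, "agonist", specs = fast_specs()),
               "no training records")
})

test_that("single-task training skips groups below the minimum size", {
  ds <- small_synth()
  parts <- split_orphan_receptors(ds$records, 8L)
  split <- stratified_split(parts$modelled, 0.8, seed = 4L)
  fm <- assemble_synth(ds)
  # shrink one receptor's training records to 3 to force a skip
  victim <- unique(split$train$receptor_id)[1]
  vict_rows <- which(split$train$receptor_id == victim)
  split$train <- split$train[-vict_rows[-(1:3)], ]
  stl <- train_single_task(fm, split, "merged", min_group = 4L,
                           specs = fast_specs(), folds = 3L, seed = 4L)
  expect_true(victim %in% stl$skipped$group)
  expect_false(victim %in% names(stl$fits))
  expect_gt(length(stl$fits), 0L)
})

test_that("Mann-Whitney matches the spec's exact enumeration example", {
  got <- compare_model_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$U, 0)
  expect_equal(got$p, 0.1)   # 2/20 arrangements as extreme
  expect_equal(got$method, "exact enumeration")
  same <- compare_model_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  tied <- compare_model_groups(rep(2, 4), rep(2, 3))
  expect_equal(tied$p, 1)
})

test_that("exact U and p match an independent enumeration for all small layouts", {
  set.seed(31)
  for (n1 in 1:7) for (n2 in 1:(8 - n1)) {
    a <- sample(1:4, n1, replace = TRUE)     # draws with ties
    b <- sample(1:4, n2, replace = TRUE)
    got <- compare_model_groups(a, b)
    want <- oracle_mannwhitney(a, b)
    expect_equal(got$U, want$U, info = paste(n1, n2))
    expect_equal(got$p, want$p, info = paste(n1, n2))
  }
  # tie-free case cross-checked against the standard implementation
  a <- c(1.2, 3.4, 2.2, 5.1); b <- c(0.5, 4.4, 6.2)
  got <- compare_model_groups(a, b)
  ref <- wilcox.test(a, b, exact = TRUE)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
})

test_that("normal approximation tracks the exact p at moderate sizes", {
  set.seed(32)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(6, mean = runif(1, -1, 1))
    exact <- compare_model_groups(a, b, exact_max = 12L)
    approx <- compare_model_groups(a, b, exact_max = 0L)
    expect_equal(approx$method, "normal approximation")
    expect_lt(abs(exact$p - approx$p), 0.02)
  }
})
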