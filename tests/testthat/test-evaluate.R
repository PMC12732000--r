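# Metric identities, cross-validation, rolling windows, importance and
# permutation attribution.

test_that("classification metrics match hand-worked contingency arithmetic", {
  labels <- c(rep(1, 10), rep(-1, 10))
  preds <- c(rep(1, 9), -1, rep(-1, 9), 1)
  m <- classification_metrics(labels, preds)
  expect_equal(m$TP, 9); expect_equal(m$FP, 1)
  expect_equal(m$FN, 1); expect_equal(m$TN, 9)
  expect_equal(m$precision, 0.9, tolerance = 1e-12)
  expect_equal(m$recall, 0.9, tolerance = 1e-12)
  expect_equal(m$f1, 0.9, tolerance = 1e-12)
  expect_equal(m$accuracy, 0.9, tolerance = 1e-12)
  expect_equal(m$accuracy, (m$TP + m$TN) / length(labels))
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall),
               tolerance = 1e-12)

  perfect <- classification_metrics(labels, labels, scores = labels)
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1",
                                "auroc")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1,
                 auroc = 1))
  reversed <- classification_metrics(labels, preds, scores = -labels)
  expect_equal(reversed$auroc, 0)
  # zero denominator flagged undefined, not zero
  none_pos <- classification_metrics(c(1, -1), c(-1, -1))
  expect_true(is.na(none_pos$precision))
  expect_error(classification_metrics(c(1, 1), c(1, 1), scores = c(1, 2)),
               "one class")
})

test_that("AUROC equals the brute-force pair-ordering fraction", {
  set.seed(8)
  for (i in 1:3) {
    n <- 150
    labels <- sample(c(-1, 1), n, replace = TRUE)
    scores <- round(rnorm(n), 1)   # rounding forces ties
    m <- classification_metrics(labels, ifelse(scores > 0, 1, -1), scores)
    pos <- scores[labels == 1]; neg <- scores[labels == -1]
    pairs <- outer(pos, neg, function(p, q)
      (p > q) + 0.5 * (p == q))
    expect_equal(m$auroc, mean(pairs), tolerance = 1e-12)
  }
})

test_that("regression metrics match their definitions", {
  y <- c(1, 2, 3, 4)
  m <- regression_metrics(y, y)
  expect_equal(m$rmse, 0); expect_equal(m$r2, 1)
  expect_equal(regression_metrics(c(0, 0), c(1, -1))$rmse, 1,
               tolerance = 1e-12)
  expect_equal(regression_metrics(y, rep(mean(y), 4))$r2, 0,
               tolerance = 1e-12)
  # constant observations: RMSE still defined, R2 flagged NA (not 0)
  const <- regression_metrics(c(0, 0), c(1, -1))
  expect_equal(const$rmse, 1, tolerance = 1e-12)
  expect_true(is.na(const$r2))
})

test_that("k-fold CV partitions rows and scores each exactly once", {
  d <- fx_prep()
  X <- d$train[1:200, AD_IN]
  y <- d$train$biogas_yield[1:200]
  cv <- kfold_cv(svm_spec("regress"), X, y, k = 5)
  expect_length(cv$folds, 5)
  expect_equal(sort(unique(cv$fold_id)), 1:5)
  expect_equal(length(cv$fold_id), 200)
  expect_equal(as.numeric(table(cv$fold_id)), rep(40, 5))

  loo <- kfold_cv(svm_spec("regress"), X[1:10, ], y[1:10], k = 10)
  expect_length(loo$folds, 10)
  expect_equal(as.numeric(table(loo$fold_id)), rep(1, 10))
  expect_true(all(vapply(loo$folds, function(f) is.na(f$r2), logical(1))))
})

test_that("CV error grows when noise is added to a clean target", {
  d <- fx_prep()
  X <- d$train[1:400, AD_IN]
  y_clean <- 2 * X$feed_solids + X$organic_matter
  set.seed(12)
  y_noisy <- y_clean + rnorm(400, 0, 0.3)
  cv_clean <- kfold_cv(rf_spec(n_trees = 50), X, y_clean, seed = 1)
  cv_noisy <- kfold_cv(rf_spec(n_trees = 50), X, y_noisy, seed = 1)
  expect_lt(cv_clean$mean, cv_noisy$mean)
})

test_that("rolling windows advance correctly and respect time order", {
  d <- fx_prep()
  X <- d$train[1:30, AD_IN]
  y <- d$train$biogas_yield[1:30]
  rw <- rolling_window_eval(svm_spec("regress"), X, y, window = 20, step = 5)
  expect_equal(nrow(rw), 2)
  expect_equal(rw$start, c(1, 6))
  one <- rolling_window_eval(svm_spec("regress"), X, y, window = 25,
                             step = 5)
  expect_equal(nrow(one), 1)
  expect_error(rolling_window_eval(svm_spec("regress"), X, y, 28, 5),
               "exceed")
})

test_that("window error shows no monotone trend on a stationary series", {
  d <- fx_prep()
  X <- d$train[, AD_IN]
  y <- d$train$biogas_yield
  rw <- rolling_window_eval(rf_spec(n_trees = 50), X, y,
                            window = 800, step = 250, seed = 2)
  expect_gte(nrow(rw), 6)
  trend <- summary(lm(rmse ~ window, data = rw))$coefficients
  ci <- trend["window", 1] + c(-2, 2) * trend["window", 2]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("RF importance shares are normalized and rank the core drivers", {
  d <- fx_prep()
  m1 <- fit_model(rf_spec(n_trees = 50),
                  d$train[, "feed_solids", drop = FALSE],
                  d$train$biogas_yield)
  expect_equal(unname(rf_importance(m1)), 1.0)

  shares <- rf_importance(fx_models()$rf)
  expect_equal(sum(shares), 1, tolerance = 1e-9)
  expect_gt(shares[["feed_solids"]], shares[["organic_matter"]])
  expect_gt(shares[["organic_matter"]], shares[["feed_rate"]])
  expect_error(rf_importance(fx_models()$svm), "random-forest")

  noisy <- fx_rf_noise()
  sh <- rf_importance(noisy$model)
  expect_lt(sh[["noise_feature"]],
            min(sh[c("feed_solids", "organic_matter", "feed_rate")]))
})

test_that("permutation delta-RMSE separates core from auxiliary features", {
  noisy <- fx_rf_noise()
  d_core <- permutation_delta_rmse(noisy$model, noisy$X_test, noisy$y_test,
                                   "feed_solids", n_perm = 5, seed = 1)
  d_noise <- permutation_delta_rmse(noisy$model, noisy$X_test, noisy$y_test,
                                    "noise_feature", n_perm = 5, seed = 1)
  expect_gt(d_core$delta_rmse, d_noise$delta_rmse)
  expect_lt(abs(d_noise$delta_rmse), 0.2 * d_core$baseline_rmse)

  r1 <- permutation_delta_rmse(noisy$model, noisy$X_test, noisy$y_test,
                               "feed_solids", n_perm = 1, seed = 9)
  r2 <- permutation_delta_rmse(noisy$model, noisy$X_test, noisy$y_test,
                               "feed_solids", n_perm = 1, seed = 9)
  expect_identical(r1, r2)
})
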