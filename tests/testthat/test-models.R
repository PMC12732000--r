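# Model fitting, prediction and grid search under the shared protocol.

test_that("high-yield labelling applies the 70 m3/t threshold", {
  expect_equal(label_high_yield(81.3), 1L)
  expect_equal(label_high_yield(70.0), 1L)
  expect_equal(label_high_yield(69.999), -1L)
  expect_equal(label_high_yield(c(65, 75)), c(-1L, 1L))
  expect_error(label_high_yield(NaN), "finite")
})

test_that("SVM separates a linearly separable toy problem perfectly", {
  set.seed(2)
  X <- data.frame(a = c(rnorm(30, -4), rnorm(30, 4)), b = rnorm(60))
  y <- rep(c(-1L, 1L), each = 30)
  fit <- fit_model(svm_spec("classify", C = 100, gamma = 0.5), X, y)
  pred <- predict(fit, X)
  expect_equal(mean(pred$label == y), 1.0)
  expect_true(all(pred$score[y == 1] > pred$score[y == -1][1:5]))
  expect_error(fit_model(svm_spec("classify"), X, rep(1L, 60)),
               "one class")
})

test_that("all three families reproduce a constant target", {
  set.seed(3)
  X <- data.frame(a = runif(80), b = runif(80))
  y <- rep(4.2, 80)
  for (spec in list(svm_spec("regress"), rf_spec(n_trees = 20),
                    fx_ann_spec(max_epochs = 5))) {
    fit <- fit_model(spec, X, y)
    expect_lt(max(abs(predict(fit, X)[[1]] - 4.2)), 1e-6)
  }
})

test_that("predictions are deterministic and honour the feature contract", {
  d <- fx_prep()
  m <- fx_models()
  X <- d$test[, AD_IN]
  expect_identical(predict(m$rf, X), predict(m$rf, X))
  expect_identical(predict(m$ann, X), predict(m$ann, X))
  # columns are matched by name, order-independent
  expect_equal(predict(m$ann, X[, rev(AD_IN)]), predict(m$ann, X))
  expect_error(predict(m$ann, X[, 1:3]), "missing")
})

test_that("a single-tree forest equals its tree, and the forest beats its average tree", {
  d <- fx_prep()
  X <- d$train[, AD_IN]
  y <- d$train$biogas_yield
  Xte <- d$test[, AD_IN]
  m1 <- fit_model(rf_spec(n_trees = 1), X, y, seed = 5L)
  p_all <- predict(m1$fit, data.frame(as_feature_matrix(Xte),
                                      check.names = FALSE),
                   predict.all = TRUE, num.threads = 1)$predictions
  expect_equal(predict(m1, Xte)[[1]], unname(p_all[, 1]))

  m <- fx_models()$rf
  p_trees <- predict(m$fit, data.frame(as_feature_matrix(Xte),
                                       check.names = FALSE),
                     predict.all = TRUE, num.threads = 1)$predictions
  yte <- d$test$biogas_yield
  mse_forest <- mean((rowMeans(p_trees) - yte)^2)
  mse_trees <- mean(colMeans((p_trees - yte)^2))
  expect_lte(mse_forest, mse_trees)
})

test_that("ANN training objective improves and early stopping retains the best weights", {
  m <- fx_models()$ann
  hist <- m$fit$history
  expect_gt(length(hist), 1)
  expect_true(all(diff(cummin(hist)) <= 0))
  expect_lte(m$fit$best_epoch, length(hist))
  expect_lte(m$fit$best_val_loss, hist[1])
})

test_that("ANN beats RF beats a linear baseline on noise-free responses", {
  cfg <- fx_config_nofault()
  wins <- vapply(1:5, function(s) {
    rec <- generate_records(cfg, 2000, seed = 200 + s)
    rec$biogas_yield <- true_response(cfg, rec$feed_solids,
                                      rec$organic_matter, rec$feed_rate,
                                      rec$regime)$biogas_yield
    sp <- split_records(rec)
    np <- minmax_fit(sp$train, c(AD_IN, "biogas_yield"))
    tr <- minmax_apply(sp$train, np)
    va <- minmax_apply(sp$validation, np)
    te <- minmax_apply(sp$test, np)
    m_rf <- fit_model(rf_spec(), tr[, AD_IN], tr$biogas_yield, seed = s)
    m_ann <- fit_model(fx_ann_spec(), tr[, AD_IN],
                       data.frame(biogas_yield = tr$biogas_yield),
                       X_val = va[, AD_IN],
                       y_val = data.frame(biogas_yield = va$biogas_yield),
                       seed = s)
    m_lin <- lm(y ~ ., data = cbind(tr[, AD_IN], y = tr$biogas_yield))
    rmse <- function(p) sqrt(mean((p - te$biogas_yield)^2))
    r <- c(ann = rmse(predict(m_ann, te[, AD_IN])[[1]]),
           rf = rmse(predict(m_rf, te[, AD_IN])[[1]]),
           lin = rmse(predict(m_lin, te[, AD_IN])))
    r["ann"] < r["rf"] && r["rf"] < r["lin"]
  }, logical(1))
  expect_gte(sum(wins), 4)
})

test_that("grid search returns the CV argmin with first-in-grid tie breaking", {
  d <- fx_prep()
  X <- d$train[1:600, AD_IN]
  y <- d$train$biogas_yield[1:600]
  single <- grid_search(svm_spec("regress"), list(C = 10), X, y, folds = 3)
  expect_equal(single$best_spec$C, 10)
  gs <- grid_search(svm_spec("regress"),
                    list(C = c(1, 10), gamma = c(0.05, 0.5)), X, y,
                    folds = 3)
  expect_equal(min(gs$scores$cv_loss), gs$best_score)
  expect_true(all(gs$best_score <= gs$scores$cv_loss))
  first_min <- which(gs$scores$cv_loss == gs$best_score)[1]
  expect_equal(gs$best_spec$C, gs$scores$C[first_min])
  expect_error(grid_search(svm_spec("regress"), list(), X, y), "grid")
})

test_that("fitting rejects misaligned rows", {
  X <- data.frame(a = 1:10, b = 1:10)
  expect_error(fit_model(rf_spec(), X, 1:9), "row counts differ")
})
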