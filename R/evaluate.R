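# Model evaluation: classification metrics (precision/recall/F1/AUROC),
# regression metrics (RMSE, R2), five-fold cross-validation, rolling-window
# evaluation, random-forest importance shares and permutation delta-RMSE.

#' Classification metrics
#'
#' Precision, recall, F1, accuracy and AUROC for +1/-1 labels. AUROC uses
#' the rank statistic with midrank tie handling (equivalent to the
#' trapezoidal ROC area). Metrics with a zero denominator are reported as
#' `NA` (flagged undefined), never as 0.
#'
#' @param labels true labels in `{+1, -1}`.
#' @param predictions predicted labels in `{+1, -1}`.
#' @param scores real-valued scores (larger = more positive) for AUROC;
#'   optional.
#' @return Object of class `classification_metrics`: accuracy, precision,
#'   recall, f1, auroc and the confusion counts.
#' @export
classification_metrics <- function(labels, predictions, scores = NULL) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must align")
  if (!all(labels %in% c(-1, 1)) || !all(predictions %in% c(-1, 1)))
    stop("labels must be +1/-1")
  tp <- sum(labels == 1 & predictions == 1)
  fp <- sum(labels == -1 & predictions == 1)
  fn <- sum(labels == 1 & predictions == -1)
  tn <- sum(labels == -1 & predictions == -1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  auroc <- if (!is.null(scores)) auroc_midrank(labels, scores) else NA_real_
  structure(list(accuracy = (tp + tn) / length(labels),
                 precision = precision, recall = recall, f1 = f1,
                 auroc = auroc, TP = tp, FP = fp, FN = fn, TN = tn),
            class = "classification_metrics")
}

auroc_midrank <- function(labels, scores) {
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == -1)
  if (n_pos == 0 || n_neg == 0)
    stop("AUROC undefined: only one class present")
  r <- rank(scores)   # midranks for ties
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(
    "<classification_metrics> acc %.3f prec %.3f rec %.3f f1 %.3f auroc %s\n",
    x$accuracy, x$precision, x$recall, x$f1,
    ifelse(is.na(x$auroc), "NA", sprintf("%.3f", x$auroc))))
  invisible(x)
}

#' Regression metrics
#'
#' @param y observed values (n >= 1).
#' @param yhat predictions, aligned with `y`.
#' @return Object of class `regression_metrics` with `rmse` (target units)
#'   and `r2` (`1 - SS_res/SS_tot`; flagged `NA` -- undefined, never 0 --
#'   when `y` is constant).
#' @export
regression_metrics <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must align")
  if (length(y) < 1) stop("need at least 1 observation")
  rmse <- sqrt(mean((y - yhat)^2))
  ss_tot <- sum((y - mean(y))^2)
  structure(list(rmse = rmse,
                 r2 = if (ss_tot == 0) NA_real_
                      else 1 - sum((y - yhat)^2) / ss_tot),
            class = "regression_metrics")
}

#' @export
print.regression_metrics <- function(x, ...) {
  cat(sprintf("<regression_metrics> rmse %.4g r2 %.4f\n", x$rmse, x$r2))
  invisible(x)
}

## ---- cross-validation ----------------------------------------------------

#' k-fold cross-validation
#'
#' Folds are contiguous in time by default (consistent with the
#' chronological split and deployment setting); `shuffle = TRUE` gives
#' seeded random folds. Each row is scored exactly once, out-of-fold.
#'
#' @param spec model specification.
#' @param X,y data (single target; +1/-1 labels give classification
#'   metrics).
#' @param k number of folds (2 <= k <= n).
#' @param shuffle randomize fold membership.
#' @param seed seed for shuffling and fits.
#' @return list with `folds` (per-fold metric objects), `fold_id`, `mean`
#'   and `sd` of the primary metric (rmse or accuracy).
#' @export
kfold_cv <- function(spec, X, y, k = 5, shuffle = FALSE, seed = 42L) {
  Xm <- as_feature_matrix(X)
  n <- nrow(Xm)
  if (k < 2 || k > n) stop("k must be between 2 and n")
  fold_id <- as.integer(cut(seq_len(n), breaks = k, labels = FALSE))
  if (shuffle) fold_id <- with_seed(seed, sample(fold_id))
  classify <- all(y %in% c(-1, 1))
  folds <- lapply(seq_len(k), function(i) {
    tr <- fold_id != i
    fit <- fit_model(spec, Xm[tr, , drop = FALSE], y[tr], seed = seed)
    pred <- predict(fit, Xm[!tr, , drop = FALSE])
    if (classify)
      classification_metrics(y[!tr], pred$label, pred$score)
    else regression_metrics(y[!tr], pred[[1]])
  })
  primary <- vapply(folds, function(m)
    if (classify) m$accuracy else m$rmse, numeric(1))
  list(folds = folds, fold_id = fold_id,
       metric = if (classify) "accuracy" else "rmse",
       mean = mean(primary), sd = stats::sd(primary))
}

#' Rolling-window evaluation
#'
#' Trains on `[t, t + window)` and tests on `[t + window, t + window +
#' step)`, advancing by `step`; no test row ever precedes its training
#' window.
#'
#' @param spec model specification.
#' @param X,y data in time order (single target).
#' @param window training-window length (rows).
#' @param step test-block length and advance (rows).
#' @param seed seed for fits.
#' @return data.frame with one row per evaluation window: `window`, `start`,
#'   `rmse` (or `accuracy`), `n_test`.
#' @export
rolling_window_eval <- function(spec, X, y, window, step, seed = 42L) {
  Xm <- as_feature_matrix(X)
  n <- nrow(Xm)
  if (window + step > n) stop("window + step must not exceed n")
  classify <- all(y %in% c(-1, 1))
  starts <- seq(1L, n - window - step + 1L, by = step)
  rows <- lapply(seq_along(starts), function(i) {
    s <- starts[i]
    tr <- s:(s + window - 1L)
    te <- (s + window):(s + window + step - 1L)
    fit <- fit_model(spec, Xm[tr, , drop = FALSE], y[tr], seed = seed)
    pred <- predict(fit, Xm[te, , drop = FALSE])
    val <- if (classify) mean(pred$label == y[te])
           else sqrt(mean((pred[[1]] - y[te])^2))
    data.frame(window = i, start = s, metric = val, n_test = length(te))
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "metric"] <-
    if (classify) "accuracy" else "rmse"
  out
}

## ---- feature attribution -------------------------------------------------

#' Random-forest importance shares
#'
#' Impurity-decrease importances of a fitted random forest, normalized to
#' shares summing to 1.
#'
#' @param model a [fit_model()] result with an `rf_spec`.
#' @return named numeric vector of per-feature shares.
#' @export
rf_importance <- function(model) {
  if (!inherits(model, "fitted_model") || !inherits(model$spec, "rf_spec"))
    stop("rf_importance requires a fitted random-forest model")
  imp <- model$fit$variable.importance
  imp / sum(imp)
}

#' Permutation delta-RMSE of a feature
#'
#' Mean increase in test RMSE after permuting one feature column, over
#' `n_perm` seeded permutations.
#'
#' @param model fitted regression model.
#' @param X,y held-out data.
#' @param feature feature to permute.
#' @param n_perm number of permutations.
#' @param seed permutation seed.
#' @param target prediction column for multi-target models.
#' @return list with `delta_rmse`, `baseline_rmse`, `per_permutation`.
#' @export
permutation_delta_rmse <- function(model, X, y, feature, n_perm = 10,
                                   seed = 42L, target = model$targets[1]) {
  if (!feature %in% names(X)) stop("unknown feature: ", feature)
  base <- sqrt(mean((y - predict(model, X)[[target]])^2))
  rmses <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    Xp <- X
    Xp[[feature]] <- Xp[[feature]][sample.int(nrow(Xp))]
    sqrt(mean((y - predict(model, Xp)[[target]])^2))
  }, numeric(1)))
  list(delta_rmse = mean(rmses) - base, baseline_rmse = base,
       per_permutation = rmses)
}

#' Flat metrics table for a set of fitted models
#'
#' @param metrics named list of metric objects
#'   (`classification_metrics`/`regression_metrics`), names formatted
#'   `model.target`.
#' @return data.frame in long format: model, target, metric, value.
#' @export
metrics_table <- function(metrics) {
  rows <- lapply(names(metrics), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    m <- metrics[[nm]]
    vals <- unclass(m)[vapply(unclass(m), is.numeric, logical(1))]
    data.frame(model = parts[1],
               target = if (length(parts) > 1) parts[2] else NA,
               metric = names(vals), value = unlist(vals),
               row.names = NULL)
  })
  do.call(rbind, rows)
}
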