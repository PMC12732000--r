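# Three predictors under one protocol: SVM (RBF kernel, classification and
# epsilon-regression), random forest (majority vote / ensemble mean), and a
# two-hidden-layer feed-forward network trained by Adam on a penalized
# squared-error objective (mean squared error + lambda * ||theta||^2) with
# early stopping on validation loss. SVM and RF delegate to e1071 and ranger;
# the network trainer is implemented here so the objective and stopping rule
# are exactly as specified.

#' Model specifications
#'
#' Construct hyperparameter specifications for the three model families.
#' Defaults are the tuned values used throughout: SVM `C = 10`,
#' `gamma = 0.05`; RF 100 trees of depth 18 with `mtry = 2`; ANN hidden
#' sizes `[128, 64]`, ReLU activations, learning rate 0.001, batch 64,
#' `l2_lambda = 0.001`.
#'
#' @param task `"regress"` or `"classify"` (SVM only; RF infers the task
#'   from the response type).
#' @param C,gamma,epsilon SVM penalty, RBF kernel width and insensitive-zone
#'   half-width (regression only, in scaled units).
#' @param n_trees,max_depth,mtry random-forest size, depth cap and features
#'   per split.
#' @param hidden_sizes,learning_rate,batch_size,l2_lambda,max_epochs,
#'   early_stop_patience ANN architecture and training controls.
#' @param seed seed for stochastic fits.
#' @return An object of class `svm_spec`, `rf_spec` or `ann_spec`.
#' @name model_specs
NULL

#' @rdname model_specs
#' @export
svm_spec <- function(task = c("regress", "classify"), C = 10, gamma = 0.05,
                     epsilon = 0.1) {
  task <- match.arg(task)
  stopifnot(C > 0, gamma > 0, epsilon >= 0)
  structure(list(task = task, C = C, gamma = gamma, epsilon = epsilon),
            class = c("svm_spec", "model_spec"))
}

#' @rdname model_specs
#' @export
rf_spec <- function(n_trees = 100, max_depth = 18, mtry = 2, seed = 42L) {
  stopifnot(n_trees >= 1, max_depth >= 1, mtry >= 1)
  structure(list(n_trees = n_trees, max_depth = max_depth, mtry = mtry,
                 seed = seed),
            class = c("rf_spec", "model_spec"))
}

#' @rdname model_specs
#' @export
ann_spec <- function(hidden_sizes = c(128, 64), learning_rate = 0.001,
                     batch_size = 64, l2_lambda = 0.001, max_epochs = 500,
                     early_stop_patience = 20, seed = 42L) {
  stopifnot(all(hidden_sizes >= 1), learning_rate > 0, l2_lambda >= 0,
            batch_size >= 1, max_epochs >= 1, early_stop_patience >= 1)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 l2_lambda = l2_lambda, max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = seed),
            class = c("ann_spec", "model_spec"))
}

#' Compact ANN preset
#'
#' Alternative lightweight architecture (two hidden layers of 32 neurons)
#' considered during architecture comparison; not the default.
#' @param ... overrides passed to [ann_spec()].
#' @export
ann_spec_compact <- function(...) ann_spec(hidden_sizes = c(32, 32), ...)

#' Label records as high or low biogas yield
#'
#' @param biogas_yield numeric yields (m3/t); must be finite.
#' @return `+1` where yield >= 70 m3/t, `-1` otherwise.
#' @export
label_high_yield <- function(biogas_yield) {
  if (any(!is.finite(biogas_yield))) stop("biogas_yield must be finite")
  ifelse(biogas_yield >= 70, 1L, -1L)
}

as_feature_matrix <- function(X, variables = NULL) {
  X <- as.data.frame(X)
  if (!is.null(variables)) {
    miss <- setdiff(variables, names(X))
    if (length(miss))
      stop("feature columns missing: ", paste(miss, collapse = ", "))
    X <- X[, variables, drop = FALSE]
  }
  as.matrix(X)
}

#' Fit a predictor
#'
#' Trains a model on scaled features. Targets may be a vector (single
#' target), or for the ANN a data.frame/matrix of multiple targets.
#' Classification targets are the `+1`/`-1` labels of [label_high_yield()].
#' Fitting consumes only the training rows (plus the optional validation
#' rows, used by the ANN's early stopping); test rows must never be passed.
#'
#' @param spec an `svm_spec`, `rf_spec` or `ann_spec`.
#' @param X training features (scaled), data.frame or matrix.
#' @param y target vector or (ANN) multi-target table.
#' @param X_val,y_val optional validation data for ANN early stopping; if
#'   omitted the chronologically last 20% of the training rows are held out.
#' @param norm_params optional [minmax_fit()] parameters carried along for
#'   prediction-time scaling.
#' @param seed seed override.
#' @return An object of class `fitted_model`.
#' @export
fit_model <- function(spec, X, y, X_val = NULL, y_val = NULL,
                      norm_params = NULL, seed = NULL) {
  UseMethod("fit_model")
}

new_fitted_model <- function(spec, fit, variables, targets, task,
                             norm_params, extra = list()) {
  structure(c(list(spec = spec, fit = fit, variables = variables,
                   targets = targets, task = task,
                   norm_params = norm_params), extra),
            class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat("<fitted_model>", class(x$spec)[1], "| task:", x$task,
      "| targets:", paste(x$targets, collapse = ", "),
      "| features:", length(x$variables), "\n")
  invisible(x)
}

check_xy <- function(X, y) {
  ym <- if (is.null(dim(y))) matrix(y, ncol = 1) else as.matrix(y)
  if (nrow(ym) != nrow(X)) stop("X and y row counts differ")
  ym
}

#' @export
fit_model.svm_spec <- function(spec, X, y, X_val = NULL, y_val = NULL,
                               norm_params = NULL, seed = NULL) {
  Xm <- as_feature_matrix(X)
  ym <- check_xy(Xm, y)
  if (ncol(ym) > 1) stop("SVM fits one target at a time")
  yv <- ym[, 1]
  if (spec$task == "classify") {
    if (length(unique(yv)) < 2)
      stop("degenerate classification input: only one class present")
    fit <- e1071::svm(Xm, factor(yv, levels = c(-1, 1)),
                      type = "C-classification", kernel = "radial",
                      cost = spec$C, gamma = spec$gamma, scale = FALSE)
  } else if (stats::sd(yv) == 0) {
    # constant target: every point sits inside the epsilon tube, leaving no
    # support vectors; return the exact constant predictor
    fit <- list(constant = yv[1])
  } else {
    fit <- e1071::svm(Xm, yv, type = "eps-regression", kernel = "radial",
                      cost = spec$C, gamma = spec$gamma,
                      epsilon = spec$epsilon, scale = FALSE)
  }
  new_fitted_model(spec, fit, colnames(Xm),
                   targets = if (is.null(colnames(ym))) "y" else colnames(ym),
                   task = spec$task, norm_params = norm_params)
}

#' @export
fit_model.rf_spec <- function(spec, X, y, X_val = NULL, y_val = NULL,
                              norm_params = NULL, seed = NULL) {
  Xm <- as_feature_matrix(X)
  ym <- check_xy(Xm, y)
  if (ncol(ym) > 1) stop("random forest fits one target at a time")
  yv <- ym[, 1]
  classify <- all(yv %in% c(-1, 1)) && length(unique(yv)) <= 2
  if (classify && length(unique(yv)) < 2)
    stop("degenerate classification input: only one class present")
  dat <- data.frame(Xm, check.names = FALSE)
  dat$.target <- if (classify) factor(yv, levels = c(-1, 1)) else yv
  fit <- ranger::ranger(
    dependent.variable.name = ".target", data = dat,
    num.trees = spec$n_trees, mtry = min(spec$mtry, ncol(Xm)),
    max.depth = spec$max_depth, importance = "impurity",
    probability = classify, seed = if (is.null(seed)) spec$seed else seed,
    num.threads = 1
  )
  new_fitted_model(spec, fit, colnames(Xm),
                   targets = if (is.null(colnames(ym))) "y" else colnames(ym),
                   task = if (classify) "classify" else "regress",
                   norm_params = norm_params)
}

#' @export
fit_model.ann_spec <- function(spec, X, y, X_val = NULL, y_val = NULL,
                               norm_params = NULL, seed = NULL) {
  Xm <- as_feature_matrix(X)
  ym <- check_xy(Xm, y)
  targets <- colnames(ym)
  if (is.null(targets)) targets <- paste0("y", seq_len(ncol(ym)))
  if (is.null(X_val)) {
    # hold out the chronologically last fifth of the training block
    n <- nrow(Xm)
    cut <- max(floor(0.8 * n), 1L)
    X_val <- Xm[(cut + 1):n, , drop = FALSE]
    y_val <- ym[(cut + 1):n, , drop = FALSE]
    Xm <- Xm[seq_len(cut), , drop = FALSE]
    ym <- ym[seq_len(cut), , drop = FALSE]
  } else {
    X_val <- as_feature_matrix(X_val, colnames(Xm))
    y_val <- check_xy(X_val, y_val)
  }
  fit <- ann_train(Xm, ym, X_val, y_val, spec,
                   seed = if (is.null(seed)) spec$seed else seed)
  new_fitted_model(spec, fit, colnames(Xm), targets = targets,
                   task = "regress", norm_params = norm_params)
}

## ---- ANN internals -------------------------------------------------------

ann_init <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b)
}

ann_forward <- function(par, X) {
  L <- length(par$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% par$W[[l]], 2L, par$b[[l]], "+")
    A[[l + 1L]] <- if (l < L) pmax(Z, 0) else Z   # ReLU hidden, linear out
  }
  A
}

# penalized objective: mean over rows of squared-error norm + l2 * ||W||^2
ann_loss <- function(par, X, Y, l2) {
  Yhat <- ann_forward(par, X)[[length(par$W) + 1L]]
  mse <- sum((Yhat - Y)^2) / nrow(X)
  mse + l2 * sum(vapply(par$W, function(w) sum(w^2), numeric(1)))
}

ann_train <- function(X, Y, X_val, Y_val, spec, seed) {
  # targets standardized internally (affine reparameterization); constant
  # targets short-circuit to an exact constant predictor
  centers <- colMeans(Y)
  scales <- apply(Y, 2, stats::sd)
  if (all(scales == 0)) {
    return(list(constant = centers, centers = centers,
                scales = rep(1, length(centers)), history = numeric(0)))
  }
  scales[scales == 0] <- 1
  Ys <- sweep(sweep(Y, 2L, centers), 2L, scales, "/")
  Yvs <- sweep(sweep(Y_val, 2L, centers), 2L, scales, "/")

  sizes <- c(ncol(X), spec$hidden_sizes, ncol(Y))
  L <- length(sizes) - 1L
  lr <- spec$learning_rate; l2 <- spec$l2_lambda
  n <- nrow(X)
  nb <- max(1L, ceiling(n / spec$batch_size))

  with_seed(seed, {
    par <- ann_init(sizes)
    mW <- lapply(par$W, function(w) w * 0); vW <- mW
    mb <- lapply(par$b, function(b) b * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0L
    best <- list(loss = Inf, par = par, epoch = 0L)
    history <- numeric(0)
    wait <- 0L

    for (epoch in seq_len(spec$max_epochs)) {
      ord <- sample.int(n)
      for (ib in seq_len(nb)) {
        rows <- ord[(((ib - 1L) * spec$batch_size) + 1L):
                      min(ib * spec$batch_size, n)]
        Xb <- X[rows, , drop = FALSE]
        Yb <- Ys[rows, , drop = FALSE]
        A <- ann_forward(par, Xb)
        m <- length(rows)
        delta <- 2 * (A[[L + 1L]] - Yb) / m
        for (l in L:1) {
          gW <- crossprod(A[[l]], delta) + 2 * l2 * par$W[[l]]
          gb <- colSums(delta)
          if (l > 1L)
            delta <- (delta %*% t(par$W[[l]])) * (A[[l]] > 0)
          step <- step + 1L
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          corr1 <- 1 - beta1^step; corr2 <- 1 - beta2^step
          par$W[[l]] <- par$W[[l]] -
            lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
          par$b[[l]] <- par$b[[l]] -
            lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
        }
      }
      val_loss <- ann_loss(par, X_val, Yvs, l2)
      history <- c(history, ann_loss(par, X, Ys, l2))
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, par = par, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= spec$early_stop_patience) break
      }
    }
    list(par = best$par, centers = centers, scales = scales,
         history = history, best_epoch = best$epoch,
         best_val_loss = best$loss)
  })
}

## ---- prediction ----------------------------------------------------------

#' Predict from a fitted model
#'
#' @param object a [fit_model()] result.
#' @param newdata feature table; must contain the training feature columns
#'   (matched by name, reordered as needed).
#' @param ... unused.
#' @return data.frame with one prediction column per target; classification
#'   adds `label` (+1/-1) and a real-valued `score` for ranking/AUROC.
#' @export
predict.fitted_model <- function(object, newdata, ...) {
  Xm <- as_feature_matrix(newdata, object$variables)
  spec_class <- class(object$spec)[1]
  if (spec_class == "svm_spec") {
    if (object$task == "classify") {
      pr <- stats::predict(object$fit, Xm, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      score <- drop(dv)
      # orient the decision values so larger = more likely +1
      if (startsWith(colnames(dv)[1], "-1")) score <- -score
      out <- data.frame(label = as.integer(as.character(pr)), score = score)
    } else if (!is.null(object$fit$constant)) {
      out <- data.frame(rep(object$fit$constant, nrow(Xm)))
      names(out) <- object$targets
    } else {
      out <- data.frame(stats::predict(object$fit, Xm))
      names(out) <- object$targets
    }
  } else if (spec_class == "rf_spec") {
    pr <- stats::predict(object$fit, data.frame(Xm, check.names = FALSE),
                         num.threads = 1)
    if (object$task == "classify") {
      p_pos <- pr$predictions[, "1"]
      out <- data.frame(label = ifelse(p_pos >= 0.5, 1L, -1L),
                        score = p_pos)
    } else {
      out <- data.frame(pr$predictions)
      names(out) <- object$targets
    }
  } else {
    if (!is.null(object$fit$constant)) {
      out <- as.data.frame(matrix(object$fit$constant, nrow(Xm),
                                  length(object$targets), byrow = TRUE))
    } else {
      Ys <- ann_forward(object$fit$par, Xm)[[length(object$fit$par$W) + 1L]]
      out <- as.data.frame(sweep(sweep(Ys, 2L, object$fit$scales, "*"),
                                 2L, object$fit$centers, "+"))
    }
    names(out) <- object$targets
  }
  rownames(out) <- NULL
  out
}

## ---- grid search ---------------------------------------------------------

#' Exhaustive grid search by k-fold cross-validation
#'
#' Evaluates every combination of the supplied parameter values by k-fold
#' cross-validated mean loss (MSE for regression, error rate for
#' classification) and returns the best specification. Ties break in favour
#' of the earliest grid point.
#'
#' @param spec_template a model spec whose fields are overridden by each
#'   grid point.
#' @param grid named list of parameter value vectors (nonempty).
#' @param X,y training data.
#' @param folds number of CV folds.
#' @param seed seed passed to each fit.
#' @return list with `best_spec`, `best_score`, and `scores` (the full
#'   grid-by-score table, in grid order).
#' @export
grid_search <- function(spec_template, grid, X, y, folds = 5, seed = 42L) {
  if (!length(grid) || any(!lengths(grid)))
    stop("grid must contain at least one value per parameter")
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  Xm <- as_feature_matrix(X)
  yv <- if (is.null(dim(y))) y else y[, 1]
  n <- nrow(Xm)
  fold_id <- cut(seq_len(n), breaks = folds, labels = FALSE)
  classify <- inherits(spec_template, "svm_spec") &&
    spec_template$task == "classify"
  scores <- numeric(nrow(combos))
  for (g in seq_len(nrow(combos))) {
    spec <- spec_template
    for (p in names(combos)) spec[[p]] <- combos[[p]][g]
    fold_loss <- vapply(seq_len(folds), function(k) {
      tr <- fold_id != k
      fit <- fit_model(spec, Xm[tr, , drop = FALSE], yv[tr], seed = seed)
      pred <- predict(fit, Xm[!tr, , drop = FALSE])
      if (classify) mean(pred$label != yv[!tr])
      else mean((pred[[1]] - yv[!tr])^2)
    }, numeric(1))
    scores[g] <- mean(fold_loss)
  }
  best <- which.min(scores)   # first minimum = earliest grid point
  best_spec <- spec_template
  for (p in names(combos)) best_spec[[p]] <- combos[[p]][best]
  combos$cv_loss <- scores
  list(best_spec = best_spec, best_score = scores[best], scores = combos)
}
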