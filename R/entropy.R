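# Entropy-based uncertainty and stability quantification.
#
# Three statistics: (i) error entropy, the differential Shannon entropy of a
# model's residual distribution estimated by Gaussian-kernel KDE with
# Silverman's bandwidth, integrated by trapezoidal quadrature; (ii) the
# permutation entropy increase of a feature, the rise in error entropy after
# breaking that feature's relation to the target; (iii) process entropy, the
# Shannon entropy of the empirical distribution over discrete operating
# states. All entropies are in nats.

#' KDE configuration for error entropy
#'
#' @param kernel only `"gaussian"`.
#' @param bandwidth_rule `"silverman"` (0.9 * min(sd, IQR/1.34) * n^(-1/5))
#'   or `"fixed"`.
#' @param fixed_bandwidth bandwidth when `bandwidth_rule = "fixed"`.
#' @param grid_points number of quadrature grid points (>= 64).
#' @param grid_pad grid extension beyond the data range, in bandwidths.
#' @return Object of class `kde_config`.
#' @export
kde_config <- function(kernel = "gaussian",
                       bandwidth_rule = c("silverman", "fixed"),
                       fixed_bandwidth = NULL,
                       grid_points = 2048L, grid_pad = 4) {
  kernel <- match.arg(kernel)
  bandwidth_rule <- match.arg(bandwidth_rule)
  if (grid_points < 64) stop("grid_points must be >= 64")
  if (bandwidth_rule == "fixed" &&
      (is.null(fixed_bandwidth) || fixed_bandwidth <= 0))
    stop("fixed_bandwidth must be > 0 when bandwidth_rule is 'fixed'")
  structure(list(kernel = kernel, bandwidth_rule = bandwidth_rule,
                 fixed_bandwidth = fixed_bandwidth,
                 grid_points = as.integer(grid_points), grid_pad = grid_pad),
            class = "kde_config")
}

silverman_bw <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  iqr <- stats::IQR(x) / 1.34
  spread <- if (iqr > 0) min(s, iqr) else s
  0.9 * spread * n^(-1 / 5)
}

#' Differential error entropy via kernel density estimation
#'
#' Estimates `H(e) = -Int p(e) ln p(e) de` for a sample of prediction errors
#' from a Gaussian-kernel KDE with Silverman bandwidth: the density is
#' evaluated on a uniform grid spanning the data range padded by `grid_pad`
#' bandwidths, renormalized to unit trapezoidal mass, and the entropy is the
#' resubstitution (plug-in) estimate `-mean(ln p(e_i))` over the sample.
#' The plug-in form is used because pure grid quadrature of `-p ln p`
#' carries a boundary-smoothing bias for compactly supported error
#' distributions that exceeds the estimator's nominal accuracy.
#' Natural logarithm (nats).
#'
#' @param errors numeric sample of errors, `n >= 10`, finite,
#'   non-degenerate.
#' @param config a [kde_config()].
#' @return Object of class `error_entropy`: list with `H` (nats),
#'   `bandwidth`, `n`, and `density_mass` (trapezoidal mass before
#'   renormalization, a truncation diagnostic).
#' @export
error_entropy <- function(errors, config = kde_config()) {
  if (length(errors) < 10) stop("need at least 10 errors")
  if (any(!is.finite(errors))) stop("errors must be finite")
  if (stats::sd(errors) == 0)
    stop("degenerate error distribution: differential entropy diverges")
  h <- if (config$bandwidth_rule == "silverman") silverman_bw(errors)
       else config$fixed_bandwidth
  lo <- min(errors) - config$grid_pad * h
  hi <- max(errors) + config$grid_pad * h
  den <- stats::density(errors, bw = h, kernel = "gaussian",
                        n = config$grid_points, from = lo, to = hi)
  dx <- den$x[2] - den$x[1]
  p <- den$y
  mass <- sum((p[-1] + p[-length(p)]) / 2) * dx
  p <- p / mass
  p_at <- stats::approx(den$x, p, xout = errors)$y
  H <- -mean(log(p_at))
  structure(list(H = H, bandwidth = h, n = length(errors),
                 density_mass = mass),
            class = "error_entropy")
}

#' @export
print.error_entropy <- function(x, ...) {
  cat(sprintf("<error_entropy> H = %.4f nats (n = %d, bw = %.4g, mass = %.4f)\n",
              x$H, x$n, x$bandwidth, x$density_mass))
  invisible(x)
}

#' Error entropy of a fitted model on held-out data
#'
#' Applies [error_entropy()] to the residuals `e = y - yhat` of a model on
#' test rows.
#'
#' @param model a [fit_model()] result (regression).
#' @param X_test,y_test held-out features and observed target values.
#' @param target which prediction column to use when the model is
#'   multi-target; defaults to the first.
#' @param config a [kde_config()].
#' @return An `error_entropy` object.
#' @export
model_error_entropy <- function(model, X_test, y_test,
                                target = model$targets[1],
                                config = kde_config()) {
  pred <- predict(model, X_test)
  if (!target %in% names(pred)) stop("unknown target: ", target)
  error_entropy(y_test - pred[[target]], config)
}

#' Permutation entropy increase of a feature
#'
#' `DeltaH_j` is the mean rise in error entropy after permuting feature `j`
#' in the test features (breaking its relation to the target), averaged over
#' `n_perm` seeded permutations. A larger value means the feature contributes
#' more to uncertainty reduction.
#'
#' @param model a fitted regression model.
#' @param X_test,y_test held-out data.
#' @param feature feature column to permute.
#' @param n_perm number of permutations (>= 1).
#' @param seed permutation seed.
#' @param target prediction column for multi-target models.
#' @param config a [kde_config()].
#' @return Object of class `feature_entropy`: list with `feature`,
#'   `delta_H`, `n_perm`, `per_permutation` (H(e^(j)) values) and
#'   `H_baseline`.
#' @export
entropy_increase <- function(model, X_test, y_test, feature, n_perm = 10,
                             seed = 42L, target = model$targets[1],
                             config = kde_config()) {
  if (!feature %in% names(X_test)) stop("unknown feature: ", feature)
  if (n_perm < 1) stop("n_perm must be >= 1")
  H0 <- model_error_entropy(model, X_test, y_test, target, config)$H
  Hs <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    Xp <- X_test
    Xp[[feature]] <- Xp[[feature]][sample.int(nrow(Xp))]
    model_error_entropy(model, Xp, y_test, target, config)$H
  }, numeric(1)))
  structure(list(feature = feature, delta_H = mean(Hs) - H0,
                 n_perm = n_perm, per_permutation = Hs, H_baseline = H0),
            class = "feature_entropy")
}

#' @export
print.feature_entropy <- function(x, ...) {
  cat(sprintf("<feature_entropy> %s: delta_H = %+.4f nats (%d permutations)\n",
              x$feature, x$delta_H, x$n_perm))
  invisible(x)
}

## ---- discrete operating states ------------------------------------------

AD_STATES <- c("normal", "vfa_accumulation", "overload", "temp_deviation")

#' Rules mapping records to discrete operating states
#'
#' Thresholds default to the plant engineering limits: VFA above 8 g/L is
#' acid accumulation; feed rate above 2.0 t/h or biogas yield below
#' 70 m3/t is overload; temperature outside 30-35 degC is thermal
#' deviation. Records violating several rules take the highest-priority
#' abnormal state.
#'
#' @param vfa_limit VFA threshold (g/L).
#' @param temp_band in-band temperature range (degC).
#' @param overload_feed_rate feed-rate threshold (t/h).
#' @param biogas_floor low-yield overload surrogate (m3/t); `NA` disables.
#' @param priority order in which the three abnormal states are checked.
#' @return Object of class `state_rules`.
#' @export
state_rules <- function(vfa_limit = 8, temp_band = c(30, 35),
                        overload_feed_rate = 2.0, biogas_floor = 70,
                        priority = c("vfa_accumulation", "overload",
                                     "temp_deviation")) {
  if (!setequal(priority, setdiff(AD_STATES, "normal")))
    stop("priority must order exactly the three abnormal states")
  stopifnot(is.finite(vfa_limit), length(temp_band) == 2,
            all(is.finite(temp_band)), temp_band[1] < temp_band[2],
            is.finite(overload_feed_rate))
  structure(list(vfa_limit = vfa_limit, temp_band = temp_band,
                 overload_feed_rate = overload_feed_rate,
                 biogas_floor = biogas_floor, priority = priority),
            class = "state_rules")
}

#' Classify records into operating states
#'
#' @param records data.frame with `vfa`, `temperature`, `feed_rate` and
#'   `biogas_yield` columns (vectorized over rows).
#' @param rules a [state_rules()] object.
#' @return Character vector of states, one per row.
#' @export
classify_state <- function(records, rules = state_rules()) {
  need <- c("vfa", "temperature", "feed_rate", "biogas_yield")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing required field(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(as.matrix(records[, need]))))
    stop("state classification requires finite values")
  viol <- list(
    vfa_accumulation = records$vfa > rules$vfa_limit,
    overload = records$feed_rate > rules$overload_feed_rate |
      (!is.na(rules$biogas_floor) &
         records$biogas_yield < rules$biogas_floor),
    temp_deviation = records$temperature < rules$temp_band[1] |
      records$temperature > rules$temp_band[2]
  )
  out <- rep("normal", nrow(records))
  for (st in rev(rules$priority)) out[viol[[st]]] <- st
  out
}

#' Empirical state distribution over observation windows
#'
#' @param states character vector of states (from [classify_state()]).
#' @param window number of consecutive observations per window; the default
#'   covers the whole sequence in one window.
#' @return data.frame with one row per window: `window`, `n`, and one
#'   probability column per state (class `state_distribution`).
#' @export
state_distribution <- function(states, window = length(states)) {
  if (!length(states)) stop("empty state sequence")
  wid <- (seq_along(states) - 1L) %/% window + 1L
  rows <- lapply(split(states, wid), function(s) {
    counts <- table(factor(s, levels = AD_STATES))
    c(n = length(s), counts / length(s))
  })
  out <- data.frame(window = as.integer(names(rows)),
                    do.call(rbind, rows), check.names = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("state_distribution", "data.frame"))
}

#' Process entropy of a state sequence
#'
#' `S_proc = -sum_k pi_k ln pi_k` over the empirical state probabilities,
#' with `0 ln 0 = 0`; bounded by `[0, ln K]`.
#'
#' @param states nonempty character vector of states, or a numeric
#'   probability vector (must sum to 1).
#' @param K number of possible states (for the entropy bound; default 4).
#' @return Process entropy in nats.
#' @export
process_entropy <- function(states, K = 4) {
  if (!length(states)) stop("empty state sequence")
  if (is.numeric(states)) {
    if (any(states < 0) || !isTRUE(all.equal(sum(states), 1)))
      stop("probability vector must be non-negative and sum to 1")
    pi_k <- states
  } else {
    pi_k <- as.numeric(table(states)) / length(states)
  }
  -sum(ifelse(pi_k > 0, pi_k * log(pi_k), 0))
}
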