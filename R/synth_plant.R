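# Synthetic plant-record generation.
#
# The generator emulates a full-scale anaerobic digester monitored at 5-min
# cadence: six measured inputs (feed solids, organic matter, feed rate, pH,
# dissolved O2, total solids) drawn from a Gaussian copula with
# truncated-normal marginals, and three responses (biogas yield, reactor
# temperature, VFA) produced by a calibrated nonlinear response kernel plus
# regime effects and Gaussian noise. Calibration is moment matching: response
# weights are solved so that the realized Pearson correlations hit the
# configured targets while marginal means/SDs stay at their configured values.

AD_INPUTS  <- c("feed_solids", "organic_matter", "feed_rate",
                "ph", "dissolved_o2", "total_solids")
AD_OUTPUTS <- c("biogas_yield", "temperature", "vfa")
AD_CORES   <- c("feed_solids", "organic_matter", "feed_rate")
AD_REGIMES <- c("steady", "load_fluctuation", "seasonal")

#' Names of the process variables
#'
#' @return Character vector of the nine monitored process variables, inputs
#'   first, in standard column order.
#' @export
plant_variables <- function() c(AD_INPUTS, AD_OUTPUTS)

## ---- truncated-normal helpers -------------------------------------------

# mean and sd of N(mean, sd) truncated to [lower, upper]
tn_moments <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  pa <- stats::dnorm(a); pb <- stats::dnorm(b)
  apa <- ifelse(is.finite(a), a * pa, 0)
  bpb <- ifelse(is.finite(b), b * pb, 0)
  m <- mean + sd * (pa - pb) / Z
  v <- sd^2 * (1 + (apa - bpb) / Z - ((pa - pb) / Z)^2)
  list(mean = m, sd = sqrt(pmax(v, 0)))
}

# quantile function of the truncated normal, u in (0, 1)
tn_quantile <- function(u, mean, sd, lower, upper) {
  Fa <- stats::pnorm(lower, mean, sd)
  Fb <- stats::pnorm(upper, mean, sd)
  stats::qnorm(Fa + u * (Fb - Fa), mean, sd)
}

## ---- seeding -------------------------------------------------------------

# run expr under a private RNG stream, restoring the caller's stream after
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## ---- configuration -------------------------------------------------------

default_marginals <- function() {
  data.frame(
    variable = c(AD_INPUTS, AD_OUTPUTS),
    mean  = c(26.5, 28.7, 1.2, 7.2, 0.25, 32.4, 79.5, 34.2, 6.3),
    sd    = c(4.2, 5.1, 0.3, 0.4, 0.10, 3.5, 6.1, 2.5, 1.5),
    lower = c(20, 15, 0.5, 6.5, 0.10, 25, -Inf, -Inf, 0),
    upper = c(35, 40, 2.0, 8.0, 0.50, 45, Inf, Inf, Inf),
    stringsAsFactors = FALSE
  )
}

default_corr_targets <- function() {
  data.frame(
    variable_a = c(rep("feed_solids", 3), "organic_matter", "feed_rate",
                   "organic_matter", "feed_rate", "organic_matter", "feed_rate",
                   "total_solids", "ph", "dissolved_o2"),
    variable_b = c("biogas_yield", "temperature", "vfa",
                   "biogas_yield", "biogas_yield",
                   "temperature", "temperature", "vfa", "vfa",
                   "feed_solids", "biogas_yield", "biogas_yield"),
    target_r   = c(0.90, 0.85, 0.60, 0.70, 0.45,
                   0.50, 0.30, 0.45, 0.30, 0.60, 0.10, -0.05),
    stringsAsFactors = FALSE
  )
}

# latent correlations among inputs not pinned by corr_targets; chosen so the
# implied auxiliary-variable correlations with biogas land near their weak
# defaults (pH ~ +0.1, dissolved O2 ~ -0.05)
default_input_corr <- function() {
  m <- diag(6)
  dimnames(m) <- list(AD_INPUTS, AD_INPUTS)
  set <- function(a, b, r) {
    m[a, b] <<- r; m[b, a] <<- r
  }
  set("feed_solids", "organic_matter", 0.55)
  set("feed_solids", "feed_rate", 0.25)
  set("organic_matter", "feed_rate", 0.20)
  set("feed_solids", "ph", 0.10)
  set("organic_matter", "ph", 0.08)
  set("feed_rate", "ph", 0.05)
  set("feed_solids", "dissolved_o2", -0.055)
  set("organic_matter", "dissolved_o2", -0.04)
  set("feed_solids", "total_solids", 0.60)
  # organic fraction trades off against inert solids at fixed feed solids,
  # keeping total solids an auxiliary (sub-0.40) correlate of biogas yield
  set("organic_matter", "total_solids", -0.25)
  set("feed_rate", "total_solids", -0.10)
  set("ph", "total_solids", 0.05)
  m
}

default_regime_effects <- function() {
  # additive mean shifts on the standardized-output scale, before centering
  # against the regime mix; load fluctuation raises VFA and depresses biogas
  list(
    biogas_yield = c(steady = 0, load_fluctuation = -0.15, seasonal = 0),
    temperature  = c(steady = 0, load_fluctuation = 0, seasonal = 0),
    vfa          = c(steady = 0, load_fluctuation = 0.85, seasonal = -0.10)
  )
}

#' Configure the synthetic plant-data generator
#'
#' Builds and calibrates a generator configuration. Marginals are
#' truncated-normal (mean/SD truncated at the engineering range); dependence
#' among inputs is a Gaussian copula; responses are a linear combination of
#' the standardized core inputs plus a solids-by-organic interaction (biogas
#' only), regime mean shifts, a seasonal temperature modulation and Gaussian
#' noise. Response weights, the latent input correlations and the residual
#' noise scale are calibrated at construction so realized correlations and
#' marginal moments match the configuration.
#'
#' @param marginals data.frame with columns `variable`, `mean`, `sd`,
#'   `lower`, `upper` for the nine process variables.
#' @param corr_targets data.frame with columns `variable_a`, `variable_b`,
#'   `target_r`. Pairs among inputs pin the copula; pairs of a core input
#'   (feed solids, organic matter, feed rate) with an output are solved
#'   exactly by the response calibration; pairs of an auxiliary input with an
#'   output are honoured only approximately, through the input correlation
#'   structure.
#' @param regime_mix named proportions over the regimes
#'   `steady`, `load_fluctuation`, `seasonal`; must sum to 1.
#' @param regime_effects per-output named vectors of regime mean shifts on
#'   the standardized output scale (centered against `regime_mix` at
#'   calibration so overall means are unaffected).
#' @param fault_rate fraction of records turned into sensor faults,
#'   in `[0, 0.1]`.
#' @param noise_sd optional named per-output override of the calibrated
#'   residual noise SD (standardized scale). Overriding it detunes the
#'   correlation targets; `NULL` (default) uses the calibrated value.
#' @param input_corr optional 6x6 latent correlation matrix overriding the
#'   built-in defaults for input pairs not listed in `corr_targets`.
#' @param interaction_weight weight of the solids-by-organic interaction in
#'   the biogas response (standardized scale).
#' @param overload_weight weight of the concave quadratic feed-rate term in
#'   the biogas response (standardized scale): yield falls off at both
#'   hydraulic extremes (washout / overload), peaking at moderate loading.
#' @param seasonal_amplitude amplitude (standardized temperature scale) of
#'   the slow sinusoidal modulation applied to seasonal-regime records.
#' @param seed default seed used by [generate_records()] when none is given.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(marginals = default_marginals(),
                             corr_targets = default_corr_targets(),
                             regime_mix = c(steady = 0.70,
                                            load_fluctuation = 0.15,
                                            seasonal = 0.15),
                             regime_effects = default_regime_effects(),
                             fault_rate = 0.023,
                             noise_sd = NULL,
                             input_corr = default_input_corr(),
                             interaction_weight = 0.10,
                             overload_weight = 0.15,
                             seasonal_amplitude = 0.8,
                             seed = 1L) {
  stopifnot(is.data.frame(marginals),
            all(c("variable", "mean", "sd", "lower", "upper") %in%
                  names(marginals)))
  if (!setequal(marginals$variable, plant_variables()))
    stop("marginals must cover exactly the nine process variables")
  if (any(marginals$sd <= 0)) stop("all marginal sds must be > 0")
  if (any(marginals$lower >= marginals$upper))
    stop("marginal lower bounds must be < upper bounds")
  if (!isTRUE(all.equal(sum(regime_mix), 1)) || any(regime_mix < 0))
    stop("regime_mix must be non-negative and sum to 1")
  if (!setequal(names(regime_mix), AD_REGIMES))
    stop("regime_mix must be named over the three regimes")
  if (fault_rate < 0 || fault_rate > 0.1)
    stop("fault_rate must be in [0, 0.1]")
  if (any(abs(corr_targets$target_r) >= 1))
    stop("correlation targets must lie in (-1, 1)")
  bad <- !(corr_targets$variable_a %in% plant_variables()) |
    !(corr_targets$variable_b %in% plant_variables())
  if (any(bad)) stop("unknown variable in corr_targets")

  rownames(marginals) <- marginals$variable
  marginals <- marginals[plant_variables(), ]

  cfg <- structure(
    list(marginals = marginals,
         corr_targets = corr_targets,
         regime_mix = regime_mix[AD_REGIMES],
         regime_effects = regime_effects,
         fault_rate = fault_rate,
         noise_sd_override = noise_sd,
         input_corr = input_corr,
         interaction_weight = interaction_weight,
         overload_weight = overload_weight,
         seasonal_amplitude = seasonal_amplitude,
         seed = seed),
    class = "generator_config"
  )
  cfg$calibration <- calibrate_generator(cfg)
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat("  variables :", length(plant_variables()), "(6 inputs, 3 outputs)\n")
  cat("  corr targets:", nrow(x$corr_targets), "pairs\n")
  cat("  regime mix:", paste(sprintf("%s=%.2f", names(x$regime_mix),
                                     x$regime_mix), collapse = ", "), "\n")
  cat("  fault rate:", x$fault_rate, "\n")
  ns <- x$calibration$noise_sd
  cat("  calibrated noise sd (std scale):",
      paste(sprintf("%s=%.3f", names(ns), ns), collapse = ", "), "\n")
  invisible(x)
}

# split corr targets into input-input and input-output pairs, orienting the
# latter as (input, output)
split_targets <- function(corr_targets) {
  a_in <- corr_targets$variable_a %in% AD_INPUTS
  b_in <- corr_targets$variable_b %in% AD_INPUTS
  ii <- corr_targets[a_in & b_in, , drop = FALSE]
  io <- corr_targets[xor(a_in, b_in), , drop = FALSE]
  if (nrow(io)) {
    flip <- io$variable_a %in% AD_OUTPUTS
    tmp <- io$variable_a[flip]
    io$variable_a[flip] <- io$variable_b[flip]
    io$variable_b[flip] <- tmp
  }
  oo <- corr_targets[!a_in & !b_in, , drop = FALSE]
  if (nrow(oo))
    stop("output-output correlation targets are not supported")
  list(input_input = ii, input_output = io)
}

# Moment-matching calibration. A fixed internal seed makes the Monte-Carlo
# moments deterministic, so identical configs always calibrate identically.
calibrate_generator <- function(cfg, m = 20000L) {
  tg <- split_targets(cfg$corr_targets)
  ic <- cfg$input_corr
  if (is.null(dimnames(ic))) dimnames(ic) <- list(AD_INPUTS, AD_INPUTS)
  Sigma <- ic[AD_INPUTS, AD_INPUTS]
  if (nrow(tg$input_input)) {
    for (i in seq_len(nrow(tg$input_input))) {
      a <- tg$input_input$variable_a[i]; b <- tg$input_input$variable_b[i]
      Sigma[a, b] <- Sigma[b, a] <- tg$input_input$target_r[i]
    }
  }

  marg <- cfg$marginals[AD_INPUTS, ]
  tmom <- tn_moments(marg$mean, marg$sd, marg$lower, marg$upper)

  draw_std_inputs <- function(S) {
    Z <- matrix(stats::rnorm(m * 6L), m, 6L) %*% chol(S)
    X <- matrix(NA_real_, m, 6L, dimnames = list(NULL, AD_INPUTS))
    for (j in seq_len(6L)) {
      X[, j] <- tn_quantile(stats::pnorm(Z[, j]), marg$mean[j], marg$sd[j],
                            marg$lower[j], marg$upper[j])
      X[, j] <- (X[, j] - tmom$mean[j]) / tmom$sd[j]
    }
    X
  }

  # two passes: measure realized input correlations, nudge the latent matrix
  # so pinned input-input targets are met after the marginal transform's
  # (mild) attenuation
  draws <- with_seed(104729L, {
    Xs <- NULL
    for (pass in 1:2) {
      if (min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) <
          1e-8)
        stop("correlation targets do not admit a positive-semidefinite ",
             "completion")
      Xs <- draw_std_inputs(Sigma)
      if (pass == 1L && nrow(tg$input_input)) {
        Rhat <- stats::cor(Xs)
        for (i in seq_len(nrow(tg$input_input))) {
          a <- tg$input_input$variable_a[i]
          b <- tg$input_input$variable_b[i]
          adj <- tg$input_input$target_r[i] +
            (tg$input_input$target_r[i] - Rhat[a, b])
          Sigma[a, b] <- Sigma[b, a] <- max(min(adj, 0.99), -0.99)
        }
      }
    }
    list(Xs = Xs, Sigma = Sigma)
  })
  Xs <- draws$Xs
  Sigma <- draws$Sigma
  Rhat <- stats::cor(Xs)

  # nonlinear-term moments (biogas response only): solids-by-organic
  # interaction and the concave quadratic overload term in feed rate
  w_int <- Xs[, "feed_solids"] * Xs[, "organic_matter"]
  m_int <- mean(w_int)
  v_int <- stats::var(w_int)
  cov_int <- vapply(AD_CORES, function(v) stats::cov(Xs[, v], w_int),
                    numeric(1))
  w_ovl <- -Xs[, "feed_rate"]^2
  m_ovl <- mean(w_ovl)
  v_ovl <- stats::var(w_ovl)
  cov_ovl <- vapply(AD_CORES, function(v) stats::cov(Xs[, v], w_ovl),
                    numeric(1))

  # centered regime effects and their variance contribution
  mix <- cfg$regime_mix
  reg_centered <- lapply(cfg$regime_effects, function(d) {
    d <- d[AD_REGIMES]
    d - sum(mix * d)
  })
  var_reg <- vapply(reg_centered, function(d) sum(mix * d^2), numeric(1))

  # seasonal sinusoid on temperature (seasonal-regime records only)
  var_seas <- c(biogas_yield = 0,
                temperature = mix[["seasonal"]] *
                  cfg$seasonal_amplitude^2 / 2,
                vfa = 0)

  Rcc <- Rhat[AD_CORES, AD_CORES]
  beta <- matrix(0, 3L, 3L, dimnames = list(AD_CORES, AD_OUTPUTS))
  noise_sd <- numeric(3L); names(noise_sd) <- AD_OUTPUTS
  for (out in AD_OUTPUTS) {
    rows <- tg$input_output$variable_b == out &
      tg$input_output$variable_a %in% AD_CORES
    r_star <- stats::setNames(rep(0, 3L), AD_CORES)
    if (any(rows)) {
      t_out <- tg$input_output[rows, ]
      r_star[t_out$variable_a] <- t_out$target_r
    }
    b_int <- if (out == "biogas_yield") cfg$interaction_weight else 0
    b_ovl <- if (out == "biogas_yield") cfg$overload_weight else 0
    b <- solve(Rcc, r_star - b_int * cov_int - b_ovl * cov_ovl)
    var_signal <- drop(t(b) %*% Rcc %*% b) +
      b_int^2 * v_int + 2 * b_int * sum(b * cov_int) +
      b_ovl^2 * v_ovl + 2 * b_ovl * sum(b * cov_ovl) +
      2 * b_int * b_ovl * stats::cov(w_int, w_ovl)
    resid <- 1 - var_signal - var_reg[[out]] - var_seas[[out]]
    if (resid < 0.01)
      stop("correlation targets for ", out, " leave no room for residual ",
           "noise; weaken the targets or the regime/seasonal effects")
    beta[, out] <- b
    noise_sd[out] <- sqrt(resid)
  }
  if (!is.null(cfg$noise_sd_override)) {
    ov <- cfg$noise_sd_override
    noise_sd[names(ov)] <- ov
  }

  list(Sigma = Sigma, chol = chol(Sigma),
       trunc_mean = stats::setNames(tmom$mean, AD_INPUTS),
       trunc_sd = stats::setNames(tmom$sd, AD_INPUTS),
       input_corr_hat = Rhat, beta = beta,
       interaction_weight = cfg$interaction_weight,
       interaction_mean = m_int,
       overload_weight = cfg$overload_weight,
       overload_mean = m_ovl,
       regime_effects_centered = reg_centered,
       noise_sd = noise_sd,
       aux_targets = tg$input_output[
         !(tg$input_output$variable_a %in% AD_CORES), , drop = FALSE])
}

## ---- response kernel -----------------------------------------------------

# standardized-scale noise-free response for the three outputs
response_u <- function(cal, xs_solids, xs_organic, xs_rate, regime) {
  X <- cbind(feed_solids = xs_solids, organic_matter = xs_organic,
             feed_rate = xs_rate)
  U <- X %*% cal$beta
  U[, "biogas_yield"] <- U[, "biogas_yield"] +
    cal$interaction_weight * (xs_solids * xs_organic - cal$interaction_mean) +
    cal$overload_weight * (-xs_rate^2 - cal$overload_mean)
  for (out in AD_OUTPUTS)
    U[, out] <- U[, out] + cal$regime_effects_centered[[out]][regime]
  U
}

#' Noise-free process response kernel
#'
#' Deterministic mapping from the three core inputs (and operating regime) to
#' the expected biogas yield, reactor temperature and VFA concentration. This
#' is the kernel [generate_records()] adds noise to; it is exposed so the
#' input-to-output map can be inspected and used as an oracle.
#'
#' @param config a [generator_config()].
#' @param feed_solids,organic_matter,feed_rate core inputs (vectors recycle);
#'   must lie within the configured marginal ranges.
#' @param regime operating regime, one of `"steady"`, `"load_fluctuation"`,
#'   `"seasonal"` (recycled).
#' @return data.frame with columns `biogas_yield`, `temperature`, `vfa`.
#' @export
true_response <- function(config, feed_solids, organic_matter, feed_rate,
                          regime = "steady") {
  stopifnot(inherits(config, "generator_config"))
  n <- max(length(feed_solids), length(organic_matter), length(feed_rate),
           length(regime))
  feed_solids <- rep_len(feed_solids, n)
  organic_matter <- rep_len(organic_matter, n)
  feed_rate <- rep_len(feed_rate, n)
  regime <- rep_len(regime, n)
  if (!all(regime %in% AD_REGIMES)) stop("unknown regime")
  marg <- config$marginals
  chk <- function(v, name) {
    if (any(v < marg[name, "lower"] - 1e-9 | v > marg[name, "upper"] + 1e-9))
      stop(name, " outside the configured operating range")
  }
  chk(feed_solids, "feed_solids")
  chk(organic_matter, "organic_matter")
  chk(feed_rate, "feed_rate")
  cal <- config$calibration
  std <- function(v, name) (v - cal$trunc_mean[[name]]) / cal$trunc_sd[[name]]
  U <- response_u(cal, std(feed_solids, "feed_solids"),
                  std(organic_matter, "organic_matter"),
                  std(feed_rate, "feed_rate"), regime)
  out <- as.data.frame(U)
  for (v in AD_OUTPUTS) out[[v]] <- marg[v, "mean"] + marg[v, "sd"] * out[[v]]
  out
}

## ---- record generation ---------------------------------------------------

#' Generate synthetic plant records
#'
#' Draws `n` records at 5-min cadence (fixed origin 2024-03-01 00:00 UTC)
#' from the calibrated generator: copula inputs, regime blocks of 4-12 h,
#' block-persistent input excursions in load-fluctuation regimes, outputs
#' from [true_response()] plus calibrated noise, a slow seasonal temperature
#' sinusoid, and sensor faults injected at the configured rate.
#'
#' @param config a [generator_config()].
#' @param n number of records (>= 1).
#' @param seed integer seed; defaults to the seed stored in `config`.
#' @return data.frame with `timestamp`, the nine process variables, `regime`
#'   and `fault_flag` columns.
#' @export
generate_records <- function(config, n, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive count")
  n <- as.integer(n)
  cal <- config$calibration
  marg <- config$marginals

  with_seed(seed, {
    # regime blocks: 2-8 h (24-96 records), regime drawn from the mix
    blocks <- integer(0); regimes_b <- character(0); total <- 0L
    while (total < n) {
      len <- sample(24:96, 1L)
      blocks <- c(blocks, len)
      regimes_b <- c(regimes_b,
                     sample(AD_REGIMES, 1L, prob = config$regime_mix))
      total <- total + len
    }
    block_id <- rep(seq_along(blocks), blocks)[seq_len(n)]
    regime <- regimes_b[block_id]

    # latent inputs; load-fluctuation blocks share a block-level component so
    # feed composition moves in step changes (marginals are unchanged). The
    # block component is centered over the load records so the clustering
    # cannot bias sample means.
    Zi <- matrix(stats::rnorm(n * 6L), n, 6L) %*% cal$chol
    Zb <- matrix(stats::rnorm(length(blocks) * 6L), length(blocks), 6L) %*%
      cal$chol
    w <- 0.5
    load <- regime == "load_fluctuation"
    Z <- Zi
    if (any(load)) {
      Bl <- Zb[block_id[load], , drop = FALSE]
      Bl <- sweep(Bl, 2L, colMeans(Bl))
      Z[load, ] <- sqrt(w) * Bl + sqrt(1 - w) * Zi[load, , drop = FALSE]
    }

    X <- matrix(NA_real_, n, 6L, dimnames = list(NULL, AD_INPUTS))
    Xs <- X
    for (j in seq_len(6L)) {
      v <- AD_INPUTS[j]
      X[, j] <- tn_quantile(stats::pnorm(Z[, j]), marg[v, "mean"],
                            marg[v, "sd"], marg[v, "lower"], marg[v, "upper"])
      Xs[, j] <- (X[, j] - cal$trunc_mean[[v]]) / cal$trunc_sd[[v]]
    }

    # responses: linear core weights + interaction + regime shifts. The
    # interaction and regime terms are centered against their realized
    # sample means (not just their expectations) so that finite-sample
    # lumpiness of the regime blocks cannot displace the output means.
    X_core <- Xs[, AD_CORES, drop = FALSE]
    U <- X_core %*% cal$beta
    w_int <- Xs[, "feed_solids"] * Xs[, "organic_matter"]
    w_ovl <- -Xs[, "feed_rate"]^2
    U[, "biogas_yield"] <- U[, "biogas_yield"] +
      cal$interaction_weight * (w_int - mean(w_int)) +
      cal$overload_weight * (w_ovl - mean(w_ovl))
    share <- vapply(AD_REGIMES, function(r) mean(regime == r), numeric(1))
    for (out in AD_OUTPUTS) {
      d <- config$regime_effects[[out]][AD_REGIMES]
      U[, out] <- U[, out] + (d - sum(share * d))[regime]
    }
    # slow seasonal temperature modulation, one cycle over the dataset span
    tfrac <- if (n > 1L) (seq_len(n) - 1L) / (n - 1L) else 0
    seas <- config$seasonal_amplitude * sin(2 * pi * tfrac)
    is_seas <- regime == "seasonal"
    if (any(is_seas)) {
      seas[is_seas] <- seas[is_seas] - mean(seas[is_seas])
      U[, "temperature"] <- U[, "temperature"] + seas * is_seas
    }
    for (out in AD_OUTPUTS)
      U[, out] <- U[, out] + stats::rnorm(n, 0, cal$noise_sd[[out]])

    tab <- data.frame(
      timestamp = as.POSIXct("2024-03-01 00:00:00", tz = "UTC") +
        300 * (seq_len(n) - 1L)
    )
    for (v in AD_INPUTS) tab[[v]] <- X[, v]
    for (v in AD_OUTPUTS)
      tab[[v]] <- marg[v, "mean"] + marg[v, "sd"] * U[, v]
    tab$vfa <- pmax(tab$vfa, 0)
    tab$regime <- regime
    tab$fault_flag <- FALSE

    if (config$fault_rate > 0)
      tab <- inject_faults(tab, config$fault_rate,
                           seed = if (is.null(seed)) NULL else seed + 1L)
    tab
  })
}

#' Inject sensor-fault outliers
#'
#' Alters `round(n * fault_rate)` records so each violates exactly one of the
#' cleaning limits (temperature > 80 degC, feed solids > 40%, organic matter
#' > 50%, or negative biogas yield), drawn uniformly, and sets `fault_flag`.
#'
#' @param table a record table as from [generate_records()].
#' @param fault_rate fraction of records to corrupt, in `[0, 0.1]`.
#' @param seed integer seed.
#' @return The table with faults applied.
#' @export
inject_faults <- function(table, fault_rate, seed = NULL) {
  if (fault_rate < 0 || fault_rate > 0.1)
    stop("fault_rate must be in [0, 0.1]")
  n <- nrow(table)
  k <- round(n * fault_rate)
  if (k == 0) return(table)
  with_seed(seed, {
    idx <- sample.int(n, k)
    type <- sample(c("temperature", "feed_solids", "organic_matter",
                     "biogas_yield"), k, replace = TRUE)
    for (i in seq_len(k)) {
      r <- idx[i]
      table[r, type[i]] <- switch(
        type[i],
        temperature = stats::runif(1, 85, 110),
        feed_solids = stats::runif(1, 41, 48),
        organic_matter = stats::runif(1, 51, 58),
        biogas_yield = -stats::runif(1, 0.5, 5)
      )
      table$fault_flag[r] <- TRUE
    }
    table
  })
}

## ---- CSV interface -------------------------------------------------------

#' Write / read plant records as CSV
#'
#' One header row, ISO-8601 UTC timestamps, columns in standard order plus
#' `regime` and `fault_flag`.
#'
#' @param table a record table.
#' @param path file path.
#' @return `write_records` returns `path` invisibly; `read_records` returns
#'   the record table.
#' @export
write_records <- function(table, path) {
  out <- table
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("timestamp" %in% names(tab))
    tab$timestamp <- as.POSIXct(tab$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                                tz = "UTC")
  if ("fault_flag" %in% names(tab))
    tab$fault_flag <- as.logical(tab$fault_flag)
  tab
}
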