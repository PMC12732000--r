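# Error entropy against closed forms, permutation entropy increase, and
# process entropy over discrete states.

test_that("KDE error entropy matches Gaussian and uniform closed forms", {
  set.seed(21)
  gauss <- rnorm(10000)
  unif <- runif(10000)
  H_gauss <- error_entropy(gauss)
  expect_lt(abs(H_gauss$H - 0.5 * log(2 * pi * exp(1))), 0.05)
  expect_lt(abs(error_entropy(unif)$H - 0), 0.05)
  expect_equal(H_gauss$n, 10000)
  expect_gt(H_gauss$density_mass, 0.99)
  expect_lt(H_gauss$density_mass, 1.01)
})

test_that("error entropy obeys the scaling and location laws", {
  set.seed(22)
  e <- rnorm(5000)
  expect_equal(error_entropy(2 * e)$H, error_entropy(e)$H + log(2),
               tolerance = 1e-9)
  expect_equal(error_entropy(e + 7)$H, error_entropy(e)$H,
               tolerance = 1e-6)
})

test_that("entropy estimates tighten from n = 500 to n = 10000", {
  closed <- 0.5 * log(2 * pi * exp(1))
  errs <- sapply(1:10, function(s) {
    set.seed(400 + s)
    c(small = abs(error_entropy(rnorm(500))$H - closed),
      large = abs(error_entropy(rnorm(10000))$H - closed),
      small_u = abs(error_entropy(runif(500))$H),
      large_u = abs(error_entropy(runif(10000))$H))
  })
  expect_lt(median(errs["large", ]), median(errs["small", ]))
  expect_lt(median(errs["large_u", ]), median(errs["small_u", ]))
})

test_that("degenerate and undersized samples are refused", {
  expect_error(error_entropy(rep(1, 100)), "degenerate")
  expect_error(error_entropy(rnorm(5)), "at least 10")
  expect_error(error_entropy(c(rnorm(20), Inf)), "finite")
  expect_error(kde_config(bandwidth_rule = "fixed"), "fixed_bandwidth")
})

test_that("model error entropy is deterministic and tracks model noise", {
  d <- fx_prep()
  m <- fx_models()
  H1 <- model_error_entropy(m$rf, d$test[, AD_IN], d$test$biogas_yield)
  H2 <- model_error_entropy(m$rf, d$test[, AD_IN], d$test$biogas_yield)
  expect_identical(H1$H, H2$H)

  # same model, noisier targets -> higher entropy (scaling law in practice)
  set.seed(23)
  y_noisy <- d$test$biogas_yield + rnorm(nrow(d$test), 0, 0.2)
  H_noisy <- model_error_entropy(m$rf, d$test[, AD_IN], y_noisy)
  expect_gt(H_noisy$H, H1$H)
})

test_that("permuting core features raises entropy; a noise feature does not", {
  noisy <- fx_rf_noise()
  dh <- lapply(c("feed_solids", "organic_matter", "feed_rate",
                 "noise_feature"), function(v)
    entropy_increase(noisy$model, noisy$X_test, noisy$y_test, v,
                     n_perm = 5, seed = 17))
  names(dh) <- c("feed_solids", "organic_matter", "feed_rate",
                 "noise_feature")
  for (v in c("feed_solids", "organic_matter", "feed_rate"))
    expect_gt(dh[[v]]$delta_H, 0.05)
  expect_lt(abs(dh$noise_feature$delta_H), 0.05)
  # bookkeeping identity: delta_H is the mean permuted H minus baseline
  x <- dh$feed_solids
  expect_equal(x$delta_H, mean(x$per_permutation) - x$H_baseline,
               tolerance = 1e-12)
  # seeded determinism
  again <- entropy_increase(noisy$model, noisy$X_test, noisy$y_test,
                            "feed_solids", n_perm = 5, seed = 17)
  expect_identical(again$delta_H, x$delta_H)
})

test_that("state classification follows thresholds and priority order", {
  rec <- data.frame(vfa = c(6.1, 9.0, 9.0, 5.0, 5.0),
                    temperature = c(33, 33, 40, 40, 33),
                    feed_rate = c(1.2, 1.2, 1.2, 1.2, 2.5),
                    biogas_yield = c(81.3, 80, 80, 80, 80))
  expect_equal(classify_state(rec),
               c("normal", "vfa_accumulation", "vfa_accumulation",
                 "temp_deviation", "overload"))
  low_yield <- data.frame(vfa = 5, temperature = 33, feed_rate = 1.2,
                          biogas_yield = 65)
  expect_equal(classify_state(low_yield), "overload")
  expect_error(classify_state(rec[, -1]), "missing required")
})

test_that("process entropy is bounded, exact on known distributions, and majorization-monotone", {
  expect_equal(process_entropy(rep("normal", 50)), 0)
  expect_equal(process_entropy(rep(c("a", "b", "c", "d"), 25)), log(4),
               tolerance = 1e-12)
  expect_equal(process_entropy(c(0.7, 0.1, 0.1, 0.1)),
               -(0.7 * log(0.7) + 3 * 0.1 * log(0.1)), tolerance = 1e-12)
  expect_equal(round(process_entropy(c(0.7, 0.1, 0.1, 0.1)), 4), 0.9404)

  set.seed(24)
  for (i in 1:20) {
    p <- as.numeric(rmultinom(1, 100, runif(4))) / 100
    expect_gte(process_entropy(p) + 1e-12, 0)
    expect_lte(process_entropy(p), log(4) + 1e-12)
    # move mass from the smallest positive class to the mode
    donor <- which(p == min(p[p > 0]))[1]
    mode_k <- which.max(p)
    if (donor != mode_k) {
      q <- p
      shift <- q[donor] / 2
      q[donor] <- q[donor] - shift
      q[mode_k] <- q[mode_k] + shift
      expect_lte(process_entropy(q), process_entropy(p) + 1e-12)
    }
  }
  expect_error(process_entropy(character(0)), "empty")
  expect_error(process_entropy(c(0.5, 0.4)), "sum to 1")
})

test_that("per-window state distributions are consistent with their counts", {
  states <- rep(c("normal", "normal", "overload", "vfa_accumulation"), 12)
  sd_tab <- state_distribution(states, window = 24)
  expect_equal(nrow(sd_tab), 2)
  probs <- as.matrix(sd_tab[, c("normal", "vfa_accumulation", "overload",
                                "temp_deviation")])
  expect_equal(unname(rowSums(probs)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(probs[1, "normal"]), 0.5)
})
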