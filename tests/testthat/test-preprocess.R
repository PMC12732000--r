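# Cleaning, scaling, splitting, K-S similarity and feature selection.

test_that("outlier removal drops exactly the limit-violating records", {
  tab <- data.frame(temperature = c(34, 85, 33), feed_solids = c(26, 27, 45),
                    organic_matter = 30, biogas_yield = c(80, 81, 79))
  res <- remove_outliers(tab)
  expect_equal(res$removed, 2L)
  expect_equal(res$table$temperature, 34)
  empty <- remove_outliers(tab[0, ])
  expect_equal(empty$removed, 0L)
  expect_equal(nrow(empty$table), 0L)
})

test_that("cleaning is idempotent and matches the fault flags", {
  d <- fx_prep()
  rec <- fx_records()
  expect_equal(d$removed, sum(rec$fault_flag))
  expect_setequal(which(rec$fault_flag),
                  setdiff(seq_len(nrow(rec)),
                          as.integer(rownames(d$clean))))
  again <- remove_outliers(d$clean)
  expect_equal(again$removed, 0L)
  expect_equal(again$table, d$clean)
})

test_that("min-max scaling reproduces training extremes and inverts exactly", {
  tab <- data.frame(feed_solids = c(20, 26.5, 35))
  np <- minmax_fit(tab, "feed_solids")
  expect_equal(np$x_min[["feed_solids"]], 20)
  expect_equal(np$x_max[["feed_solids"]], 35)
  scaled <- minmax_apply(tab, np)
  expect_equal(scaled$feed_solids, c(0, (26.5 - 20) / 15, 1))
  expect_equal(scaled$feed_solids[2], 0.43333333, tolerance = 1e-7)
  back <- minmax_invert(scaled, np)
  expect_equal(back$feed_solids, tab$feed_solids, tolerance = 1e-12)

  d <- fx_prep()
  for (v in AD_IN) {
    expect_gte(min(d$train[[v]]), 0)
    expect_lte(max(d$train[[v]]), 1)
    expect_equal(min(d$train[[v]]), 0)
    expect_equal(max(d$train[[v]]), 1)
  }
  expect_error(minmax_fit(data.frame(x = rep(1, 5)), "x"), "degenerate")
  expect_error(minmax_apply(data.frame(y = 1), np), "unknown variable")
})

test_that("normalization parameters are fitted on training data only", {
  d <- fx_prep()
  np_before <- d$np
  invisible(minmax_apply(d$splits$validation, d$np))
  invisible(minmax_apply(d$splits$test, d$np))
  expect_identical(d$np, np_before)
  for (v in AD_IN) {
    expect_equal(d$np$x_min[[v]], min(d$splits$train[[v]]))
    expect_equal(d$np$x_max[[v]], max(d$splits$train[[v]]))
  }
})

test_that("7:2:1 split has floor sizes, preserves order, and is seeded", {
  tab <- data.frame(timestamp = 1:100, x = rnorm(100))
  sp <- split_records(tab)
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 70L, validation = 20L, test = 10L))
  expect_lt(max(sp$train$timestamp), min(sp$validation$timestamp))
  expect_lt(max(sp$validation$timestamp), min(sp$test$timestamp))
  expect_equal(sort(c(sp$train$timestamp, sp$validation$timestamp,
                      sp$test$timestamp)), 1:100)

  r1 <- split_records(tab, mode = "random", seed = 3)
  r2 <- split_records(tab, mode = "random", seed = 3)
  expect_identical(r1, r2)
  expect_error(split_records(tab[1:9, ]), "at least 10")

  for (n in c(10, 37, 101, 2503)) {
    sp_n <- split_records(data.frame(x = seq_len(n)))
    sizes <- vapply(sp_n, nrow, integer(1))
    # train/validation take floors; the test block absorbs both fractional
    # remainders, so it can sit up to two rows above its 10% target
    expect_true(all(abs(sizes[1:2] - c(0.7, 0.2) * n) <= 1))
    expect_lte(abs(sizes[3] - 0.1 * n), 2)
    expect_equal(sum(sizes), n)
  }
})

test_that("K-S similarity detects equal and shifted distributions", {
  x <- rnorm(100)
  same <- ks_similarity(x, x)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  set.seed(5)
  far <- ks_similarity(rnorm(500), rnorm(500, 5))
  expect_lt(far$p, 0.001)
  expect_error(ks_similarity(1:3, 1:10), "at least 5")
})

test_that("random 7:2:1 splits of a well-mixed table pass the K-S check", {
  rec <- fx_records()
  rec <- remove_outliers(rec)$table
  pass <- vapply(1:5, function(s) {
    sp <- split_records(rec, mode = "random", seed = s)
    ks_check_split(sp, c("feed_solids", "biogas_yield", "vfa"))$pass
  }, logical(1))
  expect_gte(sum(pass), 4)
})

test_that("Pearson matrix recovers exact and configured correlations", {
  x <- rnorm(50)
  m <- pearson_matrix(data.frame(feed_solids = x, biogas_yield = 2 * x + 3),
                      c("feed_solids", "biogas_yield"))
  expect_equal(m["feed_solids", "feed_solids"], 1)
  expect_equal(m["feed_solids", "biogas_yield"], 1, tolerance = 1e-12)

  d <- fx_prep()
  pm <- pearson_matrix(d$splits$train)
  expect_lt(abs(pm["feed_solids", "biogas_yield"] - 0.90), 0.03)
  expect_lt(abs(pm["feed_solids", "temperature"] - 0.85), 0.03)
  expect_lt(abs(pm["feed_solids", "vfa"] - 0.60), 0.03)
  expect_equal(pm, t(pm))
  expect_error(pearson_matrix(data.frame(a = rnorm(10), b = rep(1, 10)),
                              c("a", "b")), "constant")
})

test_that("feature selection retains the three core drivers", {
  d <- fx_prep()
  pm <- pearson_matrix(d$splits$train, c(AD_IN, "biogas_yield"))
  sel <- select_features(pm, "biogas_yield")
  expect_setequal(sel$core, c("feed_solids", "organic_matter", "feed_rate"))
  expect_setequal(sel$auxiliary, c("ph", "dissolved_o2", "total_solids"))
  all_in <- select_features(pm, "biogas_yield", core_threshold = 0)
  expect_length(all_in$auxiliary, 0)
  none <- select_features(pm, "biogas_yield", core_threshold = 1.01)
  expect_length(none$core, 0)
  expect_error(select_features(pm, "nope"), "target")
})
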