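# Shared fixtures, built lazily and cached for the whole run. Sizes are
# scaled down from the plant-scale defaults to keep the suite fast; the
# statistical checks that depend on sample size state their own n.

AD_IN <- c("feed_solids", "organic_matter", "feed_rate",
           "ph", "dissolved_o2", "total_solids")
AD_OUT <- c("biogas_yield", "temperature", "vfa")

.fx <- new.env(parent = emptyenv())

fx_cached <- function(key, build) {
  if (is.null(.fx[[key]])) .fx[[key]] <- build()
  .fx[[key]]
}

fx_config <- function() fx_cached("config", function() generator_config())

fx_config_nofault <- function() {
  fx_cached("config0", function() generator_config(fault_rate = 0))
}

# mid-size dataset shared across modules
fx_records <- function() {
  fx_cached("records", function()
    generate_records(fx_config(), 4000, seed = 7))
}

# cleaned, chronologically split and min-max scaled version of fx_records
fx_prep <- function() {
  fx_cached("prep", function() {
    cln <- remove_outliers(fx_records())
    sp <- split_records(cln$table)
    np <- minmax_fit(sp$train, c(AD_IN, AD_OUT))
    list(clean = cln$table, removed = cln$removed, splits = sp, np = np,
         train = minmax_apply(sp$train, np),
         validation = minmax_apply(sp$validation, np),
         test = minmax_apply(sp$test, np))
  })
}

# compact ANN settings for tests (scaled-down from the [128, 64] default)
fx_ann_spec <- function(max_epochs = 80, ...) {
  ann_spec(hidden_sizes = c(64, 32), max_epochs = max_epochs, ...)
}

fx_models <- function() {
  fx_cached("models", function() {
    d <- fx_prep()
    list(
      svm = fit_model(svm_spec("regress"), d$train[, AD_IN],
                      d$train$biogas_yield, norm_params = d$np),
      rf = fit_model(rf_spec(), d$train[, AD_IN], d$train$biogas_yield,
                     norm_params = d$np, seed = 7L),
      ann = fit_model(fx_ann_spec(), d$train[, AD_IN], d$train[, AD_OUT],
                      X_val = d$validation[, AD_IN],
                      y_val = d$validation[, AD_OUT],
                      norm_params = d$np, seed = 7L)
    )
  })
}

# RF trained with a planted pure-noise feature appended
fx_rf_noise <- function() {
  fx_cached("rf_noise", function() {
    d <- fx_prep()
    Xtr <- d$train[, AD_IN]
    Xte <- d$test[, AD_IN]
    set.seed(31)
    Xtr$noise_feature <- runif(nrow(Xtr))
    Xte$noise_feature <- runif(nrow(Xte))
    list(model = fit_model(rf_spec(), Xtr, d$train$biogas_yield, seed = 3L),
         X_test = Xte, y_test = d$test$biogas_yield)
  })
}
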