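# End-to-end pipeline runner: generate -> preprocess -> train -> evaluate ->
# entropy -> operate -> tea, with per-stage CSV artifacts, JSON manifests
# (seed, input hashes) and resumable stages. A single global seed fans out
# to per-stage seeds by fixed offsets so stages are independently
# rerunnable.

PIPELINE_STAGES <- c("generate", "preprocess", "train", "evaluate",
                     "entropy", "operate", "tea")

#' Default run configuration
#'
#' @return Nested list of per-stage settings; amend and pass to
#'   [run_pipeline()], or serialize to YAML for the file interface.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    generator = list(n_records = 10000L, fault_rate = 0.023),
    preprocess = list(split_mode = "chronological"),
    models = list(
      svm = list(C = 10, gamma = 0.05, epsilon = 0.1),
      rf = list(n_trees = 100L, max_depth = 18L, mtry = 2L),
      ann = list(hidden_sizes = c(128L, 64L), learning_rate = 0.001,
                 batch_size = 64L, l2_lambda = 0.001, max_epochs = 500L,
                 early_stop_patience = 20L)
    ),
    entropy = list(n_perm = 10L),
    operation = list(weeks = 12L, gain = 1.0, lead_hours = 1),
    tea = list(capex = 1.5e6, operating_saving = 13.5, capacity = 100,
               energy_intensity = 100)
  )
}

#' Read a run configuration from YAML
#'
#' Unknown keys (at any level present in the defaults) are rejected.
#'
#' @param path YAML file.
#' @return merged configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_run_config(), user, "config")
}

merge_config <- function(defaults, user, where) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown key(s) in ", where, ": ", paste(unknown, collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      merge_config(defaults[[k]], user[[k]], paste(where, k, sep = "$"))
    else user[[k]]
  }
  defaults
}

write_manifest <- function(outdir, stage, seed, files, extra = list()) {
  paths <- file.path(outdir, files)
  manifest <- c(list(stage = stage, seed = seed,
                     created = format(Sys.time(), tz = "UTC"),
                     files = as.list(stats::setNames(
                       unname(tools::md5sum(paths)), files))),
                extra)
  jsonlite::write_json(manifest,
                       file.path(outdir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

require_artifact <- function(outdir, file, stage_needed) {
  p <- file.path(outdir, file)
  if (!file.exists(p))
    stop("missing artifact '", file, "': run stage '", stage_needed,
         "' first")
  p
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order, writing CSV artifacts
#' and a JSON manifest per stage under `outdir`. Rerunning with an identical
#' configuration reproduces identical artifacts for deterministic stages.
#'
#' @param config configuration list as from [default_run_config()] or
#'   [read_run_config()].
#' @param stages subset of
#'   `c("generate","preprocess","train","evaluate","entropy","operate","tea")`.
#' @param outdir output directory (created if needed).
#' @param seed global seed overriding `config$seed`; fanned out to stages by
#'   fixed offsets.
#' @return `outdir`, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = PIPELINE_STAGES,
                         outdir = "ad_run", seed = NULL) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  seed <- as.integer(if (is.null(seed)) config$seed else seed)
  invars <- AD_INPUTS
  outvars <- AD_OUTPUTS

  for (stage in stages) {
    t0 <- Sys.time()
    switch(stage,
      generate = {
        cfg <- generator_config(fault_rate = config$generator$fault_rate)
        rec <- generate_records(cfg, config$generator$n_records,
                                seed = seed + 101L)
        write_records(rec, file.path(outdir, "records.csv"))
        write_manifest(outdir, "generate", seed + 101L, "records.csv",
                       list(n = config$generator$n_records))
      },
      preprocess = {
        rec <- read_records(require_artifact(outdir, "records.csv",
                                             "generate"))
        cln <- remove_outliers(rec)
        sp <- split_records(cln$table, mode = config$preprocess$split_mode,
                            seed = seed + 202L)
        np <- minmax_fit(sp$train, c(invars, outvars))
        for (part in names(sp))
          write_records(minmax_apply(sp[[part]], np),
                        file.path(outdir, paste0(part, "_scaled.csv")))
        jsonlite::write_json(
          list(variables = np$variables, x_min = as.list(np$x_min),
               x_max = as.list(np$x_max), removed = cln$removed),
          file.path(outdir, "normalization.json"), auto_unbox = TRUE,
          digits = NA)
        write_manifest(outdir, "preprocess", seed + 202L,
                       c("train_scaled.csv", "validation_scaled.csv",
                         "test_scaled.csv", "normalization.json"),
                       list(removed = cln$removed))
      },
      train = {
        d <- read_pipeline_splits(outdir)
        mc <- config$models
        models <- list()
        models$svm_classify <- fit_model(
          svm_spec("classify", C = mc$svm$C, gamma = mc$svm$gamma),
          d$train[, invars], label_high_yield_scaled(d$train, d$np),
          norm_params = d$np, seed = seed + 303L)
        for (tg in outvars) {
          models[[paste0("svm_", tg)]] <- fit_model(
            svm_spec("regress", C = mc$svm$C, gamma = mc$svm$gamma,
                     epsilon = mc$svm$epsilon),
            d$train[, invars], stats::setNames(d$train[tg], tg),
            norm_params = d$np, seed = seed + 303L)
          models[[paste0("rf_", tg)]] <- fit_model(
            rf_spec(mc$rf$n_trees, mc$rf$max_depth, mc$rf$mtry),
            d$train[, invars], stats::setNames(d$train[tg], tg),
            norm_params = d$np, seed = seed + 303L)
        }
        models$rf_classify <- fit_model(
          rf_spec(mc$rf$n_trees, mc$rf$max_depth, mc$rf$mtry),
          d$train[, invars], label_high_yield_scaled(d$train, d$np),
          norm_params = d$np, seed = seed + 303L)
        models$ann <- fit_model(
          ann_spec(mc$ann$hidden_sizes, mc$ann$learning_rate,
                   mc$ann$batch_size, mc$ann$l2_lambda, mc$ann$max_epochs,
                   mc$ann$early_stop_patience),
          d$train[, invars], d$train[, outvars],
          X_val = d$validation[, invars], y_val = d$validation[, outvars],
          norm_params = d$np, seed = seed + 303L)
        saveRDS(models, file.path(outdir, "models.rds"))
        write_manifest(outdir, "train", seed + 303L, "models.rds")
      },
      evaluate = {
        d <- read_pipeline_splits(outdir)
        models <- readRDS(require_artifact(outdir, "models.rds", "train"))
        res <- list()
        lab_te <- label_high_yield_scaled(d$test, d$np)
        for (m in c("svm_classify", "rf_classify")) {
          pr <- predict(models[[m]], d$test[, invars])
          res[[paste0(m, ".biogas_yield")]] <-
            classification_metrics(lab_te, pr$label, pr$score)
        }
        for (tg in outvars) {
          rng <- d$np$x_max[[tg]] - d$np$x_min[[tg]]
          for (m in c("svm", "rf")) {
            pr <- predict(models[[paste0(m, "_", tg)]], d$test[, invars])
            res[[paste0(m, ".", tg)]] <-
              regression_metrics(d$test[[tg]] * rng, pr[[1]] * rng)
          }
          pr <- predict(models$ann, d$test[, invars])
          res[[paste0("ann.", tg)]] <-
            regression_metrics(d$test[[tg]] * rng, pr[[tg]] * rng)
        }
        utils::write.csv(metrics_table(res),
                         file.path(outdir, "metrics.csv"),
                         row.names = FALSE)
        imp <- rf_importance(models$rf_biogas_yield)
        utils::write.csv(
          data.frame(feature = names(imp), share = as.numeric(imp)),
          file.path(outdir, "rf_importance.csv"), row.names = FALSE)
        write_manifest(outdir, "evaluate", seed + 404L,
                       c("metrics.csv", "rf_importance.csv"))
      },
      entropy = {
        d <- read_pipeline_splits(outdir)
        models <- readRDS(require_artifact(outdir, "models.rds", "train"))
        ent <- data.frame()
        for (m in c("svm", "rf")) {
          for (tg in outvars) {
            h <- model_error_entropy(models[[paste0(m, "_", tg)]],
                                     d$test[, invars], d$test[[tg]])
            ent <- rbind(ent, data.frame(model = m, target = tg, H = h$H,
                                         bandwidth = h$bandwidth, n = h$n))
          }
        }
        for (tg in outvars) {
          h <- model_error_entropy(models$ann, d$test[, invars],
                                   d$test[[tg]], target = tg)
          ent <- rbind(ent, data.frame(model = "ann", target = tg, H = h$H,
                                       bandwidth = h$bandwidth, n = h$n))
        }
        utils::write.csv(ent, file.path(outdir, "error_entropy.csv"),
                         row.names = FALSE)
        feat <- data.frame()
        for (v in invars) {
          dh <- entropy_increase(models$ann, d$test[, invars],
                                 d$test$biogas_yield, v,
                                 n_perm = config$entropy$n_perm,
                                 seed = seed + 505L,
                                 target = "biogas_yield")
          dr <- permutation_delta_rmse(models$ann, d$test[, invars],
                                       d$test$biogas_yield, v,
                                       n_perm = config$entropy$n_perm,
                                       seed = seed + 505L,
                                       target = "biogas_yield")
          feat <- rbind(feat, data.frame(feature = v, delta_H = dh$delta_H,
                                         delta_rmse = dr$delta_rmse))
        }
        imp_file <- file.path(outdir, "rf_importance.csv")
        if (file.exists(imp_file)) {
          imp <- utils::read.csv(imp_file)
          feat$rf_share <- imp$share[match(feat$feature, imp$feature)]
        }
        utils::write.csv(feat, file.path(outdir, "feature_entropy.csv"),
                         row.names = FALSE)
        write_manifest(outdir, "entropy", seed + 505L,
                       c("error_entropy.csv", "feature_entropy.csv"))
      },
      operate = {
        models <- readRDS(require_artifact(outdir, "models.rds", "train"))
        cfg <- generator_config(fault_rate = config$generator$fault_rate)
        base <- simulate_operation(cfg, NULL, config$operation$weeks,
                                   seed = seed + 606L)
        pol <- advisory_policy(models$ann, gain = config$operation$gain,
                               lead_hours = config$operation$lead_hours)
        asst <- simulate_operation(cfg, pol, config$operation$weeks,
                                   seed = seed + 606L)
        tt <- compare_daily_indices(base$daily_cv, asst$daily_cv)
        utils::write.csv(
          data.frame(hour = base$hourly$hour,
                     baseline = base$hourly$biogas_yield,
                     assisted = asst$hourly$biogas_yield),
          file.path(outdir, "operation_hourly.csv"), row.names = FALSE)
        summary <- data.frame(
          cv_baseline = base$cv, cv_assisted = asst$cv,
          improvement = stability_improvement(base$cv, asst$cv),
          t = tt$t, p = tt$p,
          s_proc_baseline = base$s_proc, s_proc_assisted = asst$s_proc)
        utils::write.csv(summary, file.path(outdir, "operation_summary.csv"),
                         row.names = FALSE)
        write_manifest(outdir, "operate", seed + 606L,
                       c("operation_hourly.csv", "operation_summary.csv"))
      },
      tea = {
        tc <- config$tea
        es <- econ_scenario(capex = tc$capex,
                            operating_saving = tc$operating_saving,
                            capacity = tc$capacity)
        sweep <- payback_sensitivity(es, energy_intensity =
                                       tc$energy_intensity)
        utils::write.csv(sweep, file.path(outdir, "tea_payback.csv"),
                         row.names = FALSE)
        throughput <- tc$capacity * 330
        rows <- lapply(emission_presets(tc$energy_intensity), function(sc) {
          cr <- carbon_reduction(sc, throughput)
          data.frame(region = sc$region, grid_factor = sc$grid_factor,
                     energy_savings_rate = sc$energy_savings_rate,
                     energy_saved_kwh = cr$energy_saved,
                     co2_avoided_kg = cr$co2_avoided)
        })
        utils::write.csv(do.call(rbind, rows),
                         file.path(outdir, "lca_carbon.csv"),
                         row.names = FALSE)
        write_manifest(outdir, "tea", seed + 707L,
                       c("tea_payback.csv", "lca_carbon.csv"))
      }
    )
    message(sprintf("[%s] done in %.1fs", stage,
                    as.numeric(Sys.time() - t0, units = "secs")))
  }
  invisible(outdir)
}

read_pipeline_splits <- function(outdir) {
  np_file <- require_artifact(outdir, "normalization.json", "preprocess")
  raw <- jsonlite::read_json(np_file, simplifyVector = TRUE)
  np <- structure(list(variables = raw$variables,
                       x_min = unlist(raw$x_min), x_max = unlist(raw$x_max)),
                  class = "normalization_params")
  list(train = read_records(require_artifact(outdir, "train_scaled.csv",
                                             "preprocess")),
       validation = read_records(file.path(outdir, "validation_scaled.csv")),
       test = read_records(file.path(outdir, "test_scaled.csv")),
       np = np)
}

# labels from scaled biogas values (threshold mapped into scaled units)
label_high_yield_scaled <- function(scaled, np) {
  rng <- np$x_max[["biogas_yield"]] - np$x_min[["biogas_yield"]]
  label_high_yield(scaled$biogas_yield * rng + np$x_min[["biogas_yield"]])
}
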