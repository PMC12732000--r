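# Shared preprocessing protocol: physical-limit cleaning, min-max scaling
# fitted on the training block only, 7:2:1 splitting, two-sample K-S
# similarity checks and training-set Pearson feature selection.

#' Cleaning limits for physically impossible records
#'
#' @param temperature_max,feed_solids_max,organic_matter_max,biogas_min
#'   default engineering limits; set any to `NA` to disable.
#' @param extra named list of additional `c(lower, upper)` bounds per
#'   variable (either side may be `NA`).
#' @return Object of class `cleaning_limits`: a data.frame with `variable`,
#'   `lower`, `upper`.
#' @export
cleaning_limits <- function(temperature_max = 80, feed_solids_max = 40,
                            organic_matter_max = 50, biogas_min = 0,
                            extra = list()) {
  lim <- data.frame(
    variable = c("temperature", "feed_solids", "organic_matter",
                 "biogas_yield"),
    lower = c(NA, NA, NA, biogas_min),
    upper = c(temperature_max, feed_solids_max, organic_matter_max, NA),
    stringsAsFactors = FALSE
  )
  for (v in names(extra)) {
    b <- extra[[v]]
    lim <- rbind(lim, data.frame(variable = v, lower = b[1], upper = b[2]))
  }
  ok <- is.na(lim$lower) | is.na(lim$upper) | lim$lower < lim$upper
  if (!all(ok)) stop("cleaning limits must have lower < upper")
  structure(lim, class = c("cleaning_limits", "data.frame"))
}

#' Remove records violating the cleaning limits
#'
#' @param table record table.
#' @param limits a [cleaning_limits()] object.
#' @return list with `table` (surviving records, order preserved) and
#'   `removed` (count).
#' @export
remove_outliers <- function(table, limits = cleaning_limits()) {
  if (nrow(table) == 0) return(list(table = table, removed = 0L))
  keep <- rep(TRUE, nrow(table))
  for (i in seq_len(nrow(limits))) {
    v <- limits$variable[i]
    if (!v %in% names(table)) next
    x <- table[[v]]
    if (!is.na(limits$lower[i])) keep <- keep & x >= limits$lower[i]
    if (!is.na(limits$upper[i])) keep <- keep & x <= limits$upper[i]
  }
  list(table = table[keep, , drop = FALSE],
       removed = as.integer(sum(!keep)))
}

#' Fit min-max normalization parameters on training data
#'
#' @param train training record table (used exclusively; applying the fitted
#'   params elsewhere never updates them).
#' @param variables variables to scale.
#' @return Object of class `normalization_params`.
#' @export
minmax_fit <- function(train, variables) {
  if (nrow(train) == 0) stop("training table is empty")
  miss <- setdiff(variables, names(train))
  if (length(miss)) stop("unknown variable(s): ", paste(miss, collapse = ", "))
  x_min <- vapply(variables, function(v) min(train[[v]]), numeric(1))
  x_max <- vapply(variables, function(v) max(train[[v]]), numeric(1))
  if (any(x_max <= x_min))
    stop("degenerate scale: constant variable(s) ",
         paste(variables[x_max <= x_min], collapse = ", "))
  structure(list(variables = variables, x_min = x_min, x_max = x_max),
            class = "normalization_params")
}

#' Apply (or invert) min-max scaling
#'
#' `minmax_apply` maps each variable through
#' `(x - x_min) / (x_max - x_min)`; values outside the training range are
#' allowed to leave `[0, 1]` (no clipping). `minmax_invert` is the exact
#' algebraic inverse.
#'
#' @param table record table (only the fitted variables are transformed).
#' @param params a [minmax_fit()] result.
#' @return The transformed table.
#' @export
minmax_apply <- function(table, params) {
  stopifnot(inherits(params, "normalization_params"))
  miss <- setdiff(params$variables, names(table))
  if (length(miss)) stop("unknown variable(s): ", paste(miss, collapse = ", "))
  for (v in params$variables)
    table[[v]] <- (table[[v]] - params$x_min[[v]]) /
      (params$x_max[[v]] - params$x_min[[v]])
  table
}

#' @rdname minmax_apply
#' @export
minmax_invert <- function(table, params) {
  stopifnot(inherits(params, "normalization_params"))
  for (v in params$variables)
    table[[v]] <- table[[v]] * (params$x_max[[v]] - params$x_min[[v]]) +
      params$x_min[[v]]
  table
}

#' Split records into training, validation and test sets
#'
#' Sizes are `floor(0.7 n)`, `floor(0.2 n)` and the remainder for the default
#' 7:2:1 ratios. Chronological mode keeps time order across the blocks
#' (train earliest); random mode permutes rows first under the seed.
#'
#' @param table record table with `n >= 10` rows.
#' @param ratios positive train/validation/test proportions summing to 1.
#' @param mode `"chronological"` (default) or `"random"`.
#' @param seed seed for random mode.
#' @return list with `train`, `validation`, `test`.
#' @export
split_records <- function(table, ratios = c(0.7, 0.2, 0.1),
                          mode = c("chronological", "random"), seed = 42L) {
  mode <- match.arg(mode)
  n <- nrow(table)
  if (n < 10) stop("need at least 10 records to split")
  if (length(ratios) != 3 || any(ratios <= 0) ||
      !isTRUE(all.equal(sum(ratios), 1)))
    stop("ratios must be three positive values summing to 1")
  idx <- seq_len(n)
  if (mode == "random") idx <- with_seed(seed, sample(idx))
  n_train <- floor(ratios[1] * n)
  n_val <- floor(ratios[2] * n)
  list(train = table[idx[seq_len(n_train)], , drop = FALSE],
       validation = table[idx[n_train + seq_len(n_val)], , drop = FALSE],
       test = table[idx[(n_train + n_val + 1):n], , drop = FALSE])
}

#' Two-sample Kolmogorov-Smirnov similarity
#'
#' Used to confirm that the train/validation/test subsets are statistically
#' indistinguishable (p > 0.05) variable by variable.
#'
#' @param a,b numeric samples, each of size >= 5.
#' @return list with `D` (statistic) and `p` (asymptotic p-value).
#' @export
ks_similarity <- function(a, b) {
  if (length(a) < 5 || length(b) < 5)
    stop("both samples must have at least 5 observations")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' K-S check of a three-way split
#'
#' Runs [ks_similarity()] for every variable between each pair of subsets
#' and reports whether every p exceeds the threshold.
#'
#' @param splits result of [split_records()].
#' @param variables variables to check.
#' @param alpha significance threshold (default 0.05).
#' @return list with `table` (variable x pair p-values) and `pass`.
#' @export
ks_check_split <- function(splits, variables, alpha = 0.05) {
  pairs <- list(c("train", "validation"), c("train", "test"),
                c("validation", "test"))
  res <- sapply(pairs, function(pr)
    vapply(variables, function(v)
      ks_similarity(splits[[pr[1]]][[v]], splits[[pr[2]]][[v]])$p,
      numeric(1)))
  colnames(res) <- vapply(pairs, paste, collapse = "-", character(1))
  list(table = res, pass = all(res > alpha))
}

#' Pearson correlation matrix of the process variables
#'
#' Computed on the training set only (information-leakage guard).
#'
#' @param train training record table (>= 3 rows).
#' @param variables variables to include; defaults to the nine process
#'   variables present in the table.
#' @return symmetric correlation matrix of class `correlation_matrix`.
#' @export
pearson_matrix <- function(train, variables = intersect(plant_variables(),
                                                        names(train))) {
  if (nrow(train) < 3) stop("need at least 3 training rows")
  X <- as.matrix(train[, variables, drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant variable(s) give undefined correlations: ",
         paste(variables[sds == 0], collapse = ", "))
  m <- stats::cor(X)
  structure(m, class = c("correlation_matrix", class(m)))
}

#' Select core predictive features by correlation with a target
#'
#' Variables with `|r| >= core_threshold` against the target become core
#' predictors; the rest are auxiliary stability indicators. The default 0.40
#' cut separates the strongly correlated feed variables from weak pH and
#' dissolved oxygen under any reasonable configuration.
#'
#' @param matrix a [pearson_matrix()] result.
#' @param target target variable (must be in the matrix).
#' @param core_threshold absolute-correlation cut-off.
#' @return list with `core` and `auxiliary` character vectors (target
#'   excluded from both).
#' @export
select_features <- function(matrix, target, core_threshold = 0.40) {
  vars <- rownames(matrix)
  if (!target %in% vars) stop("target not present in correlation matrix")
  others <- setdiff(vars, target)
  r <- matrix[others, target]
  list(core = others[abs(r) >= core_threshold],
       auxiliary = others[abs(r) < core_threshold])
}
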