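#' Random-forest configuration
#'
#' Hyperparameters for the importance analysis: 500 fully grown trees
#' (`nodesize = 1`) and `mtry` either fixed or `"auto"`, in which case
#' [tune_mtry()] picks the candidate minimising the out-of-bag mean squared
#' error.
#'
#' @param ntree Number of trees (>= 100, default 500).
#' @param nodesize Minimum terminal-node size (default 1, i.e. unpruned).
#' @param mtry Integer, or `"auto"` to tune by OOB-MSE.
#' @param mtry_candidates Candidate values for tuning (default `1:p` at fit
#'   time).
#' @param seed Integer seed controlling bootstrap and permutation draws.
#' @return Object of class `rf_config`.
#' @export
rf_config <- function(ntree = 500L, nodesize = 1L, mtry = "auto",
                      mtry_candidates = NULL, seed = 1L) {
  stopifnot(ntree >= 100L, nodesize >= 1L)
  if (!identical(mtry, "auto") && !(is.numeric(mtry) && mtry >= 1))
    stopf("mtry must be 'auto' or a positive integer")
  structure(list(ntree = as.integer(ntree), nodesize = as.integer(nodesize),
                 mtry = mtry, mtry_candidates = mtry_candidates,
                 seed = as.integer(seed)),
            class = "rf_config")
}

#' Kendall correlation matrix among covariates
#'
#' Pairwise tie-corrected Kendall tau-b over cells, for assessing the
#' mutual associations of the independent variables. Constant variables get
#' an `NA` row/column (with a warning) rather than an error.
#'
#' @param cells Cell table (>= 10 rows).
#' @param variables Covariate names (>= 2; default all fifteen).
#' @return Symmetric matrix of class `c("kendall_matrix", "matrix")` with
#'   unit diagonal.
#' @export
kendall_matrix <- function(cells, variables = variable_names()) {
  stopifnot(is.data.frame(cells))
  if (nrow(cells) < 10L) stopf("need >= 10 cells for Kendall correlations")
  if (length(variables) < 2L) stopf("need >= 2 variables")
  m <- vapply(variables, function(v) get_variable(cells, v),
              numeric(nrow(cells)))
  const <- apply(m, 2, function(col) length(unique(col)) < 2L)
  tau <- matrix(NA_real_, length(variables), length(variables),
                dimnames = list(variables, variables))
  ok <- !const
  if (any(const))
    warning(sprintf("constant variable(s) reported as NA: %s",
                    paste(variables[const], collapse = ", ")),
            call. = FALSE)
  if (sum(ok) >= 2L)
    tau[ok, ok] <- cor(m[, ok, drop = FALSE], method = "kendall")
  diag(tau)[ok] <- 1
  class(tau) <- c("kendall_matrix", "matrix")
  tau
}

rf_design <- function(cells, response, predictors) {
  y <- get_variable(cells, response)
  X <- cells[, predictors, drop = FALSE]
  for (p in predictors) get_variable(cells, p)  # type check
  list(X = as.data.frame(X), y = y)
}

#' Tune mtry by out-of-bag error
#'
#' Fits one forest per candidate `mtry` (all of `1:p` by default), each from
#' the same seed, and returns the candidate with the smallest OOB mean
#' squared error; ties go to the smaller `mtry`.
#'
#' @param cells Cell table (>= 50 rows — below that the OOB estimate is too
#'   unstable to tune on).
#' @param response Response column (typically `protected_fraction`).
#' @param predictors Predictor columns (>= 2).
#' @param config An [rf_config()].
#' @return List with `mtry` (the winner), and `oob_mse` (named vector over
#'   candidates).
#' @export
tune_mtry <- function(cells, response = "protected_fraction",
                      predictors = forest_predictors(),
                      config = rf_config()) {
  stopifnot(inherits(config, "rf_config"))
  if (nrow(cells) < 50L)
    stopf("need >= 50 cells to tune mtry on OOB error (got %d)", nrow(cells))
  if (length(predictors) < 2L) stopf("need >= 2 predictors")
  d <- rf_design(cells, response, predictors)
  cand <- config$mtry_candidates %||% seq_along(predictors)
  cand <- sort(unique(as.integer(cand)))
  if (any(cand < 1L | cand > length(predictors)))
    stopf("mtry candidates must lie in 1..%d", length(predictors))
  oob <- vapply(cand, function(m) {
    rf <- with_seed(config$seed,
      randomForest::randomForest(d$X, d$y, ntree = config$ntree, mtry = m,
                                 nodesize = config$nodesize))
    rf$mse[config$ntree]
  }, 0)
  names(oob) <- cand
  list(mtry = cand[which.min(oob)], oob_mse = oob)
}

#' Permutation variable importance with group averages
#'
#' Grows a regression forest (`ntree`, `nodesize`, and tuned or fixed
#' `mtry` from `config`) and reads off, per predictor, how much the
#' out-of-bag mean squared error increases when that predictor's OOB values
#' are permuted — averaged over trees and normalised by the standard
#' deviation across trees. Raw importances are kept for audit; for the
#' ranking, negative values are clipped to zero and the rest rescaled to
#' percentages summing to 100. Group averages follow the
#' biological-conservation pre-averaging rule of [group_averages()].
#'
#' @inheritParams tune_mtry
#' @return Object of class `importance_table`: list with `table` (data
#'   frame: `variable`, `raw_importance`, `percent_importance`, `group`),
#'   `group_averages`, `chosen_mtry`, `oob_mse`, `ntree`, `nodesize`,
#'   `seed`.
#' @export
permutation_importance <- function(cells, response = "protected_fraction",
                                   predictors = forest_predictors(),
                                   config = rf_config()) {
  stopifnot(inherits(config, "rf_config"))
  d <- rf_design(cells, response, predictors)
  mtry <- config$mtry
  if (identical(mtry, "auto"))
    mtry <- tune_mtry(cells, response, predictors, config)$mtry
  mtry <- as.integer(mtry)
  if (mtry < 1L || mtry > length(predictors))
    stopf("mtry = %d outside 1..%d", mtry, length(predictors))
  rf <- with_seed(config$seed + 1L,
    randomForest::randomForest(d$X, d$y, ntree = config$ntree, mtry = mtry,
                               nodesize = config$nodesize,
                               importance = TRUE))
  raw <- randomForest::importance(rf, type = 1, scale = TRUE)[, 1]
  clipped <- pmax(raw, 0)
  if (sum(clipped) <= 0)
    stopf("no signal: all permutation importances are <= 0")
  pct <- 100 * clipped / sum(clipped)
  vt <- variable_table()
  grp <- vt$group[match(predictors, vt$variable)]
  tab <- data.frame(variable = predictors,
                    raw_importance = as.numeric(raw),
                    percent_importance = as.numeric(pct),
                    group = grp, stringsAsFactors = FALSE)
  known <- intersect(predictors, vt$variable)
  ga <- if (length(known))
    group_averages(setNames(pct, predictors)[known])
  else c(preferential = NA_real_, opportunistic = NA_real_)
  structure(list(table = tab,
                 group_averages = ga,
                 chosen_mtry = mtry, oob_mse = rf$mse[config$ntree],
                 ntree = config$ntree, nodesize = config$nodesize,
                 seed = config$seed),
            class = "importance_table")
}

#' @export
print.importance_table <- function(x, ...) {
  cat(sprintf("importance_table: ntree = %d, nodesize = %d, mtry = %d, OOB-MSE = %.5g\n",
              x$ntree, x$nodesize, x$chosen_mtry, x$oob_mse))
  tab <- x$table[order(-x$table$percent_importance), ]
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-22s %6.2f%%  (%s)\n", tab$variable[i],
                tab$percent_importance[i], tab$group[i]))
  cat(sprintf("  group averages: preferential %.2f, opportunistic %.2f\n",
              x$group_averages[["preferential"]],
              x$group_averages[["opportunistic"]]))
  invisible(x)
}

#' Group-average importances with biological pre-averaging
#'
#' Averages percent importances within the preferential and opportunistic
#' groups. Animal and vascular-plant richness depict one single motivation
#' (biological conservation), so their importances are averaged into one
#' value *before* the preferential group is averaged: the preferential
#' average runs over tourism, frontiers, biomass, and mean(animal, plant);
#' the opportunistic average over population, isolation, coasts, and
#' cropland suitability.
#'
#' @param importances Named numeric vector over the nine forest predictors
#'   (or any subset covering whole groups).
#' @param grouping Data frame mapping `variable` to `group` and
#'   `motivation` (default [variable_table()]).
#' @return Named numeric vector with elements `preferential` and
#'   `opportunistic`.
#' @examples
#' group_averages(c(tourism = 12.72, frontiers = 3.42, biomass = 7.31,
#'                  animal_richness = 9.19, plant_richness = 2.54,
#'                  population = 19.93, isolation = 34.61, coasts = 7.22,
#'                  cropland_suitability = 3.07))
#' @export
group_averages <- function(importances, grouping = variable_table()) {
  if (is.null(names(importances)))
    stopf("importances must be a named vector")
  unknown <- setdiff(names(importances), grouping$variable)
  if (length(unknown))
    stopf("unknown variable(s): %s", paste(unknown, collapse = ", "))
  out <- c(preferential = NA_real_, opportunistic = NA_real_)
  for (g in names(out)) {
    vars <- grouping$variable[grouping$group == g]
    vars <- intersect(vars, names(importances))
    if (!length(vars)) next
    vals <- importances[vars]
    mot <- grouping$motivation[match(vars, grouping$variable)]
    # one value per motivation: members sharing a motivation are
    # pre-averaged (animal + plant -> biological conservation)
    out[[g]] <- mean(tapply(vals, mot, mean))
  }
  out
}
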