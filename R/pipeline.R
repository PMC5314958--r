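#' Configure a pipeline run
#'
#' @param input A [world_config()] (the world is generated) or a path to a
#'   cell-table CSV (see [read_cells()]).
#' @param regions Region labels to analyse, or `"ALL"` for every region
#'   present plus the `GLOBAL` stratum.
#' @param variables Covariate names (default all fifteen canonical ones).
#' @param stages Subset of `c("summarize", "evenness", "regress",
#'   "importance", "correlate")`, executed in this order; `summarize`
#'   (histogram construction) is implied by the later histogram-based
#'   stages.
#' @param seed Integer seed for every stochastic stage.
#' @param output_dir Directory for the result CSV/JSON bundle, or `NULL` to
#'   keep results in memory only.
#' @param min_classes Minimum nonempty classes per histogram (default 8).
#' @param truncate Tail-pooling percentiles (default 0.025/0.975).
#' @return Object of class `run_config`.
#' @export
run_config <- function(input = world_config(),
                       regions = "ALL",
                       variables = variable_names(),
                       stages = c("summarize", "evenness", "regress",
                                  "importance", "correlate"),
                       seed = 1L,
                       output_dir = NULL,
                       min_classes = 8L,
                       truncate = c(0.025, 0.975)) {
  if (!length(stages)) stopf("stages must be nonempty")
  stages <- match.arg(stages, c("summarize", "evenness", "regress",
                                "importance", "correlate"),
                      several.ok = TRUE)
  if (!(inherits(input, "world_config") ||
        (is.character(input) && length(input) == 1L)))
    stopf("input must be a world_config or a CSV path")
  structure(list(input = input, regions = regions, variables = variables,
                 stages = stages, seed = as.integer(seed),
                 output_dir = output_dir, min_classes = min_classes,
                 truncate = truncate),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a flat YAML file with optional sections `world` (fields of
#' [world_config()]), `regions`, `variables`, `stages`, `seed`,
#' `output_dir`; `input` may alternatively name a cell CSV.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  input <- if (!is.null(y$world)) {
    args <- y$world
    if (!is.null(args$effect_sizes)) args$effect_sizes <- unlist(args$effect_sizes)
    if (!is.null(args$covariate_corr)) args$covariate_corr <- unlist(args$covariate_corr)
    if (!is.null(args$mix_weights)) args$mix_weights <- unlist(args$mix_weights)
    if (!is.null(args$lat_range)) args$lat_range <- as.numeric(args$lat_range)
    if (!is.null(args$lon_range)) args$lon_range <- as.numeric(args$lon_range)
    do.call(world_config, args)
  } else if (!is.null(y$input)) y$input else world_config()
  run_config(input = input,
             regions = y$regions %||% "ALL",
             variables = unlist(y$variables) %||% variable_names(),
             stages = unlist(y$stages) %||% c("summarize", "evenness",
                                              "regress", "importance",
                                              "correlate"),
             seed = y$seed %||% 1L,
             output_dir = y$output_dir)
}

#' Run the full gradient-analysis pipeline
#'
#' Executes, from one configuration: world generation or cell-table
#' loading, the 5%-terrestrial filter, histogram construction for every
#' (region + globe) x variable combination (so 7 regions and 15 variables
#' yield 120 histograms), evenness of `FRAC.PROT` vs `AREA.PROT` for the
#' representative (biophysical) variables, AIC model selection for the
#' preferential and opportunistic variables, random-forest importance over
#' cells, and the Kendall correlation matrix. Each stage logs a structured
#' line with its counts; any stage error aborts naming the failing
#' variable/region. Given the same configuration and seed the whole bundle
#' — including written CSVs — is byte-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a `run_bundle`: list with `cells`, `histograms`,
#'   `evenness`, `fits`, `importance`, `kendall`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()

  cells <- if (inherits(config$input, "world_config")) {
    generate_world(config$input)
  } else {
    read_cells(config$input)
  }
  n_raw <- nrow(cells)
  cells <- filter_cells(cells)
  missing_vars <- setdiff(config$variables, names(cells))
  if (length(missing_vars))
    stopf("requested variable(s) absent from cell table: %s",
          paste(missing_vars, collapse = ", "))

  regions <- if (identical(config$regions, "ALL"))
    sort(unique(cells$region)) else config$regions
  strata <- c(regions, "GLOBAL")
  stages <- config$stages
  need_hist <- any(c("summarize", "evenness", "regress") %in% stages)

  bundle <- list(cells = cells, config = config)

  if (need_hist) {
    hists <- list()
    for (v in config$variables) {
      for (rg in strata) {
        h <- tryCatch(
          ensure_min_classes(
            build_histogram(cells, v, rg, truncate = config$truncate),
            cells, min_classes = config$min_classes),
          error = function(e)
            stopf("histogram stage failed for %s x %s: %s", v, rg,
                  conditionMessage(e)))
        hists[[paste(v, rg, sep = "|")]] <- h
      }
    }
    message(sprintf("summarize: built %d histograms (%d strata x %d variables)",
                    length(hists), length(strata), length(config$variables)))
    bundle$histograms <- hists
  }

  if ("evenness" %in% stages) {
    rep_vars <- intersect(config$variables, variable_names("representative"))
    ev <- list()
    for (v in rep_vars) for (rg in strata) {
      h <- bundle$histograms[[paste(v, rg, sep = "|")]]
      ev[[paste(v, rg, sep = "|")]] <- tryCatch(
        compare_representativeness(h),
        error = function(e)
          stopf("evenness stage failed for %s x %s: %s", v, rg,
                conditionMessage(e)))
    }
    message(sprintf("evenness: %d variable x stratum comparisons", length(ev)))
    bundle$evenness <- ev
  }

  if ("regress" %in% stages) {
    fit_vars <- intersect(config$variables,
                          variable_names(c("preferential", "opportunistic")))
    fits <- list()
    n_failed <- 0L
    for (v in fit_vars) for (rg in strata) {
      h <- bundle$histograms[[paste(v, rg, sep = "|")]]
      res <- tryCatch(
        regress_histogram(h, seed = config$seed),
        error = function(e)
          stopf("regression stage failed for %s x %s: %s", v, rg,
                conditionMessage(e)))
      n_failed <- n_failed +
        (length(family_info()$family) - length(res$fits))
      fits[[paste(v, rg, sep = "|")]] <- res
    }
    message(sprintf("regress: %d profiles fitted, %d family fits unavailable/failed",
                    length(fits), n_failed))
    bundle$fits <- fits
  }

  if ("importance" %in% stages) {
    preds <- intersect(config$variables, forest_predictors())
    bundle$importance <- permutation_importance(
      cells, predictors = preds,
      config = rf_config(seed = config$seed))
    message(sprintf("importance: mtry = %d chosen by OOB-MSE over %d cells",
                    bundle$importance$chosen_mtry, nrow(cells)))
  }

  if ("correlate" %in% stages) {
    bundle$kendall <- kendall_matrix(cells, config$variables)
    message("correlate: Kendall tau matrix over ",
            length(config$variables), " variables")
  }

  bundle$manifest <- list(
    package = "protgrad",
    version = as.character(packageVersion("protgrad")),
    seed = config$seed,
    stages = stages,
    n_cells_input = n_raw,
    n_cells_analyzed = nrow(cells),
    n_regions = length(regions),
    n_variables = length(config$variables),
    n_histograms = length(bundle$histograms %||% list())
  )
  class(bundle) <- "run_bundle"

  if (!is.null(config$output_dir)) write_bundle(bundle, config$output_dir)
  message(sprintf("pipeline done in %.1f s",
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(bundle)
}

evenness_to_df <- function(ev_list) {
  do.call(rbind, lapply(ev_list, function(e) {
    data.frame(variable = e$variable, region = e$region,
               measure = c("FRAC_PROT", "AREA_PROT"),
               n_classes = e$n_classes,
               H = c(e$H_fraction$H, e$H_quota$H),
               H_prime = c(e$H_fraction$H_prime, e$H_quota$H_prime),
               stringsAsFactors = FALSE)
  }))
}

fits_to_df <- function(fit_list) {
  do.call(rbind, lapply(fit_list, function(r) {
    do.call(rbind, lapply(r$fits, function(f) {
      data.frame(variable = r$variable, region = r$region,
                 family = f$family,
                 selected = identical(f$family, r$selected$family),
                 aic = f$aic, pseudo_r2 = f$pseudo_r2, rss = f$rss,
                 coefficients = paste(
                   sprintf("%s=%.8g", names(f$coefficients), f$coefficients),
                   collapse = ";"),
                 breakpoint = if (f$family == "piecewise")
                   f$coefficients[["psi"]] else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name)
    write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
  if (!is.null(bundle$histograms))
    wcsv(histograms_to_df(bundle$histograms), "histograms.csv")
  if (!is.null(bundle$evenness))
    wcsv(evenness_to_df(bundle$evenness), "evenness.csv")
  if (!is.null(bundle$fits))
    wcsv(fits_to_df(bundle$fits), "fits.csv")
  if (!is.null(bundle$importance)) {
    wcsv(bundle$importance$table, "importance.csv")
    jsonlite::write_json(
      bundle$importance[c("chosen_mtry", "oob_mse", "ntree", "nodesize",
                          "seed", "group_averages")],
      file.path(dir, "importance_meta.json"),
      auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(bundle$kendall)) {
    k <- as.data.frame(unclass(bundle$kendall))
    k <- cbind(variable = rownames(bundle$kendall), k)
    wcsv(k, "kendall.csv")
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Summarise a pipeline run
#'
#' Condenses a bundle into the tables a reader wants first: per-stratum
#' fraction- vs quota-representativeness (H' averaged over the biophysical
#' variables, with their ratio), the selected regression family per
#' variable x stratum, and the importance ranking with group averages.
#' Missing stages produce warnings and a partial summary rather than an
#' error.
#'
#' @param bundle A `run_bundle` from [run_pipeline()].
#' @return Object of class `run_summary` (list of data frames /
#'   vectors); serialisable with [jsonlite::toJSON()].
#' @export
summarize_run <- function(bundle) {
  out <- list()
  if (is.null(bundle$evenness)) {
    warning("evenness stage missing from bundle", call. = FALSE)
  } else {
    df <- evenness_to_df(bundle$evenness)
    strata <- unique(df$region)
    out$representativeness <- do.call(rbind, lapply(strata, function(rg) {
      d <- df[df$region == rg, ]
      hf <- mean(d$H_prime[d$measure == "FRAC_PROT"])
      hq <- mean(d$H_prime[d$measure == "AREA_PROT"])
      data.frame(region = rg, H_fraction = hf, H_quota = hq,
                 ratio = if (hq > 0) hf / hq else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(bundle$fits)) {
    warning("regression stage missing from bundle", call. = FALSE)
  } else {
    out$selected_models <- do.call(rbind, lapply(bundle$fits, function(r) {
      data.frame(variable = r$variable, region = r$region,
                 family = r$selected$family,
                 pseudo_r2 = r$selected$pseudo_r2,
                 stringsAsFactors = FALSE)
    }))
    rownames(out$selected_models) <- NULL
  }
  if (is.null(bundle$importance)) {
    warning("importance stage missing from bundle", call. = FALSE)
  } else {
    tab <- bundle$importance$table
    out$importance <- tab[order(-tab$percent_importance), ]
    rownames(out$importance) <- NULL
    out$group_averages <- as.list(bundle$importance$group_averages)
    out$chosen_mtry <- bundle$importance$chosen_mtry
  }
  structure(out, class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  if (!is.null(x$representativeness)) {
    cat("Representativeness (H' averaged over biophysical variables):\n")
    print(format(x$representativeness, digits = 3), row.names = FALSE)
  }
  if (!is.null(x$group_averages)) {
    cat("\nImportance group averages: preferential",
        sprintf("%.2f", x$group_averages$preferential),
        "| opportunistic",
        sprintf("%.2f", x$group_averages$opportunistic),
        sprintf("(mtry = %d)\n", x$chosen_mtry))
    cat("Top drivers:\n")
    top <- utils::head(x$importance, 4L)
    for (i in seq_len(nrow(top)))
      cat(sprintf("  %-22s %6.2f%%\n", top$variable[i],
                  top$percent_importance[i]))
  }
  invisible(x)
}
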