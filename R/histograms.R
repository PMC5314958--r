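#' Filter grid cells by terrestrial fraction
#'
#' Keeps exactly the cells whose terrestrial fraction is at least 5% (the
#' sampling rule for the half-degree grid); the number of removed cells is
#' reported as a message.
#'
#' @param cells Cell table (see [generate_world()] / [read_cells()]).
#' @param min_terrestrial Threshold, default 0.05.
#' @return Filtered cell table. Errors if nothing survives.
#' @export
filter_cells <- function(cells, min_terrestrial = 0.05) {
  stopifnot(is.data.frame(cells), "terrestrial_fraction" %in% names(cells))
  keep <- cells$terrestrial_fraction >= min_terrestrial
  if (!any(keep))
    stopf("no cells with terrestrial fraction >= %g: nothing to analyze",
          min_terrestrial)
  message(sprintf("filter_cells: removed %d of %d cells (terrestrial fraction < %g)",
                  sum(!keep), length(keep), min_terrestrial))
  cells[keep, , drop = FALSE]
}

#' Default gradient class width
#'
#' One twentieth of the central 95% span of the variable — i.e.
#' `(P97.5 - P2.5) / n_classes` computed on the *global* (all-region)
#' distribution of included cells, unweighted. The same width is reused for
#' every region so regional histograms stay comparable.
#'
#' @param cells Filtered cell table (all regions).
#' @param variable Covariate name.
#' @param n_classes Number of interior classes the width should yield
#'   between the truncation percentiles (default 20).
#' @param truncate Lower/upper truncation percentiles (default 0.025/0.975).
#' @return Class width in the variable's units.
#' @export
default_class_width <- function(cells, variable, n_classes = 20L,
                                truncate = c(0.025, 0.975)) {
  v <- get_variable(cells, variable)
  if (length(unique(v)) < 2L)
    stopf("variable '%s' is constant: cannot set a class width", variable)
  qs <- quantile(v, truncate, names = FALSE)
  width <- (qs[2] - qs[1]) / n_classes
  if (width <= 0)
    stopf("variable '%s': central span is zero between percentiles %g and %g",
          variable, truncate[1], truncate[2])
  width
}

get_variable <- function(cells, variable) {
  if (!variable %in% names(cells))
    stopf("variable '%s' not found in cell table", variable)
  v <- cells[[variable]]
  if (!is.numeric(v)) stopf("variable '%s' is not numeric", variable)
  v
}

#' Build a three-measure gradient histogram
#'
#' Summarises protection along one covariate gradient for one stratum
#' (a region label or `"GLOBAL"` for all cells). Interior classes of fixed
#' width span the global 2.5–97.5 percentile range of the variable; cells
#' below / above that range are pooled into the first / last class, so
#' truncation changes class membership but never the totals. Per class j the
#' histogram carries:
#'
#' * `area_km2` (`AREA`) — total terrestrial area,
#' * `area_prot_km2` (`AREA.PROT`) — total protected area,
#' * `frac_prot` (`FRAC.PROT`) — the area-weighted mean protected fraction,
#'   identically `AREA.PROT / AREA`,
#'
#' with classes half-open `[lower, upper)` and the last class closed. Class
#' boundaries and percentiles are always computed on the full `cells` table
#' (the global distribution), regardless of `region`. Empty interior classes
#' are retained with zero area and an undefined (`NA`) protected fraction;
#' downstream statistics use nonempty classes only.
#'
#' @param cells Filtered cell table covering all regions (used for global
#'   class boundaries even when a region is requested).
#' @param variable Covariate name.
#' @param region Region label present in `cells$region`, or `"GLOBAL"`.
#' @param class_width Class width; default [default_class_width()].
#' @param truncate Percentile pair for tail pooling, or `NULL` to span the
#'   full data range with no pooling.
#' @param n_classes Interior class count used for the default width.
#' @return An object of class `gradient_histogram`: a list with `variable`,
#'   `region`, `class_width`, `truncation`, and `classes` (a data frame with
#'   columns `j`, `lower`, `upper`, `area_km2`, `area_prot_km2`,
#'   `frac_prot`, `n_cells`).
#' @examples
#' w <- generate_world(world_config(seed = 1, lat_range = c(-5, 5),
#'                                  lon_range = c(-10, 10)))
#' h <- build_histogram(suppressMessages(filter_cells(w)), "temperature")
#' h$classes[1:4, ]
#' @export
build_histogram <- function(cells, variable, region = "GLOBAL",
                            class_width = NULL,
                            truncate = c(0.025, 0.975),
                            n_classes = 20L) {
  v_global <- get_variable(cells, variable)
  if (identical(region, "GLOBAL")) {
    sub <- cells
  } else {
    if (!region %in% cells$region)
      stopf("unknown region label '%s'", region)
    sub <- cells[cells$region == region, , drop = FALSE]
  }
  if (is.null(class_width))
    class_width <- default_class_width(cells, variable,
                                       n_classes = n_classes,
                                       truncate = truncate %||% c(0.025, 0.975))
  if (!is.null(truncate)) {
    stopifnot(length(truncate) == 2L, truncate[1] < truncate[2])
    bounds <- quantile(v_global, truncate, names = FALSE)
    k <- max(1L, as.integer(ceiling((bounds[2] - bounds[1]) / class_width - 1e-9)))
    breaks <- bounds[1] + (0:k) * class_width
  } else {
    lo <- min(v_global)
    hi <- max(v_global)
    k <- as.integer(floor((hi - lo) / class_width)) + 1L
    breaks <- lo + (0:k) * class_width
  }
  v <- sub[[variable]]
  idx <- findInterval(v, breaks, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), k)  # pool the tails into the edge classes

  terr_area <- sub$terrestrial_fraction * sub$cell_area_km2
  prot_area <- sub$protected_fraction * terr_area
  area <- vapply(seq_len(k), function(j) sum(terr_area[idx == j]), 0)
  area_prot <- vapply(seq_len(k), function(j) sum(prot_area[idx == j]), 0)
  n_cells <- tabulate(idx, nbins = k)

  lower <- breaks[-(k + 1L)]
  upper <- breaks[-1L]
  if (length(v)) {
    lower[1] <- min(lower[1], min(v))
    upper[k] <- max(upper[k], max(v))
  }
  classes <- data.frame(
    j = seq_len(k), lower = lower, upper = upper,
    area_km2 = area, area_prot_km2 = area_prot,
    frac_prot = ifelse(area > 0, area_prot / area, NA_real_),
    n_cells = n_cells
  )
  structure(list(variable = variable, region = region,
                 class_width = class_width,
                 truncation = truncate, classes = classes),
            class = "gradient_histogram")
}

#' @export
print.gradient_histogram <- function(x, ...) {
  nz <- sum(x$classes$area_km2 > 0)
  cat(sprintf("gradient_histogram: %s x %s | %d classes (%d nonempty), width %g\n",
              x$variable, x$region, nrow(x$classes), nz, x$class_width))
  cat(sprintf("  total AREA %.4g km2, AREA.PROT %.4g km2 (%.1f%%)\n",
              sum(x$classes$area_km2), sum(x$classes$area_prot_km2),
              100 * sum(x$classes$area_prot_km2) /
                max(sum(x$classes$area_km2), 1e-12)))
  invisible(x)
}

#' Enforce the minimum-class rule
#'
#' Gradient statistics are only computed on histograms with at least
#' `min_classes` nonempty intervals. If a histogram falls short, the class
#' width is halved and the histogram rebuilt (same truncation, same global
#' boundaries) until the rule is satisfied; the search gives up below a
#' width floor of 2^-10 times the initial width.
#'
#' @param histogram A [build_histogram()] result.
#' @param cells The same full cell table the histogram was built from.
#' @param min_classes Minimum number of nonempty classes (default 8).
#' @return A compliant `gradient_histogram` (possibly the input unchanged).
#' @export
ensure_min_classes <- function(histogram, cells, min_classes = 8L) {
  stopifnot(inherits(histogram, "gradient_histogram"))
  v <- get_variable(cells, histogram$variable)
  sub_v <- if (identical(histogram$region, "GLOBAL")) v else
    v[cells$region == histogram$region]
  if (length(unique(sub_v)) < min_classes)
    stopf("variable '%s', region '%s': only %d distinct values, cannot reach %d classes",
          histogram$variable, histogram$region, length(unique(sub_v)),
          min_classes)
  h <- histogram
  width <- histogram$class_width
  floor_width <- width / 2^10
  while (sum(h$classes$area_km2 > 0) < min_classes) {
    width <- width / 2
    if (width < floor_width)
      stopf("variable '%s', region '%s': could not reach %d nonempty classes above the width floor",
            histogram$variable, histogram$region, min_classes)
    h <- build_histogram(cells, histogram$variable, histogram$region,
                         class_width = width,
                         truncate = histogram$truncation)
  }
  h
}

#' Flatten histograms to a single data frame
#'
#' @param histograms A `gradient_histogram` or list of them.
#' @return Data frame with columns `variable`, `region`, `j`, `lower`,
#'   `upper`, `area_km2`, `area_prot_km2`, `frac_prot`, `n_cells`.
#' @export
histograms_to_df <- function(histograms) {
  if (inherits(histograms, "gradient_histogram"))
    histograms <- list(histograms)
  do.call(rbind, lapply(histograms, function(h) {
    cbind(data.frame(variable = h$variable, region = h$region,
                     stringsAsFactors = FALSE),
          h$classes)
  }))
}
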