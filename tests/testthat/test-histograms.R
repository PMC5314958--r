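make_cells <- function(v, area = 100, tf = 1, pf = 0,
                       region = "region_1", var = "temperature") {
  n <- length(v)
  df <- data.frame(
    cell_id = sprintf("c%03d", seq_len(n)),
    lat = 0.25, lon = 0.25,
    cell_area_km2 = rep_len(area, n),
    terrestrial_fraction = rep_len(tf, n),
    protected_fraction = rep_len(pf, n),
    region = rep_len(region, n),
    stringsAsFactors = FALSE
  )
  df[[var]] <- v
  df
}

test_that("the terrestrial filter keeps exactly the >= 5% cells", {
  cells <- make_cells(1:3, tf = c(0.04, 0.05, 0.9))
  kept <- suppressMessages(filter_cells(cells))
  expect_identical(kept$terrestrial_fraction, c(0.05, 0.9))
  all_in <- make_cells(1:3, tf = c(0.05, 0.5, 1))
  expect_identical(suppressMessages(filter_cells(all_in)), all_in)
  expect_error(suppressMessages(filter_cells(make_cells(1:3, tf = 0.01))),
               "nothing to analyze")
  expect_message(filter_cells(cells), "removed 1 of 3")
})

test_that("the default class width is one twentieth of the central 95% span", {
  cells <- make_cells(seq(0, 100, length.out = 4001))
  expect_equal(default_class_width(cells, "temperature"), 4.75,
               tolerance = 1e-3)
  expect_error(default_class_width(make_cells(rep(1, 10)), "temperature"),
               "constant")
})

test_that("regional histograms reuse the global class width and boundaries", {
  set.seed(1)
  cells <- make_cells(c(runif(300, 0, 10), runif(300, 4, 6)),
                      region = rep(c("A", "B"), each = 300))
  w_global <- default_class_width(cells, "temperature")
  hB <- build_histogram(cells, "temperature", region = "B")
  expect_identical(hB$class_width, w_global)
  hG <- build_histogram(cells, "temperature")
  # same class grid: identical interior boundaries
  expect_equal(hB$classes$lower[2:10], hG$classes$lower[2:10])
  expect_error(build_histogram(cells, "temperature", region = "Z"),
               "unknown region")
})

test_that("histogram aggregation matches the hand-worked example", {
  cells <- make_cells(c(1, 1.4, 2.2, 3.0), area = c(100, 100, 200, 100),
                      pf = c(0.1, 0.3, 0.1, 0))
  h <- build_histogram(cells, "temperature", class_width = 1, truncate = NULL)
  expect_identical(nrow(h$classes), 3L)
  expect_equal(h$classes$lower, c(1, 2, 3))
  expect_equal(h$classes$area_km2, c(200, 200, 100))
  expect_equal(h$classes$area_prot_km2, c(40, 20, 0))
  expect_equal(h$classes$frac_prot, c(0.2, 0.1, 0))
  expect_identical(h$classes$n_cells, c(2L, 1L, 1L))
})

test_that("unprotected worlds give identically zero protected measures", {
  cells <- make_cells(runif(50, 0, 10), pf = 0)
  h <- build_histogram(cells, "temperature")
  expect_true(all(h$classes$area_prot_km2 == 0))
  nz <- h$classes$frac_prot[h$classes$area_km2 > 0]
  expect_true(all(nz == 0))
})

test_that("totals are conserved under any width and truncation", {
  f <- filtered(small_world(seed = 21))
  terr_total <- sum(f$terrestrial_fraction * f$cell_area_km2)
  prot_total <- sum(f$protected_fraction * f$terrestrial_fraction *
                      f$cell_area_km2)
  set.seed(7)
  for (i in 1:8) {
    v <- sample(variable_table()$variable, 1)
    trunc <- if (i %% 2) c(runif(1, 0, 0.2), runif(1, 0.8, 1)) else NULL
    width <- default_class_width(f, v) * runif(1, 0.3, 3)
    h <- build_histogram(f, v, class_width = width, truncate = trunc)
    expect_equal(sum(h$classes$area_km2), terr_total, tolerance = 1e-9)
    expect_equal(sum(h$classes$area_prot_km2), prot_total, tolerance = 1e-9)
  }
})

test_that("class protected fractions are bracketed by member cell fractions", {
  f <- filtered(small_world(seed = 22))
  h <- build_histogram(f, "isolation")
  breaks <- c(h$classes$lower, h$classes$upper[nrow(h$classes)])
  idx <- pmin(pmax(findInterval(f$isolation, breaks, rightmost.closed = TRUE),
                   1L), nrow(h$classes))
  for (j in which(h$classes$area_km2 > 0)) {
    pf <- f$protected_fraction[idx == j]
    expect_gte(h$classes$frac_prot[j], min(pf) - 1e-12)
    expect_lte(h$classes$frac_prot[j], max(pf) + 1e-12)
  }
})

test_that("empty interior classes are retained but carry no statistics", {
  cells <- make_cells(c(runif(30, 0, 1), runif(30, 9, 10)))
  h <- build_histogram(cells, "temperature", class_width = 1,
                       truncate = NULL)
  expect_true(any(h$classes$area_km2 == 0))
  expect_true(all(is.na(h$classes$frac_prot[h$classes$area_km2 == 0])))
})

test_that("the minimum-class rule rebuilds at halved widths", {
  set.seed(3)
  cells <- make_cells(runif(400, 0, 10), pf = 0.1)
  h5 <- build_histogram(cells, "temperature", class_width = 3,
                        truncate = NULL)
  expect_lt(sum(h5$classes$area_km2 > 0), 8)
  fixed <- ensure_min_classes(h5, cells)
  expect_gte(sum(fixed$classes$area_km2 > 0), 8)
  expect_equal(sum(fixed$classes$area_km2), sum(h5$classes$area_km2))

  h12 <- build_histogram(cells, "temperature", class_width = 0.5,
                         truncate = NULL)
  expect_identical(ensure_min_classes(h12, cells), h12)

  few <- make_cells(rep(c(1, 2, 3), 20))
  hf <- build_histogram(few, "temperature", class_width = 1, truncate = NULL)
  expect_error(ensure_min_classes(hf, few), "temperature.*3 distinct")
})

test_that("histograms flatten to the documented table layout", {
  f <- filtered(small_world(seed = 23))
  h1 <- build_histogram(f, "temperature")
  h2 <- build_histogram(f, "isolation", region = "region_2")
  df <- histograms_to_df(list(h1, h2))
  expect_identical(names(df), c("variable", "region", "j", "lower", "upper",
                                "area_km2", "area_prot_km2", "frac_prot",
                                "n_cells"))
  expect_setequal(unique(df$region), c("GLOBAL", "region_2"))
})
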