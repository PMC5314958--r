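test_that("cell areas follow the spherical band formula", {
  expect_equal(cell_area(0.25, 0.5), 3091, tolerance = 1 / 3091)
  expect_lt(cell_area(89.75, 0.5), 30)
  lats <- c(0.25, 10.25, 45.25, 80.25)
  expect_equal(cell_area(lats), cell_area(-lats))
  # strictly decreasing away from the equator
  expect_true(all(diff(cell_area(seq(0.25, 89.75, by = 0.5))) < 0))
  expect_error(cell_area(90), "pole")
  expect_error(cell_area(-90.2), "pole")
})

test_that("world generation is deterministic in the seed", {
  w1 <- small_world(seed = 11)
  w2 <- small_world(seed = 11)
  w3 <- small_world(seed = 12)
  expect_identical(w1, w2)
  expect_false(isTRUE(all.equal(w1$protected_fraction,
                                w3$protected_fraction)))
  # generation must not disturb the session RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(small_world(seed = 5)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("generated worlds respect cell invariants and the target share", {
  w <- small_world(seed = 2)
  expect_true(all(w$terrestrial_fraction >= 0 & w$terrestrial_fraction <= 1))
  expect_true(all(w$protected_fraction >= 0 & w$protected_fraction <= 1))
  expect_true(all(w$cell_area_km2 > 0))
  expect_setequal(setdiff(names(w), c("cell_id", "lat", "lon",
                                      "cell_area_km2",
                                      "terrestrial_fraction",
                                      "protected_fraction", "region")),
                  variable_table()$variable)
  terr <- w$terrestrial_fraction * w$cell_area_km2
  inc <- w$terrestrial_fraction >= 0.05
  share <- sum(w$protected_fraction[inc] * terr[inc]) / sum(terr[inc])
  target <- attr(w, "config")$target_protected_fraction
  expect_lt(abs(share - target) / target, 0.2)
})

test_that("fraction regime protects every driver class at the target rate", {
  w <- generate_world(world_config(seed = 3, regime = "fraction",
                                   effect_sizes = c(temperature = 1)))
  f <- filtered(w)
  expect_gte(nrow(f), 4000)
  h <- build_histogram(f, "temperature")
  nz <- h$classes[h$classes$area_km2 > 0, ]
  expect_true(all(abs(nz$frac_prot - 0.154) < 0.04))
})

test_that("quota regime gives every driver class the same protected area", {
  w <- suppressWarnings(
    generate_world(world_config(seed = 4, regime = "quota",
                                effect_sizes = c(temperature = 1))))
  f <- filtered(w)
  h <- build_histogram(f, "temperature")
  nz <- h$classes[h$classes$area_km2 > 0, ]
  # no class is capped at full protection in this world
  expect_true(all(nz$frac_prot < 1))
  ap <- nz$area_prot_km2
  expect_lt((max(ap) - min(ap)) / mean(ap), 0.05)
})

test_that("opportunistic regime makes protection increase with its driver", {
  w <- generate_world(world_config(
    seed = 5, regime = "opportunistic",
    effect_sizes = c(isolation = 1.0, population = -0.5, tourism = 0.25)))
  f <- filtered(w)
  expect_gt(cor(f$isolation, f$protected_fraction, method = "kendall"), 0)
  expect_lt(cor(f$population, f$protected_fraction, method = "kendall"), 0)
})

test_that("requested covariate correlations are realised with the right sign", {
  f <- filtered(generate_world(world_config(seed = 6)))
  expect_gte(nrow(f), 4000)
  planted <- default_covariate_corr()
  for (nm in names(planted)) {
    if (abs(planted[[nm]]) < 0.3) next
    pair <- strsplit(nm, ":", fixed = TRUE)[[1]]
    tau <- cor(f[[pair[1]]], f[[pair[2]]], method = "kendall")
    expect_equal(sign(tau), sign(planted[[nm]]), label = nm)
  }
})

test_that("infeasible correlation structures are rejected", {
  expect_error(world_config(covariate_corr = c(
    "temperature:precipitation" = 0.9,
    "temperature:elevation" = 0.9,
    "precipitation:elevation" = -0.9)), "positive-definite")
  expect_error(world_config(covariate_corr = c("temperature:precipitation" = 1.4)),
               "\\[-1, 1\\]")
  expect_error(world_config(covariate_corr = c("temperature:unobtainium" = 0.2)),
               "bad covariate_corr")
})

test_that("config invariants are enforced", {
  expect_error(world_config(resolution = 0.7), "does not divide")
  expect_error(world_config(target_protected_fraction = 0), "\\(0, 1\\)")
  expect_error(world_config(target_protected_fraction = 1.2), "\\(0, 1\\)")
  expect_error(world_config(effect_sizes = c(not_a_var = 1)), "unknown covariate")
  expect_error(world_config(mix_weights = c(fraction = 0.5, quota = 0.2)),
               "sum to 1")
})

test_that("cell tables round-trip through CSV losslessly", {
  w <- small_world(seed = 7)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_cells(w, path)
  r <- read_cells(path)
  expect_identical(names(r), names(as.data.frame(w)))
  expect_identical(r$cell_id, w$cell_id)
  expect_identical(r$region, w$region)
  for (cl in setdiff(names(w), c("cell_id", "region")))
    expect_equal(r[[cl]], w[[cl]], tolerance = 1e-12, label = cl)
})

test_that("cell-table reading validates structure and invariants", {
  w <- small_world(seed = 8)[1:5, ]
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))

  bad <- w; bad$protected_fraction[3] <- 1.2
  write_cells(bad, path)
  expect_error(read_cells(path), "protected_fraction.*row 3")

  bad <- w; bad$terrestrial_fraction <- NULL
  write_cells(bad, path)
  expect_error(read_cells(path), "missing mandatory column")

  bad <- w; bad$lat <- as.character(bad$lat); bad$lat[2] <- "north"
  write_cells(bad, path)
  expect_error(read_cells(path), "column 'lat', row 2")

  writeLines(paste(names(w), collapse = ","), path)
  empty <- read_cells(path)
  expect_s3_class(empty, "data.frame")
  expect_identical(nrow(empty), 0L)

  expect_error(read_cells(tempfile()), "no such file")
})
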