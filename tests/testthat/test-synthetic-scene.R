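test_that("default parameters reproduce the stated plot design", {
  p <- scene_params(seed = 11)
  gt <- generate_forest(p)
  expect_equal(nrow(gt$plots), 73)
  expect_equal(unname(gt$plots$xmax - gt$plots$xmin), rep(20, 73))
  # plot corners are multiples of 20 m (fishnet-aligned placement)
  expect_true(all(gt$plots$xmin %% 20 == 0 & gt$plots$ymin %% 20 == 0))
  # no two plots overlap
  n <- nrow(gt$plots)
  for (i in seq_len(n - 1)) {
    sep <- gt$plots$xmin[(i + 1):n] >= gt$plots$xmax[i] |
           gt$plots$xmax[(i + 1):n] <= gt$plots$xmin[i] |
           gt$plots$ymin[(i + 1):n] >= gt$plots$ymax[i] |
           gt$plots$ymax[(i + 1):n] <= gt$plots$ymin[i]
    expect_true(all(sep))
  }
  # 26 of 73 plots coniferous-dominated by design (purity keeps most labels)
  expect_equal(sum(table(gt$plots$stratum)), 73)
})

test_that("zero-variance density moments give exactly k trees per plot", {
  p <- scene_params(n_plots = 4, density_moments = c(7, 0, 7, 7),
                    purity = 1, dead_fraction = 0, seed = 2)
  gt <- generate_forest(p)
  expect_equal(gt$plots$nt, rep(7L, 4))
  expect_equal(as.integer(table(gt$trees$plot_id)), rep(7L, 4))
})

test_that("per-plot counts respect the configured bounds for every seed", {
  for (seed in 1:8) {
    p <- scene_params(n_plots = 20, density_moments = c(10, 8, 3, 25),
                      seed = seed)
    gt <- generate_forest(p)
    counts <- as.integer(table(factor(gt$trees$plot_id, levels = 1:20)))
    expect_true(all(counts >= 3 & counts <= 25))
  }
})

test_that("truncated-normal count sampler matches its analytic moments", {
  # Monte-Carlo check: mean of nt over 2000 generated plots must lie within
  # 3 standard errors of the closed-form truncated-normal mean at the default
  # moments (27, 20, 4, 110). Only ground truth is generated (no rendering).
  p <- scene_params(n_plots = 2000, dead_fraction = 0, seed = 5)
  counts <- generate_forest(p)$plots$nt
  mu <- oracle_truncnorm_mean(27, 20, 4, 110)
  sdv <- oracle_truncnorm_sd(27, 20, 4, 110)
  se <- sdv / sqrt(2000)
  expect_lt(abs(mean(counts) - mu), 3 * se + 0.5)  # +0.5 for integer rounding
  expect_lt(abs(sd(counts) - sdv), 3 * se + 0.5)
})

test_that("generation is deterministic in the seed", {
  a <- generate_forest(scene_params(n_plots = 6, seed = 9))
  b <- generate_forest(scene_params(n_plots = 6, seed = 9))
  expect_identical(a, b)
  c <- generate_forest(scene_params(n_plots = 6, seed = 10))
  expect_false(identical(a$trees$x, c$trees$x))
})

test_that("conifer crown diameters stay within the stated range", {
  gt <- generate_forest(scene_params(seed = 3))
  con <- gt$trees[gt$trees$stratum == "coniferous", ]
  expect_true(all(con$crown_ns >= 1.38 & con$crown_ns <= 6.61))
  expect_true(all(con$crown_ew >= 1.38 & con$crown_ew <= 6.61))
  expect_true(all(gt$trees$crown_ns > 0 & gt$trees$crown_ew > 0))
})

test_that("a single live conifer renders as one strict PAN maximum near the stem", {
  p <- separated_conifer_params(seed = 4, n_plots = 1, k = 1)
  sc <- simulate_scene(p)
  expect_equal(nrow(sc$trees), 1)
  pts <- local_maxima(sc$pan, 3)
  # background is one flat plateau (one point); the crown apex is the other
  expect_lte(nrow(pts), 2)
  d <- sqrt((pts$x - sc$trees$x)^2 + (pts$y - sc$trees$y)^2)
  near <- which(d < max(sc$trees$crown_ew, sc$trees$crown_ns) / 4)
  expect_length(near, 1)
  expect_equal(max(sc$pan$values),
               raster_value_at(sc$pan, pts$x[near], pts$y[near]))
})

test_that("background-only and dead-tree scenes have NDVI below 0.1", {
  p0 <- scene_params(n_plots = 1, density_moments = c(1, 0, 1, 1),
                     noise_sd = 0, road_fraction = 0.2, seed = 6)
  gt <- generate_forest(p0)
  sc <- render_scene(gt$trees[0, ], gt$plots, p0)   # zero trees
  nd <- compute_ndvi(sc$red, sc$nir)
  expect_true(all(nd$values < 0.1))

  # one dead conifer: a PAN peak exists but its NDVI stays below 0.1
  pd <- separated_conifer_params(seed = 7, n_plots = 1, k = 1)
  gtd <- generate_forest(pd)
  gtd$trees$alive <- FALSE
  scd <- render_scene(gtd$trees, gtd$plots, pd)
  ndd <- compute_ndvi(scd$red, scd$nir)
  expect_true(all(ndd$values < 0.1))
  expect_gt(max(scd$pan$values), 0.2)  # the dead crown is still bright in PAN
})

test_that("scenes round-trip through write_scene/read_scene", {
  p <- scene_params(n_plots = 4, seed = 8)
  sc <- simulate_scene(p)
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  sc2 <- read_scene(dir)
  expect_equal(sc2$pan$values, sc$pan$values, tolerance = 1e-9)
  expect_equal(sc2$red$values, sc$red$values, tolerance = 1e-9)
  expect_equal(sc2$nir$values, sc$nir$values, tolerance = 1e-9)
  expect_equal(sc2$trees$x, sc$trees$x)
  expect_equal(sc2$trees$stratum, sc$trees$stratum)
  expect_equal(sc2$plots$nt, sc$plots$nt)
  expect_equal(sc2$params$density_moments, sc$params$density_moments)
  # CSV plot table has one row per plot with the stated columns
  tab <- read.csv(file.path(dir, "plots.csv"))
  expect_equal(nrow(tab), 4)
  expect_named(tab, c("plot_id", "stratum", "nt"))
})

test_that("an empty tree list writes a valid empty GeoJSON collection", {
  p <- scene_params(n_plots = 1, density_moments = c(1, 0, 1, 1),
                    noise_sd = 0, seed = 1)
  gt <- generate_forest(p)
  sc <- render_scene(gt$trees[0, ], gt$plots, p)
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  fc <- jsonlite::read_json(file.path(dir, "trees.geojson"))
  expect_equal(fc$type, "FeatureCollection")
  expect_length(fc$features, 0)
  expect_equal(nrow(read_scene(dir)$trees), 0)
})

test_that("undersized extents are rejected with a sizing error", {
  expect_error(scene_params(n_plots = 73, extent_m = c(48, 48)),
               "room for")
  expect_error(scene_params(density_moments = c(5, 2, 10, 20)), "min <= mean")
  expect_error(scene_params(pan_pixel_m = 0.7), "divide")
})
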