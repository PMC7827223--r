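test_that("connected components follow the 8-connectivity convention", {
  expect_equal(nrow(label_bushes(matrix(0, 5, 5))), 0)

  m <- matrix(0, 5, 5); m[1, 1] <- 1; m[2, 2] <- 1   # diagonal touch
  expect_equal(nrow(label_bushes(m)), 1)

  expect_error(label_bushes(matrix(c(0, 2), 2, 2)), "binary")
})

test_that("component labeling matches a flood-fill oracle on random masks", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(runif(64 * 64) < 0.35, 64, 64)
    b <- label_bushes(m)
    oracle <- flood_fill_label(m)
    expect_equal(nrow(b), max(oracle))
    expect_equal(sort(b$pixel_count), sort(tabulate(oracle[oracle > 0])))
    # identical partitions, not just identical counts
    lab <- attr(b, "labels")
    expect_equal(length(unique(paste(lab[m], oracle[m]))), max(oracle))
  }
})

test_that("class areas convert pixels to m2 and percentages correctly", {
  full <- matrix(TRUE, 10, 10)
  empty <- matrix(FALSE, 10, 10)
  masks <- list(blueberry = empty, tree = empty, yellow_bush = empty,
                soil = full, water = empty, dead_tree = empty)
  ca <- compute_class_areas(masks, 0.05)
  expect_equal(ca$pct_site[ca$class == "soil"], 100)

  masks$soil <- empty
  masks$blueberry <- matrix(FALSE, 10, 10); masks$blueberry[1, 1:4] <- TRUE
  ca <- compute_class_areas(masks, 0.05)
  expect_equal(ca$area_m2[ca$class == "blueberry"], 4 * 0.0025)
  expect_equal(ca$pct_living_veg[ca$class == "blueberry"], 100)

  bad <- masks; bad$tree <- bad$blueberry
  expect_error(compute_class_areas(bad, 0.05), "mutually exclusive")
})

test_that("class areas on a generated scene equal generator truth and conserve pixels", {
  sc <- small_scene(1)
  ca <- compute_class_areas(sc$masks, sc$pixel_size_m)
  expect_equal(setNames(as.numeric(ca$pixels), ca$class), sc$truth$class_px)
  expect_equal(sum(ca$pixels), length(sc$dem))  # soil is the remainder
})

test_that("bush heights use the nearest ground point with clamping and missingness", {
  mask <- matrix(FALSE, 10, 10); mask[3:4, 3:4] <- TRUE
  b <- label_bushes(mask)
  dem <- matrix(1.2, 10, 10)
  gp <- data.frame(x_px = 1, y_px = 1, elevation_m = 0.4)
  expect_equal(compute_bush_heights(dem, b, gp, "max")$height_m, 0.8)
  expect_equal(compute_bush_heights(dem, b, gp, "median")$height_m, 0.8)

  dem[3, 3] <- 4; dem[3, 4] <- 0.5; dem[4, 3] <- 0.5; dem[4, 4] <- 0.5
  gp0 <- data.frame(x_px = 1, y_px = 1, elevation_m = 0)
  expect_equal(compute_bush_heights(dem, b, gp0, "max")$height_m, 4)
  expect_equal(compute_bush_heights(dem, b, gp0, "median")$height_m, 0.5)

  gp_hi <- data.frame(x_px = 1, y_px = 1, elevation_m = 9)
  h <- compute_bush_heights(dem, b, gp_hi, "max")
  expect_equal(h$height_m, 0)
  expect_true(h$clamped)

  h2 <- compute_bush_heights(dem, b, gp0, "max", pixel_size_m = 1,
                             max_ground_dist_m = 0.5)
  expect_true(is.na(h2$height_m))
})

test_that("inventory summary reproduces ratio arithmetic and undefined cases", {
  s <- summarize_inventory(site_area_ha = 11.64,
                           total_bush_area_m2 = 1331.42, bush_count = 375)
  expect_equal(s$rounded$mean_area_per_bush_m2, 3.55)
  s6 <- summarize_inventory(site_area_ha = 15.14,
                            total_bush_area_m2 = 278.07, bush_count = 235)
  expect_equal(s6$rounded$mean_area_per_bush_m2, 1.18)

  s0 <- summarize_inventory(site_area_ha = 1, total_bush_area_m2 = 0,
                            bush_count = 0)
  expect_true(is.na(s0$mean_area_per_bush_m2))
})

test_that("height histogram uses half-open bins with overflow", {
  h <- bin_distribution(c(0.2, 0.4), seq(0, 3.5, 0.5))
  expect_equal(h$count[1], 2)

  h2 <- bin_distribution(0.5, seq(0, 3.5, 0.5))
  expect_equal(h2$count[2], 1)   # 0.5 belongs to [0.5, 1.0)

  h3 <- bin_distribution(4.2, seq(0, 3.5, 0.5))
  expect_equal(h3$count[length(h3$count)], 1)

  set.seed(4)
  v <- runif(200, 0, 5)
  hh <- bin_distribution(v, seq(0, 3.5, 0.5))
  edges <- seq(0, 3.5, 0.5)
  oracle <- vapply(seq_along(edges), function(i) {
    if (i < length(edges)) sum(v >= edges[i] & v < edges[i + 1])
    else sum(v >= edges[i])
  }, 0)
  expect_equal(hh$count, as.integer(oracle))
  expect_equal(sum(hh$count), length(v))
})

test_that("bush count recovery matches the generator's merged-component count", {
  for (seed in 1:3) {
    sc <- small_scene(seed)
    b <- label_bushes(sc$masks$blueberry)
    expect_equal(nrow(b), sc$truth$merged_component_count)
  }
})
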