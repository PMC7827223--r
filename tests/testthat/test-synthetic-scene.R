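test_that("point pattern generation handles empty, degenerate and seeded cases", {
  cfg0 <- small_scene_config(seed = 3)
  cfg0$bush_count <- 0L
  expect_equal(nrow(generate_point_pattern(cfg0)$points), 0)

  cfg1 <- small_scene_config(seed = 5)
  cfg1$bush_count <- 10L
  cfg1$cluster_process <- list(parent_count = 1L, cluster_sigma_m = 1e-9,
                               background_fraction = 0)
  pp <- generate_point_pattern(cfg1)
  expect_equal(nrow(pp$points), 10)
  expect_lt(max(dist(pp$points)), 1e-6)

  p1 <- generate_point_pattern(small_scene_config(seed = 7))
  p2 <- generate_point_pattern(small_scene_config(seed = 7))
  expect_identical(p1$points, p2$points)

  ext <- p1$extent
  expect_true(all(p1$points$x_m >= ext[["xmin"]] &
                  p1$points$x_m <= ext[["xmax"]] &
                  p1$points$y_m >= ext[["ymin"]] &
                  p1$points$y_m <= ext[["ymax"]]))
})

test_that("invalid configurations are rejected", {
  expect_error(scene_config(class_fractions = c(blueberry = 0.6, water = 0.6)),
               "sum")
  expect_error(scene_config(bush_radius_range_px = c(0, 10)), "radius")
  expect_error(scene_config(width_px = 100, height_px = 100,
                            bush_radius_range_px = c(20, 80)), "radius")
  expect_error(generate_scene(scene_config(width_px = 30, height_px = 30,
                                           bush_radius_range_px = c(14, 14),
                                           bush_count = 2)),
               "frame too small")
})

test_that("identical config and seed give a bit-identical scene", {
  s1 <- generate_scene(small_scene_config(seed = 21))
  s2 <- generate_scene(small_scene_config(seed = 21))
  expect_identical(s1$rgb, s2$rgb)
  expect_identical(s1$dem, s2$dem)
  expect_identical(s1$masks, s2$masks)
  expect_identical(s1$ground_points, s2$ground_points)
})

test_that("scene respects class structure and generator bookkeeping", {
  sc <- small_scene(1)
  dims <- dim(sc$dem)
  for (m in sc$masks) expect_identical(dim(m), dims)
  # masks mutually exclusive
  total_labeled <- Reduce(`+`, lapply(sc$masks, function(m) m + 0L))
  expect_true(all(total_labeled <= 1L))
  # recorded class pixel counts equal direct pixel counting
  expect_identical(vapply(sc$masks, sum, 0), sc$truth$class_px)
  # realized blueberry fraction within half a percentage point of target
  expect_lt(abs(mean(sc$masks$blueberry) - 0.012), 0.005)
  # non-merged planted bushes keep their equivalent radius in range
  if (sc$truth$overlap_accepted == 0L) {
    # half-pixel slack: the integer pixel quota is rounded per bush
    expect_true(all(sc$truth$planted$radius_px >= 10 - 0.5 &
                    sc$truth$planted$radius_px <= 25 + 0.5))
  }
})

test_that("a single forced-radius bush covers ~ pi r^2 pixels", {
  r <- 12
  cfg <- scene_config(width_px = 200L, height_px = 200L, bush_count = 1L,
                      bush_radius_range_px = c(r, r),
                      class_fractions = c(blueberry = pi * r^2 / 200^2),
                      seed = 2)
  sc <- generate_scene(cfg)
  b <- label_bushes(sc$masks$blueberry)
  expect_equal(nrow(b), 1)
  expect_equal(b$pixel_count, round(pi * r^2))
})

test_that("true bush heights are recoverable from the DEM", {
  sc <- small_scene(2)
  b <- label_bushes(sc$masks$blueberry, sc$pixel_size_m)
  hb <- compute_bush_heights(sc$dem, b, sc$ground_points, "max",
                             pixel_size_m = sc$pixel_size_m)
  tr <- sc$truth$planted
  m <- vapply(seq_len(nrow(b)), function(i)
    which.min((tr$row - b$centroid_row[i])^2 +
              (tr$col - b$centroid_col[i])^2), 1L)
  err <- abs(hb$height_m - tr$height_m[m])
  expect_lte(median(err), 3 * sc$truth$config$height_model$hassock_noise_sd_m)
})
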