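quick_cfg <- function(...) train_config(epochs = 40L, conv_filters = 6L,
                                        hidden_units = 8L, input_px = 16L,
                                        swa_fraction = 0, ...)

test_that("a trivially separable solid-colour dataset is learned quickly", {
  train <- make_solid_patch_set(6, site_id = "A", seed = 1)
  val <- make_solid_patch_set(3, site_id = "B", seed = 2)
  m <- train_classifier(train, val, quick_cfg(seed = 3))
  pr <- blueberrymap:::predict_probs(m, val$images)
  truth <- val$meta$blueberry_fraction > 0
  pos <- pr[, "blueberry"] >= 0.5
  expect_equal(sum(pos & truth) / sum(truth), 1)      # blueberry TPR 1.0
  expect_true(mean((pos == truth)) > 0.9)
})

test_that("overlapping sites across splits raise a data-leakage error", {
  a <- make_solid_patch_set(2, site_id = "A")
  expect_error(train_classifier(a, a, quick_cfg()), "leakage")
})

test_that("frozen mode leaves the convolutional bank at its seeded init", {
  t1 <- make_solid_patch_set(3, site_id = "A", seed = 1)
  t2 <- make_solid_patch_set(3, site_id = "C", seed = 9)
  m1 <- train_classifier(t1, NULL, quick_cfg(seed = 4, weights_mode = "frozen"))
  m2 <- train_classifier(t2, NULL, quick_cfg(seed = 4, weights_mode = "frozen"))
  expect_identical(m1$par$Fc, m2$par$Fc)     # untouched random features
  expect_false(identical(m1$par$W2, m2$par$W2))
  m3 <- train_classifier(t1, NULL, quick_cfg(seed = 4))
  expect_false(identical(m1$par$Fc, m3$par$Fc))
})

test_that("training is deterministic for identical data, config and seed", {
  tr <- make_solid_patch_set(3, site_id = "A", seed = 1)
  m1 <- train_classifier(tr, NULL, quick_cfg(seed = 7))
  m2 <- train_classifier(tr, NULL, quick_cfg(seed = 7))
  expect_identical(m1$log$loss, m2$log$loss)
  expect_identical(m1$par, m2$par)
})

test_that("prediction masks paint exactly the positive patch footprints", {
  sc <- small_scene(1)
  tiles <- tile_orthomosaic(sc, 100L)

  never <- stub_model(-10, side_px = 100L)
  pm0 <- predict_patches(never, tiles, scene_dim = dim(sc$dem))
  expect_equal(sum(pm0$mask), 0)

  always <- stub_model(10, side_px = 100L)
  pm1 <- predict_patches(always, tiles, scene_dim = dim(sc$dem))
  expect_equal(sum(pm1$mask), 100^2 * length(tiles))

  expect_error(predict_patches(stub_model(0, side_px = 50L), tiles), "side")
})

test_that("refinement spawns 4x4 sub-patches and stays inside the coarse mask", {
  sc <- small_scene(1)
  tiles <- tile_orthomosaic(sc, 100L)
  always <- stub_model(10, side_px = 100L)
  coarse <- predict_patches(always, tiles, scene_dim = dim(sc$dem))

  refined <- refine_predictions(always, coarse, tiles)
  expect_equal(nrow(refined$pred), 16 * length(tiles))
  expect_true(all(refined$pred$side_px == 25))
  expect_identical(refined$mask, coarse$mask)   # all sub-patches positive

  never <- stub_model(-10, side_px = 100L)
  r0 <- refine_predictions(never, coarse, tiles)
  expect_equal(sum(r0$mask), 0)

  # subset invariant under a real trained model
  tr <- make_solid_patch_set(4, site_id = "A", seed = 1)
  m <- train_classifier(tr, NULL, quick_cfg(seed = 5))
  m$side_px <- 100L
  pm <- predict_patches(m, tiles, scene_dim = dim(sc$dem))
  rf <- refine_predictions(m, pm, tiles)
  expect_true(all(pm$mask[rf$mask]))
})

test_that("leave-one-mosaic-out refuses fewer than three scenes", {
  sc <- small_scene(1)
  expect_error(leave_one_mosaic_out(list(sc, sc), train_config()), ">= 3")
})
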