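test_that("tiling drops partial strips and labels tiles from the masks", {
  sc <- small_scene(1)   # 360 x 360
  ps <- tile_orthomosaic(sc, side_px = 100L)
  expect_equal(length(ps), 9)       # 3 x 3 full tiles, trailing 60 px dropped
  expect_true(all(ps$meta$row0 %% 100 == 0))

  # per-patch labels and fractions equal direct pixel counting
  for (i in seq_len(length(ps))) {
    rs <- (ps$meta$row0[i] + 1):(ps$meta$row0[i] + 100)
    cs <- (ps$meta$col0[i] + 1):(ps$meta$col0[i] + 100)
    frac <- sum(sc$masks$blueberry[rs, cs]) / 1e4
    expect_equal(ps$meta$blueberry_fraction[i], frac)
    want <- SCENE_CLASSES[vapply(SCENE_CLASSES, function(cl)
      any(sc$masks[[cl]][rs, cs]), TRUE)]
    expect_setequal(ps$meta$labels[[i]], want)
    expect_equal((ps$meta$blueberry_fraction[i] > 0),
                 "blueberry" %in% ps$meta$labels[[i]])
  }

  tiny <- sc; tiny$rgb <- sc$rgb[1:50, 1:50, , drop = FALSE]
  expect_error(tile_orthomosaic(tiny, 100L), "smaller")
})

test_that("augmentations preserve geometry contracts and are seeded", {
  img <- small_scene(1)$rgb[1:60, 1:60, ] * 1.0

  expect_equal(augment_patch(augment_patch(img, "flip_ud", 1), "flip_ud", 1),
               img)
  expect_equal(augment_patch(augment_patch(img, "flip_lr", 1), "flip_lr", 1),
               img)
  # zero-range rotation is the identity
  expect_equal(augment_patch(img, "rotate", 3, rotate_range_deg = 0), img,
               tolerance = 1e-12)

  for (tr in PATCH_TRANSFORMS) {
    a1 <- augment_patch(img, tr, seed = 42)
    a2 <- augment_patch(img, tr, seed = 42)
    expect_identical(a1, a2)
    expect_identical(dim(a1), dim(img))
    expect_true(all(a1 >= 0 & a1 <= 255))
  }
  expect_error(augment_patch(img, "zoom", 1), "unknown transform")
})

test_that("balancing upsamples blueberry 1 + 12 and halves soil-only patches", {
  pal <- default_palette()
  mk <- function(cls, n, frac) {
    metas <- lapply(seq_len(n), function(i) {
      m <- data.frame(patch_id = NA_integer_, site_id = "t", row0 = 0L,
                      col0 = 0L, side_px = 40L, blueberry_fraction = frac)
      m$labels <- I(list(cls))
      m
    })
    blueberrymap:::new_patch_set(do.call(rbind, metas),
                                 replicate(n, solid_patch(pal[[cls[1]]]),
                                           simplify = FALSE))
  }
  ps <- blueberrymap:::bind_patches(mk("blueberry", 10, 0.4),
                                    mk("soil", 100, 0),
                                    mk("tree", 7, 0))
  ps$meta$patch_id <- seq_len(nrow(ps$meta))
  cfg <- train_config(seed = 5)
  out <- balance_dataset(ps, cfg)
  expect_equal(sum(out$meta$blueberry_fraction > 0), 130)   # 10 x (1 + 12)
  soil_only <- vapply(out$meta$labels, identical, TRUE, "soil")
  expect_equal(sum(soil_only), 50)
  expect_equal(sum(vapply(out$meta$labels, identical, TRUE, "tree")), 7)

  expect_error(balance_dataset(ps, cfg, split = "test"), "training split")
  expect_warning(balance_dataset(mk("soil", 10, 0), cfg), "no blueberry")
})
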