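test_that("region sampling covers every component and labels match flood fill", {
  m <- matrix(FALSE, 20, 20); m[5, 7] <- TRUE
  s <- sample_regions(m, spacing_px = 6)
  expect_equal(nrow(s), 1)
  expect_equal(c(s$row, s$col), c(5, 7))

  full <- matrix(TRUE, 21, 17)
  expect_equal(nrow(sample_regions(full, 5)), ceiling(21 / 5) * ceiling(17 / 5))

  expect_equal(nrow(sample_regions(matrix(FALSE, 10, 10), 3)), 0)

  set.seed(8)
  blobs <- matrix(runif(50 * 50) < 0.3, 50, 50)
  s2 <- sample_regions(blobs, 4)
  oracle <- flood_fill_label(blobs)
  expect_true(all(oracle[cbind(s2$row, s2$col)] > 0))
  # consistent relabeling between implementation and oracle
  key <- paste(s2$region_id, oracle[cbind(s2$row, s2$col)])
  expect_equal(length(unique(key)), length(unique(s2$region_id)))
  # every oracle component is represented
  expect_equal(length(unique(s2$region_id)), max(oracle))
})

test_that("merge radii follow the touching-disk convention on known configurations", {
  s <- data.frame(row = c(0, 0), col = c(0, 10), region_id = c(1, 2))
  ph <- h0_persistence(s)
  expect_equal(ph$merge_events$radius, 5)
  expect_true(all(ph$fused_fraction_radii == 5))

  s3 <- data.frame(row = c(0, 0, 0), col = c(0, 10, 30), region_id = 1:3)
  ph3 <- h0_persistence(s3)
  expect_equal(ph3$merge_events$radius, c(5, 10))
  expect_equal(unname(ph3$fused_fraction_radii[["0.5"]]), 5)
  expect_equal(unname(ph3$fused_fraction_radii[["0.9"]]), 10)

  phd <- h0_persistence(s3, radius_convention = "distance")
  expect_equal(phd$merge_events$radius, c(10, 20))

  s1 <- data.frame(row = c(0, 1), col = c(0, 0), region_id = c(1, 1))
  ph1 <- h0_persistence(s1)
  expect_equal(nrow(ph1$merge_events), 0)
  expect_true(all(is.na(ph1$fused_fraction_radii)))
})

test_that("intra-region merges are discarded and event count is R - 1", {
  set.seed(2)
  s <- data.frame(row = c(rnorm(8, 0, 1), rnorm(8, 30, 1), rnorm(8, 60, 1)),
                  col = rnorm(24, 0, 1),
                  region_id = rep(1:3, each = 8))
  ph <- h0_persistence(s)
  expect_equal(nrow(ph$merge_events), 2)
  expect_true(all(diff(ph$merge_events$radius) >= 0))
})

test_that("persistence equals the brute-force pair oracle on random instances", {
  for (seed in 1:25) {
    set.seed(seed)
    R <- sample(3:8, 1)
    s <- do.call(rbind, lapply(seq_len(R), function(r) {
      k <- sample(2:6, 1)
      data.frame(row = rnorm(k, runif(1, 0, 100), 2),
                 col = rnorm(k, runif(1, 0, 100), 2),
                 region_id = r)
    }))
    ph <- h0_persistence(s)
    expect_equal(sort(ph$merge_events$radius), brute_force_h0(s),
                 tolerance = 1e-10)
  }
})

test_that("densifying samples within fixed regions cannot increase merge radii", {
  for (seed in 1:8) {
    set.seed(seed)
    R <- 4
    centers <- cbind(runif(R, 0, 80), runif(R, 0, 80))
    coarse <- do.call(rbind, lapply(seq_len(R), function(r)
      data.frame(row = rnorm(3, centers[r, 1], 2),
                 col = rnorm(3, centers[r, 2], 2), region_id = r)))
    extra <- do.call(rbind, lapply(seq_len(R), function(r)
      data.frame(row = rnorm(4, centers[r, 1], 2),
                 col = rnorm(4, centers[r, 2], 2), region_id = r)))
    r_coarse <- sort(h0_persistence(coarse)$merge_events$radius)
    r_dense <- sort(h0_persistence(rbind(coarse, extra))$merge_events$radius)
    expect_true(all(r_dense <= r_coarse + 1e-10))
  }
})

test_that("point clustering and persistence connectivity agree across modules", {
  set.seed(13)
  n <- 25
  xy <- cbind(runif(n, 0, 40), runif(n, 0, 40))
  thr <- 5
  p <- point_pattern(xy[, 1], xy[, 2],
                     extent = c(xmin = 0, xmax = 40, ymin = 0, ymax = 40))
  memb <- cluster_points(p, thr)$membership
  # centroids as one region each; count merges with radius <= thr/2
  s <- data.frame(row = xy[, 2], col = xy[, 1], region_id = seq_len(n))
  ph <- h0_persistence(s)
  n_components <- n - sum(ph$merge_events$radius <= thr / 2)
  expect_equal(length(unique(memb)), n_components)
})
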