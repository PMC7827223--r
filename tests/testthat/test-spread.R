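test_that("distance clustering is transitive single linkage with inclusive threshold", {
  p <- point_pattern(c(0, 0), c(0, 2.5), extent = c(xmin = 0, xmax = 10,
                                                    ymin = 0, ymax = 10))
  ct <- cluster_points(p, 3)
  expect_equal(ct$max_cluster_size, 2)

  p3 <- point_pattern(c(0, 0, 0), c(0, 2.5, 5), extent = c(xmin = 0, xmax = 10,
                                                           ymin = 0, ymax = 10))
  ct3 <- cluster_points(p3, 3)
  expect_equal(ct3$max_cluster_size, 3)           # chained: 0-2.5-5
  expect_equal(ct3$pct_grouped_3plus, 100)

  pe <- point_pattern(c(0, 3), c(0, 0), extent = c(xmin = 0, xmax = 10,
                                                   ymin = 0, ymax = 10))
  expect_equal(cluster_points(pe, 3)$max_cluster_size, 2)  # d == threshold

  pf <- point_pattern(c(0, 5, 10), c(0, 5, 0), extent = c(xmin = 0, xmax = 20,
                                                          ymin = 0, ymax = 20))
  cf <- cluster_points(pf, 3)
  expect_equal(cf$n_singletons, 3)
  expect_equal(cf$pct_grouped_3plus, 0)
})

test_that("clustering equals a union-find oracle on random patterns", {
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(5:40, 1)
    xy <- cbind(runif(n, 0, 30), runif(n, 0, 30))
    thr <- runif(1, 1, 8)
    p <- point_pattern(xy[, 1], xy[, 2],
                       extent = c(xmin = 0, xmax = 30, ymin = 0, ymax = 30))
    got <- cluster_points(p, thr)$membership
    want <- union_find_clusters(xy, thr)
    # same partition up to relabeling
    expect_equal(length(unique(paste(got, want))), length(unique(want)))
  }
})

test_that("quartic kernel density has compact support and integrates to the count", {
  ext <- c(xmin = 0, xmax = 60, ymin = 0, ymax = 60)
  p <- point_pattern(30, 30, extent = ext)
  kd <- kernel_density(p, cell_size_m = 0.5, radius_m = 6)
  expect_equal(which.max(kd$values),
               which(kd$values == max(kd$values))[1])
  # zero where farther than the radius from the single point
  expect_equal(kd$values[1, 1], 0)
  expect_equal(sum(kd$values) * 0.5^2, 1, tolerance = 0.01)

  set.seed(9)
  pm <- point_pattern(runif(7, 15, 45), runif(7, 15, 45), extent = ext)
  kdm <- kernel_density(pm, cell_size_m = 0.5, radius_m = 6)
  expect_equal(sum(kdm$values) * 0.25, 7, tolerance = 0.07)

  expect_error(kernel_density(p, 2, 1), "radius")
})

test_that("Gi* matches the direct formula and behaves at degenerate inputs", {
  set.seed(11)
  f <- data.frame(x_m = runif(10, 0, 50), y_m = runif(10, 0, 50),
                  count = rpois(10, 4))
  g <- gi_star(f, neighborhood_m = 15)
  expect_equal(g$z, gi_star_direct(f, 15), tolerance = 1e-12)

  # equal counts: zero variance, all z zero, bin none
  f0 <- data.frame(x_m = 1:5, y_m = rep(0, 5), count = rep(3, 5))
  g0 <- gi_star(f0, 2)
  expect_true(all(g0$z == 0) && all(g0$confidence == "none"))

  # one large count among zeros is the most positive feature
  f1 <- data.frame(x_m = seq(0, 40, 10), y_m = rep(0, 5),
                   count = c(0, 0, 50, 0, 0))
  g1 <- gi_star(f1, 11)
  expect_equal(g1$z[3], max(g1$z))
  expect_gt(g1$z[3], 0)

  expect_error(gi_star(f1[1, ], 5), "at least 2")
})

test_that("Gi* z-scores sum to ~0 when all features share the neighbourhood", {
  set.seed(3)
  n <- 12
  f <- data.frame(x_m = runif(n, 0, 5), y_m = runif(n, 0, 5),
                  count = rpois(n, 6))
  g <- gi_star(f, neighborhood_m = 100)   # complete graph: equal weights
  expect_lt(abs(sum(g$z)), 1e-9 * n)
})

test_that("collect_events aggregates cluster counts that sum to the point count", {
  sc <- small_scene(1)
  pp <- scene_centroids(sc)
  ct <- cluster_points(pp, 6)
  ev <- collect_events(pp, ct)
  expect_equal(sum(ev$count), nrow(pp$points))
  expect_equal(nrow(ev), length(ct$sizes))
})
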