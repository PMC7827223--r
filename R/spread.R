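#' Distance clustering of bush points
#'
#' Single-linkage (transitive) grouping: two bushes share a cluster iff a
#' chain of pairwise distances, each at most `threshold_m`, connects them —
#' the behaviour of snapping points within a tolerance and then collecting
#' coincident events. Implemented as connected components of the
#' distance-threshold graph.
#'
#' @param pattern a [point_pattern()].
#' @param threshold_m grouping distance in metres (3 and 6 m are the survey
#'   defaults).
#' @return list of class `cluster_table`: `membership` (integer per point),
#'   `sizes`, `pct_grouped_3plus` (percent of bushes in clusters of size
#'   >= 3), `n_singletons`, `max_cluster_size`, `threshold_m`.
#' @export
cluster_points <- function(pattern, threshold_m) {
  if (threshold_m <= 0) stop_bbm("threshold_m must be > 0")
  pts <- pattern$points
  n <- nrow(pts)
  if (n == 0L) {
    res <- list(membership = integer(0), sizes = integer(0),
                pct_grouped_3plus = NA_real_, n_singletons = 0L,
                max_cluster_size = 0L, threshold_m = threshold_m)
    class(res) <- "cluster_table"
    return(res)
  }
  if (n == 1L) {
    membership <- 1L
  } else {
    d <- as.matrix(dist(pts))
    adj <- d <= threshold_m
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    membership <- as.integer(igraph::components(g)$membership)
  }
  sizes <- tabulate(membership)
  res <- list(membership = membership,
              sizes = sizes,
              pct_grouped_3plus = 100 * sum(sizes[membership] >= 3) / n,
              n_singletons = sum(sizes == 1L),
              max_cluster_size = max(sizes),
              threshold_m = threshold_m)
  class(res) <- "cluster_table"
  res
}

#' @export
print.cluster_table <- function(x, ...) {
  cat(sprintf(
    "cluster_table @ %.1f m: %d points, %.2f%% grouped >=3, %d singletons, largest %d\n",
    x$threshold_m, length(x$membership), x$pct_grouped_3plus,
    x$n_singletons, x$max_cluster_size))
  invisible(x)
}

#' Quartic kernel density surface of bush points
#'
#' Magnitude-per-unit-area surface: each point contributes the compactly
#' supported quartic kernel K(d) = 3/(pi r^2) (1 - d^2/r^2)^2 for d < r.
#' The kernel integrates to one, so the raster integrates to the point
#' count (away from edges). Units are points per m2.
#'
#' @param pattern a [point_pattern()].
#' @param cell_size_m output cell size, metres.
#' @param radius_m kernel search radius, metres.
#' @return list of class `density_raster`: `values` (matrix, rows = north
#'   to south), `cell_size_m`, `radius_m`, `extent`.
#' @export
kernel_density <- function(pattern, cell_size_m, radius_m) {
  if (!(radius_m > cell_size_m && cell_size_m > 0))
    stop_bbm("need radius_m > cell_size_m > 0")
  ext <- pattern$extent
  nx <- max(1L, ceiling((ext[["xmax"]] - ext[["xmin"]]) / cell_size_m))
  ny <- max(1L, ceiling((ext[["ymax"]] - ext[["ymin"]]) / cell_size_m))
  xc <- ext[["xmin"]] + (seq_len(nx) - 0.5) * cell_size_m
  yc <- ext[["ymax"]] - (seq_len(ny) - 0.5) * cell_size_m
  vals <- matrix(0, ny, nx)
  pts <- pattern$points
  for (k in seq_len(nrow(pts))) {
    jx <- which(abs(xc - pts$x_m[k]) < radius_m)
    jy <- which(abs(yc - pts$y_m[k]) < radius_m)
    if (!length(jx) || !length(jy)) next
    d2 <- outer((yc[jy] - pts$y_m[k])^2, (xc[jx] - pts$x_m[k])^2, `+`)
    w <- 3 / (pi * radius_m^2) * (1 - d2 / radius_m^2)^2
    w[d2 >= radius_m^2] <- 0
    vals[jy, jx] <- vals[jy, jx] + w
  }
  structure(list(values = vals, cell_size_m = cell_size_m,
                 radius_m = radius_m, extent = ext),
            class = "density_raster")
}

#' Getis-Ord Gi* hotspot statistic
#'
#' Classic Gi* z-score with fixed-distance binary weights (neighbours
#' within `neighborhood_m`, the feature itself included). Features whose
#' neighbourhood sum is significantly above (below) the global mean are
#' hot (cold) spots; confidence bins follow the two-sided normal
#' thresholds 1.645 / 1.960 / 2.576 for 90 / 95 / 99%.
#'
#' @param features data.frame with `x_m`, `y_m`, `count` (event counts,
#'   e.g. bushes per collected cluster).
#' @param neighborhood_m fixed distance band, metres.
#' @return data.frame `features` plus `z` and `confidence` in
#'   `c("none","90","95","99","cold90","cold95","cold99")`.
#' @export
gi_star <- function(features, neighborhood_m) {
  n <- nrow(features)
  if (n < 2L) stop_bbm("gi_star needs at least 2 features")
  if (any(features$count < 0)) stop_bbm("counts must be >= 0")
  x <- features$count
  xbar <- mean(x)
  s <- sqrt(sum(x^2) / n - xbar^2)
  d <- as.matrix(dist(features[, c("x_m", "y_m")]))
  w <- (d <= neighborhood_m) + 0   # includes self (diagonal is 0 distance)
  z <- numeric(n)
  if (s > 0) {
    for (i in seq_len(n)) {
      wi <- w[i, ]
      sw <- sum(wi)
      num <- sum(wi * x) - xbar * sw
      den <- s * sqrt((n * sum(wi^2) - sw^2) / (n - 1))
      z[i] <- if (den > 0) num / den else 0
    }
  }
  bins <- c(none = 0, `90` = 1.644854, `95` = 1.959964, `99` = 2.575829)
  lev <- vapply(z, function(zi) {
    b <- sum(abs(zi) >= bins[-1])
    if (b == 0) "none"
    else paste0(if (zi < 0) "cold" else "", names(bins)[b + 1])
  }, "")
  features$z <- z
  features$confidence <- lev
  features
}

#' Collect coincident cluster events for hotspot input
#'
#' Aggregates a clustered pattern into one feature per cluster located at
#' the cluster mean with the member count as its value, the standard input
#' layer for [gi_star()].
#'
#' @param pattern a [point_pattern()].
#' @param clusters a [cluster_points()] result on the same pattern.
#' @return data.frame `x_m`, `y_m`, `count`.
#' @export
collect_events <- function(pattern, clusters) {
  m <- clusters$membership
  stopifnot(length(m) == nrow(pattern$points))
  agg <- data.frame(
    x_m = tapply(pattern$points$x_m, m, mean),
    y_m = tapply(pattern$points$y_m, m, mean),
    count = as.integer(table(factor(m, levels = sort(unique(m))))))
  rownames(agg) <- NULL
  agg
}
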