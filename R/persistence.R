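#' Uniformly sample annotated regions for persistence analysis
#'
#' Discretises the annotated blueberry regions by keeping every
#' `spacing_px`-th pixel of a regular grid that falls inside the mask. Each
#' 8-connected component is one region; a component missed by the grid
#' contributes its pixel nearest to the component centroid so no region is
#' lost.
#'
#' @param mask binary matrix.
#' @param spacing_px grid spacing in pixels (>= 1).
#' @return data.frame `row`, `col`, `region_id`.
#' @export
sample_regions <- function(mask, spacing_px = 5L) {
  if (spacing_px < 1L) stop_bbm("spacing_px must be >= 1")
  mask <- as_logical_mask(mask)
  lab <- label_components8_cpp(mask)
  k <- max(lab)
  if (k == 0L)
    return(data.frame(row = integer(0), col = integer(0),
                      region_id = integer(0)))
  rows <- seq(1L, nrow(mask), by = spacing_px)
  cols <- seq(1L, ncol(mask), by = spacing_px)
  grid <- lab[rows, cols, drop = FALSE]
  keep <- which(grid > 0L, arr.ind = TRUE)
  out <- data.frame(row = rows[keep[, 1]], col = cols[keep[, 2]],
                    region_id = grid[keep])
  missing <- setdiff(seq_len(k), unique(out$region_id))
  for (id in missing) {
    idx <- which(lab == id)
    r <- (idx - 1L) %% nrow(mask) + 1L
    c <- (idx - 1L) %/% nrow(mask) + 1L
    j <- which.min((r - mean(r))^2 + (c - mean(c))^2)
    out <- rbind(out, data.frame(row = r[j], col = c[j], region_id = id))
  }
  out[order(out$region_id, out$row, out$col), , drop = FALSE]
}

#' 0-dimensional persistence of annotated regions
#'
#' Grows a disk of common radius around every sample point and records when
#' two *regions* first become connected; merges between samples of the same
#' region are artifacts of the discretisation and are discarded. Two disks
#' of radius r touch when the point distance is 2r, so with the default
#' `"half-distance"` convention an inter-region event between samples at
#' distance d is recorded at radius d/2 (`"distance"` records d). The
#' merge sequence is the single-linkage merge tree of the samples filtered
#' to region-level events; with R regions, exactly R - 1 events occur.
#'
#' The fused-fraction radius for fraction f is the smallest event radius at
#' which at least f of the R - 1 possible region merges have happened
#' (first crossing; ties resolved by the earlier event).
#'
#' @param samples data.frame from [sample_regions()] (`row`, `col`,
#'   `region_id`), or any point set with those columns; coordinates are in
#'   pixels unless `pixel_size_m` is given.
#' @param fractions fused fractions to report radii for.
#' @param radius_convention `"half-distance"` (touching disks) or
#'   `"distance"`.
#' @param pixel_size_m if non-NULL, radii are also reported in metres.
#' @return list of class `persistence_result`: `region_count`,
#'   `merge_events` (data.frame `radius`, `region_a`, `region_b`, ordered
#'   by radius), `fused_fraction_radii` (named numeric),
#'   `radius_convention`, and `merge_events_m` / `fused_fraction_radii_m`
#'   when `pixel_size_m` is given.
#' @export
h0_persistence <- function(samples,
                           fractions = c(0.01, 0.10, 0.50, 0.90),
                           radius_convention = c("half-distance", "distance"),
                           pixel_size_m = NULL) {
  radius_convention <- match.arg(radius_convention)
  regions <- unique(samples$region_id)
  R <- length(regions)
  if (R < 2L) {
    res <- list(region_count = R,
                merge_events = data.frame(radius = numeric(0),
                                          region_a = integer(0),
                                          region_b = integer(0)),
                fused_fraction_radii = setNames(rep(NA_real_,
                                                    length(fractions)),
                                                as.character(fractions)),
                radius_convention = radius_convention)
    class(res) <- "persistence_result"
    return(res)
  }
  n <- nrow(samples)
  hc <- hclust(dist(samples[, c("row", "col")]), method = "single")

  # replay the merge tree with a union-find over regions; a merge whose two
  # sides already share a region-component is an intra-region artifact
  parent <- seq_len(R)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  reg_of_cluster <- integer(n - 1L)        # representative region per node
  region_index <- match(samples$region_id, regions)
  events <- vector("list", R - 1L)
  ne <- 0L
  for (k in seq_len(n - 1L)) {
    side <- function(m) if (m < 0L) region_index[-m] else reg_of_cluster[m]
    ra <- side(hc$merge[k, 1]); rb <- side(hc$merge[k, 2])
    fa <- find(ra); fb <- find(rb)
    if (fa != fb) {
      ne <- ne + 1L
      r_ev <- if (radius_convention == "half-distance")
        hc$height[k] / 2 else hc$height[k]
      events[[ne]] <- data.frame(radius = r_ev,
                                 region_a = regions[fa],
                                 region_b = regions[fb])
      parent[fb] <- fa
    }
    reg_of_cluster[k] <- fa
  }
  ev <- do.call(rbind, events[seq_len(ne)])
  ev <- ev[order(ev$radius), , drop = FALSE]
  rownames(ev) <- NULL
  frac_done <- seq_len(nrow(ev)) / (R - 1L)
  ffr <- vapply(fractions, function(f) {
    i <- which(frac_done >= f)[1]
    if (is.na(i)) NA_real_ else ev$radius[i]
  }, 0)
  res <- list(region_count = R, merge_events = ev,
              fused_fraction_radii = setNames(ffr, as.character(fractions)),
              radius_convention = radius_convention)
  if (!is.null(pixel_size_m)) {
    res$merge_events_m <- transform(ev, radius = radius * pixel_size_m)
    res$fused_fraction_radii_m <- res$fused_fraction_radii * pixel_size_m
  }
  class(res) <- "persistence_result"
  res
}

#' @export
print.persistence_result <- function(x, ...) {
  cat(sprintf("persistence_result: %d regions, %d inter-region merges (%s)\n",
              x$region_count, nrow(x$merge_events), x$radius_convention))
  print(round(x$fused_fraction_radii, 2))
  invisible(x)
}
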