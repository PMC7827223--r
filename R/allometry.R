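#' Label blueberry bushes as connected components
#'
#' Annotation strokes that touch diagonally belong to one bush, so
#' components are extracted under 8-connectivity. Bushes drawn close
#' together in the mask merge into a single component, exactly as
#' PNG-layer-based counting behaves on real annotations.
#'
#' @param mask binary matrix (logical or 0/1).
#' @param pixel_size_m metres per pixel; used for `area_m2`.
#' @return data.frame with one row per component: `component_id`,
#'   `pixel_count`, `area_m2`, `centroid_row`, `centroid_col`. The integer
#'   label matrix is attached as attribute `"labels"`.
#' @export
label_bushes <- function(mask, pixel_size_m = 1) {
  mask <- as_logical_mask(mask)
  lab <- label_components8_cpp(mask)
  k <- max(lab)
  if (k == 0L) {
    out <- data.frame(component_id = integer(0), pixel_count = integer(0),
                      area_m2 = numeric(0), centroid_row = numeric(0),
                      centroid_col = numeric(0))
    attr(out, "labels") <- lab
    return(out)
  }
  idx <- which(lab > 0L)
  ids <- lab[idx]
  rows <- (idx - 1L) %% nrow(mask) + 1L
  cols <- (idx - 1L) %/% nrow(mask) + 1L
  cnt <- tabulate(ids, k)
  out <- data.frame(component_id = seq_len(k),
                    pixel_count = cnt,
                    area_m2 = cnt * pixel_size_m^2,
                    centroid_row = tapply(rows, ids, mean),
                    centroid_col = tapply(cols, ids, mean))
  rownames(out) <- NULL
  attr(out, "labels") <- lab
  out
}

#' Per-class pixel and area statistics
#'
#' Counts annotated pixels per class and converts them to m2, percentage of
#' the site, and (for blueberry, tree and yellow bush) percentage of the
#' living vegetation.
#'
#' @param masks named list of binary matrices, mutually exclusive.
#' @param pixel_size_m metres per pixel.
#' @return data.frame: `class`, `pixels`, `area_m2`, `pct_site`,
#'   `pct_living_veg` (NA for non-living classes).
#' @export
compute_class_areas <- function(masks, pixel_size_m) {
  masks <- lapply(masks, as_logical_mask)
  overlap <- Reduce(`+`, lapply(masks, function(m) m + 0L))
  n_over <- sum(overlap > 1L)
  if (n_over > 0L)
    stop_bbm("masks are not mutually exclusive: %d pixel(s) multiply labeled",
             n_over)
  total <- length(masks[[1]])
  px <- vapply(masks, sum, 0)
  living <- sum(px[names(px) %in% LIVING_CLASSES])
  out <- data.frame(class = names(px),
                    pixels = as.integer(px),
                    area_m2 = px * pixel_size_m^2,
                    pct_site = 100 * px / total,
                    pct_living_veg = ifelse(names(px) %in% LIVING_CLASSES,
                                            100 * px / living, NA_real_))
  rownames(out) <- NULL
  out
}

#' Per-bush height from DEM and ground annotation points
#'
#' Height of each labeled bush is the chosen statistic (maximum or median)
#' of the DEM over the component's pixels minus the elevation of the
#' ground point nearest to the component centroid. Grass hassocks next to a
#' bush can raise the local ground reading above the canopy, so negative
#' heights are clamped to 0 m and flagged. Bushes with no ground point
#' within `max_ground_dist_m` get a missing height.
#'
#' @param dem elevation matrix, metres.
#' @param bushes output of [label_bushes()] (the `"labels"` attribute is
#'   required).
#' @param ground_points data.frame with `x_px`, `y_px`, `elevation_m`.
#' @param statistic `"max"` or `"median"`.
#' @param pixel_size_m metres per pixel (for the distance cutoff).
#' @param max_ground_dist_m ground points farther than this from the bush
#'   centroid do not support a height estimate.
#' @return `bushes` with added columns `height_m` (NA when undefined),
#'   `clamped` (TRUE when a negative estimate was clamped to 0) and
#'   `ground_point` (row index into `ground_points`, NA when missing).
#' @export
compute_bush_heights <- function(dem, bushes, ground_points,
                                 statistic = c("max", "median"),
                                 pixel_size_m = 1,
                                 max_ground_dist_m = Inf) {
  statistic <- match.arg(statistic)
  if (is.null(dem) || !is.matrix(dem))
    stop_bbm("no DEM available: height analysis disabled")
  lab <- attr(bushes, "labels")
  if (is.null(lab)) stop_bbm("bushes must carry the 'labels' attribute")
  if (!all(dim(lab) == dim(dem))) stop_bbm("DEM and labels not co-registered")
  if (nrow(ground_points) < 1L) stop_bbm("at least one ground point required")
  stat_fun <- if (statistic == "max") max else median
  n <- nrow(bushes)
  height <- rep(NA_real_, n); clamped <- rep(FALSE, n)
  gp_idx <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    d <- sqrt((ground_points$y_px - bushes$centroid_row[i])^2 +
              (ground_points$x_px - bushes$centroid_col[i])^2) * pixel_size_m
    j <- which.min(d)
    if (d[j] > max_ground_dist_m) next
    gp_idx[i] <- j
    vals <- dem[lab == bushes$component_id[i]]
    h <- stat_fun(vals) - ground_points$elevation_m[j]
    if (h < 0) { h <- 0; clamped[i] <- TRUE }
    height[i] <- h
  }
  bushes$height_m <- height
  bushes$clamped <- clamped
  bushes$ground_point <- gp_idx
  bushes
}

#' Site-level bush inventory summary
#'
#' Summary statistics in the shape of the per-site survey table: bush count,
#' bushes per hectare, total and mean bush area. Accepts either per-bush
#' records or pre-computed totals (e.g. published per-site totals).
#'
#' @param records data.frame from [label_bushes()]; may be NULL when
#'   `total_bush_area_m2` and `bush_count` are given directly.
#' @param site_area_ha site area in hectares.
#' @param total_bush_area_m2,bush_count totals, derived from `records` by
#'   default.
#' @param class_areas optional result of [compute_class_areas()]; adds the
#'   per-class fractions and the blueberry share of living vegetation.
#' @return list of class `inventory_summary` with raw values and a
#'   `rounded` data.frame (2 decimals, half-up) in report shape. Ratio
#'   fields are NA (undefined) when `bush_count` is 0.
#' @export
summarize_inventory <- function(records = NULL, site_area_ha,
                                total_bush_area_m2 = sum(records$area_m2),
                                bush_count = nrow(records),
                                class_areas = NULL) {
  if (is.null(records) && (missing(total_bush_area_m2) || missing(bush_count)))
    stop_bbm("provide records or explicit totals")
  mean_area <- if (bush_count > 0) total_bush_area_m2 / bush_count else NA_real_
  per_ha <- if (site_area_ha > 0) bush_count / site_area_ha else NA_real_
  bb_living <- if (!is.null(class_areas))
    class_areas$pct_living_veg[class_areas$class == "blueberry"] else NA_real_
  out <- list(site_area_ha = site_area_ha,
              bush_count = bush_count,
              bushes_per_ha = per_ha,
              total_bush_area_m2 = total_bush_area_m2,
              mean_area_per_bush_m2 = mean_area,
              blueberry_pct_living_veg = bb_living,
              class_areas = class_areas)
  out$rounded <- data.frame(
    site_area_ha = round_half_up(site_area_ha),
    bush_count = bush_count,
    bushes_per_ha = round_half_up(per_ha),
    total_bush_area_m2 = round_half_up(total_bush_area_m2),
    mean_area_per_bush_m2 = round_half_up(mean_area))
  class(out) <- "inventory_summary"
  out
}

#' @export
print.inventory_summary <- function(x, ...) {
  print(x$rounded)
  invisible(x)
}

#' Histogram table with half-open bins and an overflow bin
#'
#' Bins are left-closed right-open `[e_i, e_{i+1})`; values at or above the
#' last edge fall into an overflow bin, matching 0.5 m height classes up to
#' "more than 3.5 m". NA values are dropped and reported.
#'
#' @param values numeric vector (NAs allowed).
#' @param bin_edges strictly increasing numeric vector.
#' @return data.frame `bin`, `lower`, `upper` (Inf for overflow), `count`.
#' @export
bin_distribution <- function(values, bin_edges = seq(0, 3.5, by = 0.5)) {
  if (any(diff(bin_edges) <= 0)) stop_bbm("bin_edges must be strictly increasing")
  v <- values[!is.na(values)]
  if (any(v < bin_edges[1]))
    stop_bbm("%d value(s) below the first bin edge", sum(v < bin_edges[1]))
  k <- length(bin_edges)
  idx <- findInterval(v, bin_edges)      # k means overflow
  lower <- bin_edges
  upper <- c(bin_edges[-1], Inf)
  lab <- c(sprintf("[%.2g, %.2g)", head(lower, -1), head(upper, -1)),
           sprintf(">= %.2g", bin_edges[k]))
  out <- data.frame(bin = lab, lower = lower, upper = upper,
                    count = tabulate(idx, k))
  attr(out, "n_missing") <- sum(is.na(values))
  out
}
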