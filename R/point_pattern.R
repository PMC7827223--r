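#' Generate a clustered bush centroid pattern
#'
#' Draws `bush_count` centroids inside the metric frame of the scene as a
#' Neyman-Scott style process: cluster parents placed uniformly, offspring
#' scattered around them with isotropic Gaussian dispersion, plus a
#' `background_fraction` of uniformly placed singletons. Coordinates are in
#' metres with x increasing east and y increasing north.
#'
#' @param cfg a [scene_config()].
#' @param margin_m keep-out margin from every frame edge, metres.
#' @return a `point_pattern`: list with `points` (data.frame `x_m`, `y_m`),
#'   `site_id`, `extent` (named xmin/xmax/ymin/ymax) and the parent
#'   assignment used.
#' @export
generate_point_pattern <- function(cfg, margin_m = 0) {
  ext <- c(xmin = 0, xmax = cfg$width_px * cfg$pixel_size_m,
           ymin = 0, ymax = cfg$height_px * cfg$pixel_size_m)
  lo <- c(ext[["xmin"]], ext[["ymin"]]) + margin_m
  hi <- c(ext[["xmax"]], ext[["ymax"]]) - margin_m
  if (cfg$bush_count > 0L && any(hi <= lo))
    stop_bbm("frame too small to place %d centroids with a %.2f m margin",
             cfg$bush_count, margin_m)
  n <- cfg$bush_count
  cp <- cfg$cluster_process
  pts <- with_seed(derive_seed(cfg$seed, "pattern"), {
    if (n == 0L) {
      data.frame(x_m = numeric(0), y_m = numeric(0), parent = integer(0))
    } else {
      n_bg <- round(cp$background_fraction * n)
      n_cl <- n - n_bg
      n_par <- max(1L, min(cp$parent_count, n_cl))
      px <- runif(n_par, lo[1], hi[1])
      py <- runif(n_par, lo[2], hi[2])
      out <- data.frame(x_m = numeric(0), y_m = numeric(0),
                        parent = integer(0))
      if (n_cl > 0L) {
        assign_par <- rep(seq_len(n_par), length.out = n_cl)
        x <- clamp(px[assign_par] + rnorm(n_cl, 0, cp$cluster_sigma_m),
                   lo[1], hi[1])
        y <- clamp(py[assign_par] + rnorm(n_cl, 0, cp$cluster_sigma_m),
                   lo[2], hi[2])
        out <- data.frame(x_m = x, y_m = y, parent = assign_par)
      }
      if (n_bg > 0L) {
        out <- rbind(out, data.frame(x_m = runif(n_bg, lo[1], hi[1]),
                                     y_m = runif(n_bg, lo[2], hi[2]),
                                     parent = 0L))
      }
      out
    }
  })
  structure(list(points = pts[, c("x_m", "y_m")], parent = pts$parent,
                 site_id = sprintf("synthetic_seed%d", cfg$seed),
                 extent = ext),
            class = "point_pattern")
}

#' Build a point pattern from raw metric coordinates
#'
#' @param x_m,y_m coordinates in metres.
#' @param extent named numeric (xmin, xmax, ymin, ymax); defaults to the
#'   bounding box.
#' @param site_id site label.
#' @return a `point_pattern`.
#' @export
point_pattern <- function(x_m, y_m, extent = NULL, site_id = "site") {
  stopifnot(length(x_m) == length(y_m))
  if (is.null(extent)) {
    extent <- c(xmin = min(x_m, 0), xmax = max(x_m, 1),
                ymin = min(y_m, 0), ymax = max(y_m, 1))
  }
  inside <- x_m >= extent[["xmin"]] & x_m <= extent[["xmax"]] &
    y_m >= extent[["ymin"]] & y_m <= extent[["ymax"]]
  if (!all(inside)) stop_bbm("%d point(s) fall outside the extent",
                             sum(!inside))
  structure(list(points = data.frame(x_m = x_m, y_m = y_m),
                 parent = rep(NA_integer_, length(x_m)),
                 site_id = site_id, extent = extent),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point_pattern '%s': %d points in [%.1f, %.1f] x [%.1f, %.1f] m\n",
              x$site_id, nrow(x$points), x$extent[["xmin"]],
              x$extent[["xmax"]], x$extent[["ymin"]], x$extent[["ymax"]]))
  invisible(x)
}
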