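#' Configuration for a synthetic wetland scene
#'
#' Bundles all knobs of the synthetic orthomosaic generator. The defaults
#' emulate the statistical structure of an autumn wetland UAV survey at
#' 5 cm/pixel: soil dominates (roughly 85% of the area), blueberry bushes
#' cover 1-1.5%, bush radii fall in the 20-100 pixel range the patch size
#' was designed around, bush centroids are clustered, and bush heights are
#' mostly below 0.5 m with a sparse tail towards 3 m. A configurable
#' fraction of soil receives a reddish tint so the classifier sees hard
#' negatives resembling autumn blueberry foliage.
#'
#' @param width_px,height_px frame size in pixels.
#' @param pixel_size_m ground sampling distance, metres per pixel.
#' @param class_fractions named target area fractions for the non-soil
#'   classes plus blueberry; whatever remains is soil. Must sum to <= 1.
#' @param bush_radius_range_px numeric length-2, min and max equivalent
#'   bush radius in pixels.
#' @param bush_count number of blueberry bushes to plant.
#' @param cluster_process list with `parent_count`, `cluster_sigma_m` and
#'   `background_fraction` controlling the Neyman-Scott style centroid
#'   pattern (a fraction of bushes is placed uniformly as background).
#' @param height_model list with `short_mode_m` (modal height of the short
#'   growth form), `tall_tail_max_m` (ceiling for the sparse tall form) and
#'   `hassock_noise_sd_m` (sd of grass-tussock elevation noise on the DEM).
#' @param confounder_fraction fraction of soil pixels tinted reddish.
#' @param color_noise_sd per-pixel RGB noise sd (0-255 scale).
#' @param palette named list of length-3 RGB vectors per class, plus
#'   `soil_confounder`.
#' @param seed integer seed; identical config + seed gives a bit-identical
#'   scene.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(width_px = 1000L, height_px = 1000L,
                         pixel_size_m = 0.05,
                         class_fractions = c(blueberry = 0.012, tree = 0.05,
                                             yellow_bush = 0.03, water = 0.03,
                                             dead_tree = 0.005),
                         bush_radius_range_px = c(20, 100),
                         bush_count = 8L,
                         cluster_process = list(parent_count = 3L,
                                                cluster_sigma_m = 4,
                                                background_fraction = 0.25),
                         height_model = list(short_mode_m = 0.3,
                                             tall_tail_max_m = 3,
                                             hassock_noise_sd_m = 0.1),
                         confounder_fraction = 0.10,
                         color_noise_sd = 8,
                         palette = default_palette(),
                         seed = 1L) {
  cfg <- list(width_px = as.integer(width_px),
              height_px = as.integer(height_px),
              pixel_size_m = pixel_size_m,
              class_fractions = class_fractions,
              bush_radius_range_px = bush_radius_range_px,
              bush_count = as.integer(bush_count),
              cluster_process = cluster_process,
              height_model = height_model,
              confounder_fraction = confounder_fraction,
              color_noise_sd = color_noise_sd,
              palette = palette,
              seed = as.integer(seed))
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
}

validate_scene_config <- function(cfg) {
  if (cfg$width_px < 1L || cfg$height_px < 1L)
    stop_bbm("frame dimensions must be positive")
  if (cfg$pixel_size_m <= 0) stop_bbm("pixel_size_m must be > 0")
  cf <- cfg$class_fractions
  if (is.null(names(cf)) || !all(names(cf) %in% SCENE_CLASSES))
    stop_bbm("class_fractions must be named with scene classes")
  if (any(cf < 0)) stop_bbm("class fractions must be non-negative")
  if (sum(cf) > 1)
    stop_bbm("class fractions sum to %.3f > 1; no area left for soil",
             sum(cf))
  rr <- cfg$bush_radius_range_px
  if (length(rr) != 2 || rr[1] > rr[2] || rr[1] < 1 ||
      rr[2] > min(cfg$width_px, cfg$height_px) / 2)
    stop_bbm("bush_radius_range_px must lie in [1, min(width, height)/2]")
  if (cfg$bush_count < 0L) stop_bbm("bush_count must be >= 0")
  if (cfg$confounder_fraction < 0 || cfg$confounder_fraction > 1)
    stop_bbm("confounder_fraction must be in [0, 1]")
  cfg
}

#' @rdname scene_config
#' @export
default_palette <- function() {
  list(blueberry        = c(155,  45,  55),
       tree             = c( 35,  85,  45),
       yellow_bush      = c(205, 185,  70),
       soil             = c(168, 138,  98),
       water            = c( 45,  70, 120),
       dead_tree        = c(130, 125, 115),
       soil_confounder  = c(170,  95,  80))
}
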