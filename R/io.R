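#' Write a scene to disk as plain rasters plus a manifest
#'
#' RGB and the per-class masks are written as PNG, the DEM as a
#' full-precision TSV matrix (value-exact round trip), points as CSV and
#' GeoJSON, and a manifest JSON ties the files together with per-file
#' checksums and the pixel size.
#'
#' @param scene an `orthomosaic_scene`.
#' @param dir output directory (created if needed).
#' @return path of the manifest JSON, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sid <- scene$site_id
  paths <- list(rgb = file.path(dir, paste0(sid, "_rgb.png")))
  png::writePNG(scene$rgb / 255, paths$rgb)
  if (!is.null(scene$dem)) {
    paths$dem <- file.path(dir, paste0(sid, "_dem.tsv"))
    data.table::fwrite(data.table::as.data.table(scene$dem), paths$dem,
                       sep = "\t", col.names = FALSE)
  }
  for (cls in names(scene$masks)) {
    p <- file.path(dir, paste0(sid, "_", cls, ".png"))
    png::writePNG(scene$masks[[cls]] * 1.0, p)
    paths[[paste0("mask_", cls)]] <- p
  }
  paths$ground_points <- file.path(dir, paste0(sid, "_ground_points.csv"))
  write.csv(scene$ground_points, paths$ground_points, row.names = FALSE)
  cent <- scene$truth$planted
  if (!is.null(cent) && nrow(cent)) {
    paths$centroids <- file.path(dir, paste0(sid, "_centroids.csv"))
    write.csv(cent[, c("x_m", "y_m", "height_m")], paths$centroids,
              row.names = FALSE)
    paths$centroids_geojson <- file.path(dir, paste0(sid, "_centroids.geojson"))
    gj <- list(type = "FeatureCollection",
               features = lapply(seq_len(nrow(cent)), function(i) list(
                 type = "Feature",
                 geometry = list(type = "Point",
                                 coordinates = c(cent$x_m[i], cent$y_m[i])),
                 properties = list(bush_id = cent$bush_id[i],
                                   height_m = cent$height_m[i]))))
    jsonlite::write_json(gj, paths$centroids_geojson, auto_unbox = TRUE,
                         digits = NA)
  }
  manifest <- list(site_id = sid,
                   pixel_size_m = scene$pixel_size_m,
                   width_px = dim(scene$rgb)[2],
                   height_px = dim(scene$rgb)[1],
                   files = lapply(paths, basename),
                   checksums = lapply(paths, function(p)
                     unname(tools::md5sum(p))))
  mpath <- file.path(dir, paste0(sid, "_manifest.json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m >= 128 / 255   # binarize grayscale annotations at 128
}

#' Read a scene from a manifest
#'
#' Restores the rasters written by [write_scene()], checking that all files
#' exist and share dimensions. Masks are binarized at the 128/255 gray
#' level. A missing DEM file leaves `dem` NULL (height analyses then fail
#' with a clear error); a missing class mask is an error naming the file.
#'
#' @param manifest_path path to the `*_manifest.json`.
#' @return an `orthomosaic_scene` (without generator truth).
#' @export
read_scene <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  fp <- function(key) file.path(dir, man$files[[key]])
  if (!file.exists(fp("rgb"))) stop_bbm("missing RGB file %s", fp("rgb"))
  rgb01 <- png::readPNG(fp("rgb"))
  rgb <- round(rgb01 * 255); storage.mode(rgb) <- "integer"
  dm <- dim(rgb)[1:2]
  dem <- NULL
  if (!is.null(man$files$dem)) {
    if (!file.exists(fp("dem"))) stop_bbm("missing DEM file %s", fp("dem"))
    dem <- as.matrix(data.table::fread(fp("dem"), header = FALSE, sep = "\t"))
    dimnames(dem) <- NULL
    if (!all(dim(dem) == dm))
      stop_bbm("DEM dimensions %dx%d do not match RGB %dx%d",
               nrow(dem), ncol(dem), dm[1], dm[2])
  }
  masks <- list()
  for (cls in SCENE_CLASSES) {
    key <- paste0("mask_", cls)
    if (is.null(man$files[[key]]) || !file.exists(fp(key)))
      stop_bbm("missing class mask file for '%s' (%s)", cls,
               man$files[[key]] %||% "not in manifest")
    m <- read_mask_png(fp(key))
    if (!all(dim(m) == dm))
      stop_bbm("mask '%s' dimensions do not match the RGB raster", cls)
    masks[[cls]] <- m
  }
  gp <- if (!is.null(man$files$ground_points) && file.exists(fp("ground_points")))
    read.csv(fp("ground_points")) else
      data.frame(x_px = integer(0), y_px = integer(0), elevation_m = numeric(0))
  structure(list(rgb = rgb, dem = dem, masks = masks, ground_points = gp,
                 pixel_size_m = man$pixel_size_m, site_id = man$site_id,
                 truth = NULL),
            class = "orthomosaic_scene")
}
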