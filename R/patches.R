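# patch sets: meta data.frame + parallel list of image tiles.
# origins are 0-based (row0, col0) so a tile covers rows row0+1 .. row0+side.

new_patch_set <- function(meta, images) {
  stopifnot(nrow(meta) == length(images))
  structure(list(meta = meta, images = images), class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  nb <- sum(x$meta$blueberry_fraction > 0)
  cat(sprintf("patch_set: %d patches (side %d px) from %s; %d contain blueberry\n",
              nrow(x$meta), x$meta$side_px[1] %||% NA,
              paste(unique(x$meta$site_id), collapse = ", "), nb))
  invisible(x)
}

#' @export
length.patch_set <- function(x) nrow(x$meta)

subset_patches <- function(ps, idx) new_patch_set(ps$meta[idx, , drop = FALSE],
                                                  ps$images[idx])

bind_patches <- function(...) {
  sets <- list(...)
  new_patch_set(do.call(rbind, lapply(sets, `[[`, "meta")),
                do.call(c, lapply(sets, `[[`, "images")))
}

#' Tile a scene into axis-parallel labeled patches
#'
#' Cuts the orthomosaic into a non-overlapping grid of `side_px` tiles
#' (trailing strips that do not fill a tile are dropped). Each patch gets
#' the multi-label set of all classes with at least one annotated pixel in
#' the tile and the exact fraction of blueberry pixels.
#'
#' @param scene an `orthomosaic_scene`.
#' @param side_px tile side; 100 px for coarse tiles, 25 px for refinement.
#' @return a `patch_set` with meta columns `patch_id`, `site_id`, `row0`,
#'   `col0`, `side_px`, `blueberry_fraction`, `labels` (list column).
#' @export
tile_orthomosaic <- function(scene, side_px = 100L) {
  H <- dim(scene$rgb)[1]; W <- dim(scene$rgb)[2]
  if (H < side_px || W < side_px)
    stop_bbm("scene (%d x %d) smaller than one %d px tile", H, W, side_px)
  nr <- H %/% side_px; nc <- W %/% side_px
  n <- nr * nc
  meta <- data.frame(patch_id = seq_len(n),
                     site_id = scene$site_id,
                     row0 = rep((seq_len(nr) - 1L) * side_px, times = nc),
                     col0 = rep((seq_len(nc) - 1L) * side_px, each = nr),
                     side_px = as.integer(side_px),
                     blueberry_fraction = NA_real_)
  images <- vector("list", n)
  labels <- vector("list", n)
  for (i in seq_len(n)) {
    rs <- (meta$row0[i] + 1L):(meta$row0[i] + side_px)
    cs <- (meta$col0[i] + 1L):(meta$col0[i] + side_px)
    images[[i]] <- scene$rgb[rs, cs, , drop = FALSE]
    present <- vapply(SCENE_CLASSES,
                      function(cl) any(scene$masks[[cl]][rs, cs]), TRUE)
    labels[[i]] <- SCENE_CLASSES[present]
    meta$blueberry_fraction[i] <- sum(scene$masks$blueberry[rs, cs]) /
      side_px^2
  }
  meta$labels <- I(labels)
  new_patch_set(meta, images)
}

PATCH_TRANSFORMS <- c("flip_ud", "flip_lr", "rotate", "blur", "contrast",
                      "elastic")

# bilinear sampling at fractional (row, col) with reflect padding;
# used by the rotation and elastic-deformation augmentations
warp_bilinear <- function(img, rows, cols) {
  H <- dim(img)[1]; W <- dim(img)[2]
  reflect <- function(x, n) {
    x <- (x - 1) %% (2 * (n - 1))
    ifelse(x > (n - 1), 2 * (n - 1) - x, x) + 1
  }
  rows <- reflect(rows, H); cols <- reflect(cols, W)
  r0 <- clamp(floor(rows), 1, H); c0 <- clamp(floor(cols), 1, W)
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  fr <- rows - r0; fc <- cols - c0
  out <- img
  for (ch in seq_len(dim(img)[3])) {
    m <- img[, , ch]
    v <- m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
      m[cbind(r1, c0)] * fr * (1 - fc) +
      m[cbind(r0, c1)] * (1 - fr) * fc +
      m[cbind(r1, c1)] * fr * fc
    out[, , ch] <- matrix(v, H, W)
  }
  out
}

#' Augment a patch with one of the six survey transforms
#'
#' Vertical/horizontal flips, small central rotation (uniform within
#' `rotate_range_deg`, reflect padding), Gaussian blur (UAV motion),
#' linear contrast/brightness change (light and shadow), and localised
#' elastic deformation. All transforms preserve the patch geometry and the
#' label list; randomness is fully determined by `seed`.
#'
#' @param image HxWx3 numeric array, 0-255.
#' @param transform_id one of
#'   `"flip_ud"`, `"flip_lr"`, `"rotate"`, `"blur"`, `"contrast"`,
#'   `"elastic"`.
#' @param seed integer seed for the transform's random parameters.
#' @param rotate_range_deg half-range of the rotation angle.
#' @return transformed image array of identical dimensions.
#' @export
augment_patch <- function(image, transform_id, seed = 1L,
                          rotate_range_deg = 15) {
  if (!transform_id %in% PATCH_TRANSFORMS)
    stop_bbm("unknown transform '%s'", transform_id)
  H <- dim(image)[1]; W <- dim(image)[2]
  img <- image * 1.0
  out <- with_seed(derive_seed(seed, transform_id), switch(
    transform_id,
    flip_ud = img[H:1, , , drop = FALSE],
    flip_lr = img[, W:1, , drop = FALSE],
    rotate = {
      ang <- runif(1, -rotate_range_deg, rotate_range_deg) * pi / 180
      cr <- (H + 1) / 2; cc <- (W + 1) / 2
      g <- expand.grid(r = seq_len(H), c = seq_len(W))
      rs <- cr + cos(ang) * (g$r - cr) - sin(ang) * (g$c - cc)
      cs <- cc + sin(ang) * (g$r - cr) + cos(ang) * (g$c - cc)
      warp_bilinear(img, rs, cs)
    },
    blur = {
      sig <- runif(1, 0.5, 1.5)
      e <- EBImage::gblur(EBImage::Image(aperm(img, c(2, 1, 3)) / 255,
                                         colormode = "Color"), sigma = sig)
      aperm(EBImage::imageData(e), c(2, 1, 3)) * 255
    },
    contrast = {
      a <- runif(1, 0.8, 1.2); b <- runif(1, -10, 10)
      (img - 127.5) * a + 127.5 + b
    },
    elastic = {
      alpha <- runif(1, 2, 5); sig <- 4
      field <- function() {
        f <- matrix(rnorm(H * W), H, W)
        e <- EBImage::gblur(EBImage::Image(t(f)), sigma = sig)
        t(EBImage::imageData(e)) * alpha * sig
      }
      g <- expand.grid(r = seq_len(H), c = seq_len(W))
      warp_bilinear(img, g$r + as.vector(field()), g$c + as.vector(field()))
    }))
  clamp(out, 0, 255)
}
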