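# small scenes shared across test files, built once per run

.fixture_env <- new.env(parent = emptyenv())

small_scene_config <- function(seed = 1L, ...) {
  scene_config(width_px = 360L, height_px = 360L, bush_count = 4L,
               bush_radius_range_px = c(10, 25),
               class_fractions = c(blueberry = 0.012, tree = 0.05,
                                   yellow_bush = 0.03, water = 0.03,
                                   dead_tree = 0.005),
               seed = seed, ...)
}

small_scene <- function(seed = 1L) {
  key <- paste0("scene", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_scene(small_scene_config(seed))
  .fixture_env[[key]]
}

# pure-R flood-fill over 8-neighbourhoods; the independent labeling oracle
flood_fill_label <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0)); lab[r0, c0] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= H && c >= 1 && c <= W &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# union-find over all point pairs; the independent clustering oracle
union_find_clusters <- function(xy, threshold) {
  n <- nrow(xy)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (sqrt(sum((xy[i, ] - xy[j, ])^2)) <= threshold) {
      fi <- find(i); fj <- find(j)
      if (fi != fj) parent[fj] <- fi
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

# brute-force inter-region merge radii: sort all pairs, union-find over
# samples, track region connectivity; the persistence oracle
brute_force_h0 <- function(samples, convention = "half-distance") {
  xy <- as.matrix(samples[, c("row", "col")])
  n <- nrow(xy)
  regions <- unique(samples$region_id)
  d <- as.matrix(dist(xy))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[pairs])
  pairs <- pairs[ord, , drop = FALSE]
  sp <- seq_len(n); rp <- seq_along(regions)
  findf <- function(parent, i) { while (parent[i] != i) i <- parent[i]; i }
  ridx <- match(samples$region_id, regions)
  out <- numeric(0)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    fi <- findf(sp, i); fj <- findf(sp, j)
    if (fi == fj) next
    sp[fj] <- fi
    ri <- findf(rp, ridx[i]); rj <- findf(rp, ridx[j])
    if (ri != rj) {
      rp[rj] <- ri
      out <- c(out, d[i, j])
    }
  }
  r <- sort(out)
  if (convention == "half-distance") r / 2 else r
}

# direct Gi* formula evaluation, written independently of gi_star()
gi_star_direct <- function(features, dmax) {
  n <- nrow(features)
  x <- features$count
  xb <- mean(x); s <- sqrt(mean(x^2) - xb^2)
  vapply(seq_len(n), function(i) {
    w <- as.numeric(sqrt((features$x_m - features$x_m[i])^2 +
                         (features$y_m - features$y_m[i])^2) <= dmax)
    U <- sqrt((n * sum(w^2) - sum(w)^2) / (n - 1))
    if (s == 0 || U == 0) return(0)
    (sum(w * x) - xb * sum(w)) / (s * U)
  }, 0)
}

solid_patch <- function(color, side = 40L) {
  img <- array(0, dim = c(side, side, 3))
  for (ch in 1:3) img[, , ch] <- color[ch]
  img
}

# a hand-built patch set with solid-colour tiles; labels follow the colour
make_solid_patch_set <- function(n_per_class, site_id = "toy", side = 40L,
                                 seed = 1L) {
  pal <- default_palette()
  set.seed(seed)
  metas <- list(); imgs <- list()
  for (cls in SCENE_CLASSES) {
    for (i in seq_len(n_per_class)) {
      img <- solid_patch(pal[[cls]], side)
      img <- pmin(pmax(img + array(rnorm(length(img), 0, 2), dim(img)), 0), 255)
      metas[[length(metas) + 1]] <- data.frame(
        patch_id = NA_integer_, site_id = site_id,
        row0 = 0L, col0 = 0L, side_px = side,
        blueberry_fraction = as.numeric(cls == "blueberry"))
      metas[[length(metas)]]$labels <- I(list(cls))
      imgs[[length(imgs) + 1]] <- img
    }
  }
  meta <- do.call(rbind, metas)
  meta$patch_id <- seq_len(nrow(meta))
  blueberrymap:::new_patch_set(meta, imgs)
}

# a degenerate classifier whose blueberry output is a constant logit
stub_model <- function(logit, side_px = 100L, cfg = train_config()) {
  d <- cfg$kernel_px^2 * 3
  k <- 7L
  ns <- ncol(blueberrymap:::patch_color_stats(list(solid_patch(c(0, 0, 0), 8L))))
  par <- list(Fc = matrix(0, d, cfg$conv_filters), bc = rep(0, cfg$conv_filters),
              W1 = matrix(0, 2 * cfg$conv_filters, cfg$hidden_units),
              b1 = rep(0, cfg$hidden_units),
              W2 = matrix(0, cfg$hidden_units, k), b2 = rep(logit, k),
              Ws = matrix(0, ns, k))
  structure(list(par = par, cfg = cfg, side_px = side_px,
                 classes = SCENE_CLASSES,
                 stats_center = rep(0, ns), stats_scale = rep(1, ns),
                 log = data.frame(epoch = 1, loss = NA, val_loss = NA)),
            class = "berry_classifier")
}
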