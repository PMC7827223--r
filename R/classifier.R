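# multi-label patch classifier: a tiny convolutional network. One 5x5
# convolution bank over the resampled patch, ReLU, then global max + mean
# pooling per filter (translation invariant: a bush counts wherever it sits
# in the patch), a small tanh dense layer, and a sigmoid head with six
# presence units plus a blueberry-fraction unit. Trained with Adam on the
# weighted dual loss
#   L = sum_c w_c BCE(y_c, p_c) / sum_c w_c + lambda (f_hat - f)^2

patch_features <- function(images, input_px) {
  t(vapply(images, function(img) {
    e <- EBImage::resize(EBImage::Image(aperm(img, c(2, 1, 3)) / 255,
                                        colormode = "Color"),
                         w = input_px, h = input_px)
    as.vector(EBImage::imageData(e))
  }, numeric(input_px * input_px * 3)))
}

# full-resolution colour quantile descriptors over the raw bands and the
# chromatic difference indices (R-G, R-B, G-B; the excess-red/green index
# family). Band statistics are standard vegetation-mapping features and,
# unlike the resampled thumbnail, keep the signal of a bush sliver that
# covers only a few pixels of a patch: the extreme quantiles of the
# green band and of R-G move whenever reddish foliage is present at all.
COLOR_QUANTILES <- c(0, 0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99, 1)
INDEX_THRESHOLDS <- seq(0.10, 0.45, by = 0.05)

patch_color_stats <- function(images) {
  nfeat <- 6 * length(COLOR_QUANTILES) + 6 * length(INDEX_THRESHOLDS)
  t(vapply(images, function(img) {
    x <- img / 255
    idx <- list(x[, , 1] - x[, , 2], x[, , 1] - x[, , 3],
                x[, , 2] - x[, , 3])
    bands <- c(list(x[, , 1], x[, , 2], x[, , 3]), idx)
    q <- unlist(lapply(bands, quantile, probs = COLOR_QUANTILES,
                       names = FALSE), use.names = FALSE)
    # exceedance fractions of the chromatic indices: a handful of strongly
    # tinted pixels yields a strictly positive count where a patch without
    # them gives exactly zero, whatever its bulk colour distribution.
    # log1p compresses the two-decade dynamic range of the counts so a
    # single-sliver patch is not a hundred times weaker than a full bush
    exc <- unlist(lapply(idx, function(b)
      vapply(INDEX_THRESHOLDS, function(th) log1p(1e4 * mean(b > th)), 0)),
      use.names = FALSE)
    # presence flags: "any pixel at all beyond the threshold" — binary
    # evidence a linear model can weight independently of the count
    c(q, exc, as.numeric(exc > 0))
  }, numeric(nfeat)))
}

patch_targets <- function(meta) {
  y <- vapply(SCENE_CLASSES, function(cl)
    vapply(meta$labels, function(l) cl %in% l, TRUE), logical(nrow(meta)))
  y <- matrix(as.numeric(y), nrow(meta), length(SCENE_CLASSES),
              dimnames = list(NULL, SCENE_CLASSES))
  list(presence = y, fraction = meta$blueberry_fraction)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# sliding-window unfold of all thumbnails at once: rows are windows
# (window-fastest within each sample), columns the k*k*3 window pixels
im2col_all <- function(X, input_px, k, stride) {
  n <- nrow(X)
  starts <- seq(1L, input_px - k + 1L, by = stride)
  nw <- length(starts)^2
  # offsets of one window's pixels within the flattened thumbnail
  off <- as.vector(outer(0:(k - 1),
                         rep(0:(k - 1), 3) * input_px +
                           rep(0:2, each = k) * input_px^2, `+`))
  base <- as.vector(outer(starts - 1L, (starts - 1L) * input_px, `+`)) + 1L
  idx <- outer(base, off, `+`)              # nw x (k*k*3)
  out <- matrix(0, n * nw, length(off))
  for (s in seq_len(n)) out[((s - 1) * nw + 1):(s * nw), ] <- X[s, ][idx]
  list(cols = out, nw = nw)
}

cnn_forward <- function(par, cols, nw, n, stats, want_cache = FALSE) {
  nf <- ncol(par$Fc)
  pre <- sweep(cols %*% par$Fc, 2, par$bc, `+`)
  act <- pmax(pre, 0)
  # pooling over the nw windows of each sample: view as nw x (n*nf)
  M <- matrix(act, nw, n * nf)
  amax <- max.col(t(M), ties.method = "first")      # per (sample, filter)
  mx <- matrix(M[cbind(amax, seq_len(n * nf))], n, nf)
  mn <- matrix(colMeans(M), n, nf)
  amax <- matrix(amax, n, nf)
  feats <- cbind(mx, mn)                    # n x 2nf, conv trunk input
  h <- tanh(sweep(feats %*% par$W1, 2, par$b1, `+`))
  # wide-and-deep head: the colour descriptors reach the output only
  # linearly (quasi-convex colour rules), the conv features only through
  # the trunk (texture/shape); neither can shortcut through the other
  p <- sigmoid(sweep(h %*% par$W2 + stats %*% par$Ws, 2, par$b2, `+`))
  if (!want_cache) return(list(p = p))
  list(p = p, h = h, feats = feats, act = act, pre = pre, amax = amax,
       nf = nf)
}

cnn_grad <- function(par, cols, nw, n, stats, Y, w_out, frozen) {
  fw <- cnn_forward(par, cols, nw, n, stats, want_cache = TRUE)
  k <- ncol(Y)
  # d loss / d logit of sigmoid+BCE is (p - y); the MSE fraction head gets
  # the extra 2 p (1 - p) factor
  delta <- sweep(fw$p - Y, 2, w_out, `*`)
  delta[, k] <- 2 * w_out[k] * (fw$p[, k] - Y[, k]) *
    fw$p[, k] * (1 - fw$p[, k])
  g <- list(W2 = crossprod(fw$h, delta) / n, b2 = colMeans(delta),
            Ws = crossprod(stats, delta) / n)
  dh <- (delta %*% t(par$W2)) * (1 - fw$h^2)
  g$W1 <- crossprod(fw$feats, dh) / n
  g$b1 <- colMeans(dh)
  if (frozen) {
    g$Fc <- par$Fc * 0; g$bc <- par$bc * 0
    return(g)
  }
  dfeats <- dh %*% t(par$W1)        # n x 2nf, conv pooled features
  nf <- fw$nf
  dact <- matrix(0, n * nw, nf)
  for (f in seq_len(nf)) {
    # mean-pool path spreads evenly; max-pool path routes to the argmax
    dact[, f] <- rep(dfeats[, nf + f] / nw, each = nw)
    rows <- (seq_len(n) - 1L) * nw + fw$amax[, f]
    dact[rows, f] <- dact[rows, f] + dfeats[, f]
  }
  dpre <- dact * (fw$pre > 0)
  g$Fc <- crossprod(cols, dpre) / n
  g$bc <- colSums(dpre) / n
  g
}

cnn_loss <- function(p, Y, w_out) {
  k <- ncol(Y)
  eps <- 1e-12
  bce <- -(Y[, -k, drop = FALSE] * log(p[, -k, drop = FALSE] + eps) +
           (1 - Y[, -k, drop = FALSE]) * log(1 - p[, -k, drop = FALSE] + eps))
  mean(bce %*% w_out[-k]) + w_out[k] * mean((p[, k] - Y[, k])^2)
}

# penalized IRLS for one ridge-logistic output column of the wide path;
# ridge keeps the fit bounded although the training classes are separable
irls_ridge <- function(X, y, lambda, iters = 40L) {
  n <- nrow(X); p <- ncol(X)
  Xi <- cbind(1, X)
  beta <- rep(0, p + 1)
  pen <- diag(c(0, rep(lambda * n, p)))
  for (it in seq_len(iters)) {
    eta <- as.vector(Xi %*% beta)
    mu <- sigmoid(eta)
    w <- pmax(mu * (1 - mu), 1e-6)
    z <- eta + (y - mu) / w
    newb <- solve(crossprod(Xi, Xi * w) + pen, crossprod(Xi, w * z))
    if (max(abs(newb - beta)) < 1e-9) { beta <- newb; break }
    beta <- newb
  }
  as.vector(beta)
}

prepare_inputs <- function(patch_set_or_images, cfg) {
  images <- if (inherits(patch_set_or_images, "patch_set"))
    patch_set_or_images$images else patch_set_or_images
  X <- patch_features(images, cfg$input_px)
  c(im2col_all(X, cfg$input_px, cfg$kernel_px, cfg$conv_stride),
    list(n = nrow(X), stats = patch_color_stats(images)))
}

#' Train the multi-label patch classifier
#'
#' Fits the tiny convolutional presence + blueberry-fraction network on a
#' training patch set under the weighted dual loss, with Adam and seeded
#' initialisation. Train and validation patches must come from disjoint
#' sites (mosaic-level split); overlapping site ids raise a data-leakage
#' error.
#'
#' @param train_patches,val_patches `patch_set`s from disjoint sites;
#'   `val_patches` may be NULL.
#' @param cfg a [train_config()].
#' @return object of class `berry_classifier`: weights, config, the patch
#'   side it was trained on, and a training log (per-epoch training loss,
#'   plus validation loss when validation patches are given).
#' @export
train_classifier <- function(train_patches, val_patches = NULL, cfg) {
  stopifnot(inherits(cfg, "train_config"))
  if (!is.null(val_patches)) {
    common <- intersect(unique(train_patches$meta$site_id),
                        unique(val_patches$meta$site_id))
    if (length(common))
      stop_bbm("data leakage: site(s) %s appear in both train and validation",
               paste(common, collapse = ", "))
  }
  tr <- prepare_inputs(train_patches, cfg)
  # z-score the colour descriptors on training statistics so their (small)
  # dynamic range competes on equal footing with the conv activations
  stats_center <- colMeans(tr$stats)
  stats_scale <- pmax(apply(tr$stats, 2, stats::sd), 1e-6)
  tr$stats <- scale(tr$stats, stats_center, stats_scale)
  tg <- patch_targets(train_patches$meta)
  Y <- cbind(tg$presence, fraction = tg$fraction)
  w_out <- c(cfg$class_loss_weights / sum(cfg$class_loss_weights),
             fraction = cfg$fraction_loss_weight)
  va <- NULL; Yv <- NULL
  if (!is.null(val_patches) && length(val_patches) > 0) {
    va <- prepare_inputs(val_patches, cfg)
    va$stats <- scale(va$stats, stats_center, stats_scale)
    tv <- patch_targets(val_patches$meta)
    Yv <- cbind(tv$presence, fraction = tv$fraction)
  }
  d <- cfg$kernel_px^2 * 3; nf <- cfg$conv_filters
  h <- cfg$hidden_units; k <- ncol(Y)
  nfeat <- 2 * nf
  par <- with_seed(derive_seed(cfg$seed, "init"), list(
    Fc = matrix(rnorm(d * nf, 0, sqrt(2 / d)), d, nf),
    bc = rep(0, nf),
    W1 = matrix(rnorm(nfeat * h, 0, sqrt(2 / nfeat)), nfeat, h),
    b1 = rep(0, h),
    W2 = matrix(0, h, k),   # zero-init head: the trunk contributes only
    b2 = rep(0, k),          # after it has learned something useful
    Ws = matrix(0, ncol(tr$stats), k)))
  # stage 1: the wide colour path of each presence class is an exact
  # penalized logistic fit (the class loss weights rescale whole columns,
  # so the per-column optimum is weight-free); the trunk then learns the
  # residual. The fraction head is left to the trunk.
  for (cl in seq_len(k - 1L)) {
    beta <- irls_ridge(tr$stats, Y[, cl], cfg$ridge_lambda)
    par$b2[cl] <- beta[1]
    par$Ws[, cl] <- beta[-1]
  }
  mom <- lapply(par, function(x) x * 0)
  vel <- lapply(par, function(x) x * 0)
  b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
  frozen <- cfg$weights_mode == "frozen"
  log_df <- data.frame(epoch = seq_len(cfg$epochs), loss = NA_real_,
                       val_loss = NA_real_)
  bs <- cfg$batch_size %||% tr$n
  t <- 0
  swa_from <- cfg$epochs - ceiling((cfg$swa_fraction %||% 0) * cfg$epochs) + 1L
  swa <- NULL; n_swa <- 0L
  best_val <- Inf; best_par <- NULL
  with_seed(derive_seed(cfg$seed, "shuffle"), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- if (bs < tr$n) sample.int(tr$n) else seq_len(tr$n)
      # cosine learning-rate decay over the training run
      lr <- cfg$learning_rate * 0.5 * (1 + cos(pi * (ep - 1) / cfg$epochs))
      for (start in seq(1, tr$n, by = bs)) {
        sel <- ord[start:min(start + bs - 1, tr$n)]
        rows <- rep((sel - 1L) * tr$nw, each = tr$nw) + seq_len(tr$nw)
        g <- cnn_grad(par, tr$cols[rows, , drop = FALSE], tr$nw,
                      length(sel), tr$stats[sel, , drop = FALSE],
                      Y[sel, , drop = FALSE], w_out, frozen)
        g$Ws <- g$Ws * 0          # stage-1 fit stays fixed
        g$b2[seq_len(k - 1L)] <- 0  # presence intercepts keep the stage-1
                                    # calibration; the trunk learns residuals
        t <- t + 1
        wd <- cfg$weight_decay %||% 0
        for (nm in names(par)) {
          mom[[nm]] <- b1m * mom[[nm]] + (1 - b1m) * g[[nm]]
          vel[[nm]] <- b2m * vel[[nm]] + (1 - b2m) * g[[nm]]^2
          par[[nm]] <- par[[nm]] - lr *
            (mom[[nm]] / (1 - b1m^t)) / (sqrt(vel[[nm]] / (1 - b2m^t)) + eps)
          if (wd > 0 && nm %in% c("Fc", "W1", "W2"))
            par[[nm]] <- par[[nm]] * (1 - lr * wd)
        }
      }
      if (ep >= swa_from) {
        # tail weight averaging: small cosine-decayed steps stay in one
        # basin, so averaging the trajectory reduces estimator variance
        n_swa <- n_swa + 1L
        swa <- if (is.null(swa)) par else
          mapply(function(a, b) a + (b - a) / n_swa, swa, par,
                 SIMPLIFY = FALSE)
      }
      log_df$loss[ep] <- cnn_loss(
        cnn_forward(par, tr$cols, tr$nw, tr$n, tr$stats)$p, Y, w_out)
      if (!is.null(va)) {
        log_df$val_loss[ep] <- cnn_loss(
          cnn_forward(par, va$cols, va$nw, va$n, va$stats)$p, Yv, w_out)
        # validation-mosaic model selection: keep the weights with the
        # lowest held-out loss seen during training
        if (log_df$val_loss[ep] < best_val) {
          best_val <- log_df$val_loss[ep]
          best_par <- par
        }
      }
    }
  })
  par <- if (!is.null(best_par)) best_par else if (!is.null(swa)) swa else par
  structure(list(par = par, cfg = cfg, side_px = train_patches$meta$side_px[1],
                 classes = SCENE_CLASSES, log = log_df,
                 stats_center = stats_center, stats_scale = stats_scale),
            class = "berry_classifier")
}

#' @export
print.berry_classifier <- function(x, ...) {
  cat(sprintf(
    "berry_classifier (%s, %s): trained %d epochs on side-%d patches, final loss %.4f\n",
    x$cfg$backbone, x$cfg$weights_mode, nrow(x$log), x$side_px,
    x$log$loss[nrow(x$log)]))
  invisible(x)
}

predict_probs <- function(model, images) {
  inp <- prepare_inputs(images, model$cfg)
  inp$stats <- scale(inp$stats, model$stats_center, model$stats_scale)
  p <- cnn_forward(model$par, inp$cols, inp$nw, inp$n, inp$stats)$p
  colnames(p) <- c(model$classes, "fraction")
  p
}

#' Classify patches and paint the coarse prediction mask
#'
#' Applies the trained classifier to a patch set; a class is predicted
#' present when its probability reaches the decision threshold. The coarse
#' mask paints the full square footprint of every blueberry-positive patch.
#'
#' @param model a `berry_classifier`.
#' @param patches a `patch_set` with the same patch side the model was
#'   trained on.
#' @param scene_dim optional c(H, W); defaults to the grid bounding box.
#' @return list of class `prediction_mask`: `pred` (meta plus per-class
#'   probabilities, `blueberry_pos`, `fraction_pred`), `mask` (logical
#'   HxW), `granularity` tag built from the patch side.
#' @export
predict_patches <- function(model, patches, scene_dim = NULL) {
  side <- patches$meta$side_px[1]
  if (!identical(as.integer(side), as.integer(model$side_px)))
    stop_bbm("patch side %d does not match the side the model was trained on (%d)",
             side, model$side_px)
  probs <- predict_probs(model, patches$images)
  meta <- patches$meta
  meta$blueberry_prob <- probs[, "blueberry"]
  meta$fraction_pred <- probs[, "fraction"]
  meta$blueberry_pos <- probs[, "blueberry"] >= model$cfg$threshold
  if (is.null(scene_dim))
    scene_dim <- c(max(meta$row0) + side, max(meta$col0) + side)
  mask <- matrix(FALSE, scene_dim[1], scene_dim[2])
  for (i in which(meta$blueberry_pos)) {
    mask[(meta$row0[i] + 1):(meta$row0[i] + side),
         (meta$col0[i] + 1):(meta$col0[i] + side)] <- TRUE
  }
  structure(list(pred = meta, probs = probs, mask = mask,
                 granularity = sprintf("coarse_%d", side),
                 site_id = meta$site_id[1]),
            class = "prediction_mask")
}

#' Coarse-to-fine refinement of positive patches
#'
#' Splits every blueberry-positive coarse patch into a 4 x 4 grid of
#' quarter-side sub-patches, resamples each to the network input size and
#' re-classifies it; the refined mask is the union of positive sub-patch
#' footprints and is therefore always a subset of the coarse mask.
#'
#' @param model the same `berry_classifier` used for the coarse pass.
#' @param coarse a `prediction_mask` from [predict_patches()].
#' @param patches the `patch_set` the coarse prediction was computed on.
#' @return a `prediction_mask` with `granularity = "refined_<side/4>"`; its
#'   `pred` table has one row per evaluated sub-patch.
#' @export
refine_predictions <- function(model, coarse, patches) {
  side <- patches$meta$side_px[1]
  sub <- side %/% 4L
  pos <- which(coarse$pred$blueberry_pos)
  mask <- matrix(FALSE, nrow(coarse$mask), ncol(coarse$mask))
  rows <- list()
  for (i in pos) {
    img <- patches$images[[i]]
    subs <- list(); orig <- list()
    for (a in 0:3) for (b in 0:3) {
      subs[[length(subs) + 1L]] <-
        img[(a * sub + 1):((a + 1) * sub), (b * sub + 1):((b + 1) * sub), ,
            drop = FALSE]
      orig[[length(orig) + 1L]] <- c(coarse$pred$row0[i] + a * sub,
                                     coarse$pred$col0[i] + b * sub)
    }
    pr <- predict_probs(model, subs)
    pos_sub <- pr[, "blueberry"] >= model$cfg$threshold
    for (j in seq_along(subs)) {
      if (pos_sub[j]) {
        mask[(orig[[j]][1] + 1):(orig[[j]][1] + sub),
             (orig[[j]][2] + 1):(orig[[j]][2] + sub)] <- TRUE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        parent_patch = coarse$pred$patch_id[i],
        row0 = orig[[j]][1], col0 = orig[[j]][2], side_px = sub,
        blueberry_prob = pr[j, "blueberry"], blueberry_pos = pos_sub[j])
    }
  }
  pred <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parent_patch = integer(0), row0 = integer(0),
               col0 = integer(0), side_px = integer(0),
               blueberry_prob = numeric(0), blueberry_pos = logical(0))
  structure(list(pred = pred, mask = mask,
                 granularity = sprintf("refined_%d", sub),
                 site_id = coarse$site_id),
            class = "prediction_mask")
}
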