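#' Training configuration for the patch classifier
#'
#' Bundles the data-balance and optimisation settings. The class-imbalance
#' treatment follows the survey protocol: the blueberry presence loss is
#' weighted eight times the soil class and four times the remaining
#' classes, each blueberry patch is upsampled with 12 augmented copies, and
#' soil-only patches are downsampled to 50%.
#'
#' @param backbone `"tiny_cnn"` — a small convolutional network (one 5x5
#'   filter bank, global max + mean pooling, small dense head) trained
#'   inside the package. A large pretrained backbone would slot into the
#'   same interface but none ships with this package.
#' @param weights_mode `"unfrozen"` trains all layers; `"frozen"` keeps the
#'   convolutional filter bank at its random initialisation and trains only
#'   the dense head.
#' @param class_loss_weights named positive weights per class.
#' @param blueberry_upsample_factor augmented copies added per blueberry
#'   patch (12).
#' @param soil_downsample_fraction fraction of soil-only patches kept (0.5).
#' @param augmentations transforms cycled through when upsampling.
#' @param epochs,learning_rate,batch_size Adam optimisation settings;
#'   `batch_size = NULL` trains full-batch (exact deterministic steps at
#'   the patch counts this workflow sees).
#' @param hidden_units width of the dense hidden layer.
#' @param conv_filters,kernel_px,conv_stride convolutional bank geometry.
#' @param input_px network input side; patches are resampled to
#'   `input_px` x `input_px` before entering the network.
#' @param threshold positive-decision probability threshold per class.
#' @param fraction_loss_weight weight of the blueberry-fraction regression
#'   term relative to the presence loss.
#' @param weight_decay decoupled L2 weight decay applied to all weight
#'   matrices each optimisation step (regularises the small network toward
#'   colour-rule solutions that transfer across mosaics).
#' @param swa_fraction fraction of final epochs whose weights are averaged
#'   (stochastic weight averaging over the cosine-decayed tail); 0 disables.
#' @param ridge_lambda per-observation ridge penalty of the stage-1
#'   penalized-logistic fit of the linear colour-descriptor path.
#' @param seed seed for initialisation and shuffling.
#' @return object of class `train_config`.
#' @export
train_config <- function(backbone = "tiny_cnn",
                         weights_mode = c("unfrozen", "frozen"),
                         class_loss_weights = c(blueberry = 8, tree = 2,
                                                yellow_bush = 2, soil = 1,
                                                water = 2, dead_tree = 2),
                         blueberry_upsample_factor = 12L,
                         soil_downsample_fraction = 0.5,
                         augmentations = PATCH_TRANSFORMS,
                         epochs = 350L, learning_rate = 0.005,
                         batch_size = NULL, hidden_units = 32L,
                         conv_filters = 16L, kernel_px = 5L,
                         conv_stride = 2L,
                         input_px = 24L, threshold = 0.5,
                         fraction_loss_weight = 1.0, weight_decay = 0.1,
                         swa_fraction = 0.25, ridge_lambda = 0.01,
                         seed = 1L) {
  weights_mode <- match.arg(weights_mode)
  if (!identical(backbone, "tiny_cnn"))
    stop_bbm(paste0("backbone '%s' is not available in this package; ",
                    "'tiny_cnn' is the supported backbone"), backbone)
  if (any(class_loss_weights <= 0)) stop_bbm("class weights must be positive")
  if (soil_downsample_fraction <= 0 || soil_downsample_fraction > 1)
    stop_bbm("soil_downsample_fraction must be in (0, 1]")
  stopifnot(all(augmentations %in% PATCH_TRANSFORMS))
  cfg <- list(backbone = backbone, weights_mode = weights_mode,
              class_loss_weights = class_loss_weights[SCENE_CLASSES],
              blueberry_upsample_factor = as.integer(blueberry_upsample_factor),
              soil_downsample_fraction = soil_downsample_fraction,
              augmentations = augmentations,
              epochs = as.integer(epochs), learning_rate = learning_rate,
              batch_size = if (is.null(batch_size)) NULL
                           else as.integer(batch_size),
              hidden_units = as.integer(hidden_units),
              conv_filters = as.integer(conv_filters),
              kernel_px = as.integer(kernel_px),
              conv_stride = as.integer(conv_stride),
              input_px = as.integer(input_px), threshold = threshold,
              fraction_loss_weight = fraction_loss_weight,
              weight_decay = weight_decay,
              swa_fraction = swa_fraction,
              ridge_lambda = ridge_lambda,
              seed = as.integer(seed))
  class(cfg) <- "train_config"
  cfg
}

#' Rebalance a training patch set
#'
#' Every blueberry-containing patch contributes its original plus
#' `blueberry_upsample_factor` augmented copies (transforms cycled, seeded);
#' soil-only patches are randomly downsampled to
#' `soil_downsample_fraction`; all other patches pass through unchanged.
#' Balancing is a training-time device only and refuses to run on
#' validation or test splits.
#'
#' @param patches a `patch_set`.
#' @param cfg a [train_config()].
#' @param split must be `"train"`.
#' @return a rebalanced `patch_set`; augmented copies get `augmented = TRUE`
#'   in the meta table.
#' @export
balance_dataset <- function(patches, cfg, split = "train") {
  if (!identical(split, "train"))
    stop_bbm("balancing is only applied to the training split, not '%s'",
             split)
  meta <- patches$meta
  is_bb <- meta$blueberry_fraction > 0
  is_soil_only <- vapply(meta$labels, function(l) identical(l, "soil"), TRUE)
  if (!any(is_bb))
    warning("no blueberry patches present; upsampling is a no-op")
  keep_soil <- with_seed(derive_seed(cfg$seed, "soil_downsample"), {
    idx <- which(is_soil_only)
    sort(sample(idx, round(length(idx) * cfg$soil_downsample_fraction)))
  })
  keep <- sort(c(which(!is_soil_only), keep_soil))
  out <- subset_patches(patches, keep)
  out$meta$augmented <- FALSE
  bb_idx <- which(out$meta$blueberry_fraction > 0)
  if (length(bb_idx) && cfg$blueberry_upsample_factor > 0L) {
    aug_meta <- list(); aug_img <- list()
    for (i in bb_idx) {
      for (k in seq_len(cfg$blueberry_upsample_factor)) {
        tr <- cfg$augmentations[(k - 1L) %% length(cfg$augmentations) + 1L]
        seed_k <- derive_seed(cfg$seed, sprintf("aug_%d_%d", i, k))
        m <- out$meta[i, , drop = FALSE]
        m$augmented <- TRUE
        aug_meta[[length(aug_meta) + 1L]] <- m
        aug_img[[length(aug_img) + 1L]] <-
          augment_patch(out$images[[i]], tr, seed = seed_k)
      }
    }
    out <- new_patch_set(rbind(out$meta, do.call(rbind, aug_meta)),
                         c(out$images, aug_img))
  }
  out$meta$patch_id <- seq_len(nrow(out$meta))
  out
}
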