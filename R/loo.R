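#' Leave-one-mosaic-out cross-validation of the patch pipeline
#'
#' Whole orthomosaics rotate through the train / validation / test roles so
#' that no patch of the test mosaic ever influences training (mosaic-level
#' split against spatial data leakage). For every fold the training mosaics
#' are tiled and rebalanced, the classifier is trained, and the held-out
#' mosaic is evaluated unbalanced: patch-level blueberry TPR and accuracy,
#' and pixel-level Dice / ground-truth cover for the coarse and refined
#' masks. Pooled metrics are the arithmetic mean over test folds, with
#' count-pooled (micro) patch metrics reported alongside.
#'
#' @param scenes list of at least three `orthomosaic_scene`s with distinct
#'   site ids.
#' @param cfg a [train_config()].
#' @param side_px coarse patch side.
#' @return list of class `loo_result`: `folds` (per fold: roles, model,
#'   patch metrics, coarse/refined mask metrics) and `pooled`.
#' @export
leave_one_mosaic_out <- function(scenes, cfg, side_px = 100L) {
  if (length(scenes) < 3L)
    stop_bbm("leave-one-mosaic-out needs >= 3 scenes, got %d", length(scenes))
  ids <- vapply(scenes, `[[`, "", "site_id")
  if (anyDuplicated(ids)) stop_bbm("scene site ids must be distinct")
  n <- length(scenes)
  tiles <- lapply(scenes, tile_orthomosaic, side_px = side_px)
  folds <- vector("list", n)
  for (f in seq_len(n)) {
    test_i <- f
    val_i <- f %% n + 1L
    train_i <- setdiff(seq_len(n), c(test_i, val_i))
    train_ps <- do.call(bind_patches, tiles[train_i])
    train_bal <- balance_dataset(train_ps, cfg, split = "train")
    calib <- do.call(bind_patches, lapply(scenes[train_i], refinement_tiles,
                                          side_px = side_px))
    calib$meta$augmented <- FALSE
    model <- train_classifier(bind_patches(train_bal, calib),
                              tiles[[val_i]], cfg)
    coarse <- predict_patches(model, tiles[[test_i]],
                              scene_dim = dim(scenes[[test_i]]$dem))
    refined <- refine_predictions(model, coarse, tiles[[test_i]])
    truth_patch <- tiles[[test_i]]$meta$blueberry_fraction > 0
    cc <- confusion_counts(coarse$pred$blueberry_pos, truth_patch, "patch")
    truth_mask <- scenes[[test_i]]$masks$blueberry
    folds[[f]] <- list(
      roles = c(train = paste(ids[train_i], collapse = "+"),
                val = ids[val_i], test = ids[test_i]),
      model = model,
      patch_counts = cc,
      patch_metrics = metrics(cc),
      coarse = evaluate_mask(coarse, truth_mask),
      refined = evaluate_mask(refined, truth_mask))
  }
  get_f <- function(path) vapply(folds, function(x) {
    v <- x; for (p in path) v <- v[[p]]; as.numeric(v)
  }, 0)
  tp <- sum(get_f(c("patch_counts", "TP"))); fn <- sum(get_f(c("patch_counts", "FN")))
  fp <- sum(get_f(c("patch_counts", "FP"))); tn <- sum(get_f(c("patch_counts", "TN")))
  pooled <- list(
    tpr = mean(get_f(c("patch_metrics", "tpr"))),
    acc = mean(get_f(c("patch_metrics", "acc"))),
    dice_coarse = mean(get_f(c("coarse", "dice"))),
    dice_refined = mean(get_f(c("refined", "dice"))),
    gt_cover_coarse = mean(get_f(c("coarse", "gt_cover"))),
    gt_cover_refined = mean(get_f(c("refined", "gt_cover"))),
    micro = list(tpr = tp / (tp + fn),
                 acc = (tp + tn) / (tp + tn + fp + fn)))
  structure(list(folds = folds, pooled = pooled, site_ids = ids),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("leave-one-mosaic-out over %d sites\n", length(x$folds)))
  for (f in seq_along(x$folds)) {
    fd <- x$folds[[f]]
    cat(sprintf("  fold %d (test %s): TPR %.3f ACC %.3f | Dice %.3f -> %.3f | cover %.3f -> %.3f\n",
                f, fd$roles[["test"]], fd$patch_metrics$tpr,
                fd$patch_metrics$acc, fd$coarse$dice, fd$refined$dice,
                fd$coarse$gt_cover, fd$refined$gt_cover))
  }
  cat(sprintf("  pooled: TPR %.3f ACC %.3f | Dice %.3f -> %.3f\n",
              x$pooled$tpr, x$pooled$acc, x$pooled$dice_coarse,
              x$pooled$dice_refined))
  invisible(x)
}

#' Refinement-scale calibration tiles
#'
#' Quarter-side tiles cut from every coarse tile of a scene that contains
#' blueberry pixels. The refinement pass re-classifies quarter tiles whose
#' content distribution (up to fully bush-covered crops) never occurs among
#' full coarse tiles; a from-scratch backbone has no pretrained scale
#' invariance to bridge that gap, so these tiles are added to the training
#' set of each fold (training mosaics only — the mosaic-level split is
#' unaffected).
#'
#' @param scene an `orthomosaic_scene`.
#' @param side_px coarse tile side.
#' @return a `patch_set` of side `side_px / 4` tiles.
#' @export
refinement_tiles <- function(scene, side_px = 100L) {
  sub <- side_px %/% 4L
  coarse <- tile_orthomosaic(scene, side_px)
  fine <- tile_orthomosaic(scene, sub)
  parent_row <- fine$meta$row0 %/% side_px
  parent_col <- fine$meta$col0 %/% side_px
  key <- paste(parent_row, parent_col)
  pos_key <- paste(coarse$meta$row0 %/% side_px, coarse$meta$col0 %/% side_px)[
    coarse$meta$blueberry_fraction > 0]
  subset_patches(fine, which(key %in% pos_key))
}
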