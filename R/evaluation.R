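#' Confusion counts at patch or pixel granularity
#'
#' @param predicted,truth logical vectors or matrices of identical shape:
#'   per-patch blueberry presence, or per-pixel membership in the predicted
#'   mask / annotated ground truth.
#' @param granularity `"patch"` or `"pixel"` (bookkeeping tag).
#' @return object of class `confusion_counts` with integer `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion_counts <- function(predicted, truth,
                             granularity = c("patch", "pixel")) {
  granularity <- match.arg(granularity)
  if (!identical(dim(predicted), dim(truth)) ||
      length(predicted) != length(truth))
    stop_bbm("predicted and truth are not aligned")
  p <- as.logical(predicted); t <- as.logical(truth)
  out <- list(TP = sum(p & t), FP = sum(p & !t),
              TN = sum(!p & !t), FN = sum(!p & t),
              granularity = granularity)
  class(out) <- "confusion_counts"
  out
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion (%s): TP %d  FP %d  TN %d  FN %d\n",
              x$granularity, x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Sensitivity, accuracy and Dice from confusion counts
#'
#' TPR = TP / (TP + FN), ACC = (TP + TN) / (TP + TN + FP + FN),
#' Dice = 2 TP / (2 TP + FP + FN). A metric whose denominator is zero is
#' undefined and reported as NA.
#'
#' @param counts a [confusion_counts()] object.
#' @return list `tpr`, `acc`, `dice` (NA when undefined) plus the counts.
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  with(counts, list(
    tpr = safe(TP, TP + FN),
    acc = safe(TP + TN, TP + TN + FP + FN),
    dice = safe(2 * TP, 2 * TP + FP + FN),
    counts = counts))
}

#' Fraction of ground-truth positives covered by a mask
#'
#' @param mask logical prediction mask.
#' @param truth logical ground-truth raster of the same shape.
#' @return |truth intersect mask| / |truth|; NA (undefined, with a warning)
#'   when the truth is empty.
#' @export
gt_cover <- function(mask, truth) {
  if (!identical(dim(mask), dim(truth)))
    stop_bbm("mask and truth are not aligned")
  n <- sum(truth)
  if (n == 0L) {
    warning("ground truth is empty; gt_cover undefined")
    return(NA_real_)
  }
  sum(mask & truth) / n
}

#' Pixel-level evaluation of a prediction mask
#'
#' Treats every pixel inside a predicted patch footprint as positive and
#' every unannotated pixel as negative ground truth.
#'
#' @param prediction a `prediction_mask`.
#' @param truth_mask logical blueberry annotation raster.
#' @return list with the pixel [metrics()] and `gt_cover`.
#' @export
evaluate_mask <- function(prediction, truth_mask) {
  cc <- confusion_counts(prediction$mask, truth_mask, "pixel")
  c(metrics(cc), list(gt_cover = gt_cover(prediction$mask, truth_mask),
                      granularity = prediction$granularity))
}

#' Assemble the per-site coarse/refined comparison table
#'
#' One row per site and mask type with pixel Dice and ground-truth cover —
#' the shape of the refinement evaluation table of the survey.
#'
#' @param results named list (per site) of lists with `coarse` and
#'   `refined` entries as returned by [evaluate_mask()].
#' @return data.frame `site`, `mask_type`, `dice`, `gt_cover`.
#' @export
refinement_table <- function(results) {
  rows <- lapply(names(results), function(site) {
    data.frame(site = site,
               mask_type = c("coarse", "refined"),
               dice = c(results[[site]]$coarse$dice,
                        results[[site]]$refined$dice),
               gt_cover = c(results[[site]]$coarse$gt_cover,
                            results[[site]]$refined$gt_cover))
  })
  do.call(rbind, rows)
}
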