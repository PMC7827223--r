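#!/usr/bin/env Rscript
# Stage 5: assemble the run report from the stage outputs.

inv <- jsonlite::read_json("results/02_inventory.json", simplifyVector = TRUE)
clust <- read.csv("results/03_cluster_table.csv")
pers <- jsonlite::read_json("results/03_persistence.json", simplifyVector = TRUE)
folds <- read.csv("results/04_fold_metrics.csv")

report <- list(
  inventory = inv$summary,
  clustering = clust,
  fused_fraction_radii_px = pers$fused_fraction_radii_px,
  classifier = list(
    pooled_tpr = mean(folds$tpr), pooled_acc = mean(folds$acc),
    dice_coarse = mean(folds$dice_coarse),
    dice_refined = mean(folds$dice_refined),
    gt_cover_coarse = mean(folds$gt_cover_coarse),
    gt_cover_refined = mean(folds$gt_cover_refined)))
jsonlite::write_json(report, "results/05_report.json", auto_unbox = TRUE,
                     digits = NA)
cat("pooled blueberry TPR", round(100 * report$classifier$pooled_tpr, 2),
    "%, accuracy", round(100 * report$classifier$pooled_acc, 2), "%\n")
cat("Dice", round(report$classifier$dice_coarse, 3), "->",
    round(report$classifier$dice_refined, 3),
    "; GT cover", round(report$classifier$gt_cover_coarse, 3), "->",
    round(report$classifier$gt_cover_refined, 3), "\n")
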