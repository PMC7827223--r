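#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study sites.
#
# One default-condition scene (the allometry/spread site, hard palette with
# reddish-soil confounders) and the three-mosaic classifier corpus. The
# first corpus mosaic is exported to disk as PNG/TSV/CSV with a manifest so
# later stages can demonstrate the file round trip.

library(blueberrymap)
seed <- 1L
dir.create("results/scenes", recursive = TRUE, showWarnings = FALSE)

scene <- generate_scene(scene_config(seed = seed), site_id = "A1")
corpus <- scene_corpus(seed = seed)

write_scene(scene, "results/scenes")
fr <- data.frame(class = names(scene$truth$class_px),
                 pixels = as.integer(scene$truth$class_px),
                 pct_of_site = round(100 * scene$truth$class_px /
                                     length(scene$dem), 2))
write.csv(fr, "results/01_class_fractions.csv", row.names = FALSE)

cat("site A1:", nrow(scene$truth$planted), "bushes planted,",
    scene$truth$merged_component_count, "mask components;",
    sprintf("blueberry %.2f%% of area\n", 100 * mean(scene$masks$blueberry)))
cat("corpus:", length(corpus), "mosaics at",
    paste(dim(corpus[[1]]$dem), collapse = " x "), "px\n")
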