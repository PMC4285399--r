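#!/usr/bin/env Rscript
# Stage 3 — pattern-expression scoring on the planted voxel brain.
#
# Simulates the desk-scale voxel brain (signature, m1 and m2 clusters plus
# noise background), scores every per-trial beta volume against the
# signature weight map by the dot product over its support, and extracts
# 6-mm sphere ROI averages at the planted m1/m2 cluster centers. Scored
# responses are appended to the trial table for the mediation stages.

library(painpath)

seed <- 20260928L
dataset <- read.csv("results/trial_dataset.csv")

brain <- simulate_voxel_brain(dataset, seed = seed)
w <- brain$signature$weights[brain$signature$mask]
sig_cols <- which(as.integer(brain$labels) == 1L)
dataset$sig_scored <- as.numeric(brain$betas[, sig_cols, drop = FALSE] %*% w)

cat("signature score vs simulated signature response: r =",
    round(cor(dataset$sig_scored, dataset$sig), 3), "\n")

# 6-mm sphere ROI average centred on one m2-cluster voxel, first trial
m2_center_vox <- which(brain$labels == 3L, arr.ind = TRUE)[14, ]
center_mm <- as.numeric(brain$affine[1:3, 1:3] %*% (m2_center_vox - 1) +
                          brain$affine[1:3, 4])
vol1 <- map_to_volume(brain$betas[1, ], brain$mask)
cat("6-mm sphere average at the m2 center (trial 1):",
    round(roi_sphere_average(vol1, center_mm, 6, brain$affine), 3),
    "| simulated m2 value:", round(dataset$m2[1], 3), "\n")

write.csv(dataset, "results/trial_dataset_scored.csv", row.names = FALSE)
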