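#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study.
#
# Builds the nine-run thermal stimulation design for 30 subjects (55
# counterbalanced passive trials over runs 1/2/4/8/9, two shifted-context
# runs, two regulation runs of 10 trials each) and simulates trial-level
# pain ratings, a signature-like scalar response driven by temperature only,
# and an m1 -> m2 mediator chain driven by regulation only, all with known
# ground-truth path coefficients.

library(painpath)

seed <- 20260926L
dir.create("results", showWarnings = FALSE)

truth <- ground_truth_params()
design <- generate_design(30, seed = seed)
dataset <- simulate_trial_responses(design, truth, seed = seed + 1L)

write_ground_truth(truth, "results/ground_truth.yaml")
write.csv(dataset, "results/trial_dataset.csv", row.names = FALSE)

# sanity prints: design counts a reader can check against the task structure
cb <- dataset[dataset$run %in% c(1, 2, 4, 8, 9), ]
cat("passive counterbalanced trials per subject:",
    nrow(cb) / length(unique(dataset$subject)), "\n")
cat("every ordered transition occurs twice:",
    all(transition_table(dataset, 1) == 2), "\n")
cat("rating range:", round(range(dataset$rating), 1), "\n")
cat("trials judged painful:", round(mean(dataset$decision), 3), "\n")
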