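#!/usr/bin/env Rscript
# Stage 4 — behavioral multilevel GLMs.
#
# Two-stage (summary statistics) multilevel models of trial behavior:
# per-subject OLS of pain ratings on regulation code (+1/0/-1), centred
# temperature and their interaction, then a group-level t test on the
# subject coefficients with the regulation-run-order covariate; and the
# logistic counterpart for the pain/no-pain decision, dropping one-class
# and separated subjects.

library(painpath)

dataset <- read.csv("results/trial_dataset_scored.csv")

lin <- multilevel_behavioral_glm(dataset, outcome = "rating",
                                 family = "linear")
cat("Linear model (pain ratings):\n")
print(lin, digits = 3)

logi <- multilevel_behavioral_glm(dataset, outcome = "decision",
                                  family = "logistic")
cat("\nLogistic model (pain decision):\n")
print(logi, digits = 3)

write.csv(lin, "results/behavioral_linear.csv", row.names = FALSE)
write.csv(logi, "results/behavioral_logistic.csv", row.names = FALSE)
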