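#!/usr/bin/env Rscript
# Simulate the study cohort: 21 participants (11 lower / 10 higher visual
# degradation), each driving one 390 s session under optimal and one under
# degraded vision, 120 Hz eye and head traces, 7 x 6 s visual-search trials.
# Writes the ground-truth parameter table and one example session file.
# Later scripts re-simulate the same cohort deterministically from the same
# master seed instead of storing ~150 MB of traces.

library(gazescan)

MASTER_SEED <- 20260930L
dir.create("results", showWarnings = FALSE)

cohort <- simulate_cohort(cohort_spec(master_seed = MASTER_SEED))
write.csv(cohort$truth, "results/cohort_ground_truth.csv", row.names = FALSE)

ex <- cohort$sessions[[1]]
write_session(ex, "results/example_session.csv")

cat(sprintf("simulated %d sessions (%d participants x 2 conditions)\n",
            length(cohort$sessions), nrow(cohort$truth) / 2))
cat(sprintf("example session: %s, %s vision, %d samples, %d trials\n",
            ex$meta$participant, ex$meta$condition, length(ex$eye),
            nrow(ex$trials)))
cat("ground truth ->", "results/cohort_ground_truth.csv\n")
cat("head gain (yaw), mean by cell:\n")
print(aggregate(head_gain_yaw ~ condition + group, cohort$truth, mean))
cat("state randomness, mean by cell:\n")
print(aggregate(state_randomness ~ condition + group, cohort$truth, mean))
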