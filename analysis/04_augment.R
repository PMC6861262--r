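#!/usr/bin/env Rscript
# Stage 4: human-in-the-loop augmentation.
#
# Machine diagnoses with probability inside the closed low-confidence
# band [0.025, 0.055] around the 4.008% threshold are deferred to each
# group's swarm; the augmented model keeps machine diagnoses elsewhere.
# Reports machine-only, swarm-only and augmented performance on the
# pooled (case x group) evaluation.

suppressPackageStartupMessages(library(swarmdx))

SEED <- 1234
ML_T <- 0.04008
BAND <- c(0.025, 0.055)

tab <- read_case_table("results/case_table.csv", kinds = c(machine = "ml"))
sw_tab <- read_case_table("results/swarm_table.csv",
                          kinds = c(swarm_a = "swarm", swarm_b = "swarm"))
cases <- tab$cases
ml <- tab$diagnoses$machine

plan <- route(ml, band = BAND, threshold = ML_T)
cat(sprintf("routed %d of %d cases to the swarm (%d positive-predicted, %d negative-predicted)\n",
            length(plan$routed), nrow(cases),
            length(plan$pos_pred), length(plan$neg_pred)))

aug_a <- augment(ml, sw_tab$diagnoses$swarm_a, plan, source_id = "augmented_a")
aug_b <- augment(ml, sw_tab$diagnoses$swarm_b, plan, source_id = "augmented_b")
aug_pool <- pool_groups(cases, list(A = aug_a, B = aug_b),
                        source_id = "augmented")
sw_pool <- pool_groups(cases, list(A = sw_tab$diagnoses$swarm_a,
                                   B = sw_tab$diagnoses$swarm_b),
                       source_id = "swarm_combined")
ml_pool <- pool_groups(cases, list(A = ml, B = ml),
                       source_id = "machine_pooled")

set.seed(SEED + 404L)
report <- rbind(
  metric_table(list(ml = ml_pool$diag), ml_pool$cases,
               thresholds = c(machine_pooled = ML_T), n_boot = 1000),
  metric_table(list(sw = sw_pool$diag), sw_pool$cases, n_boot = 1000),
  metric_table(list(aug = aug_pool$diag), aug_pool$cases, n_boot = 1000))
write_report(report, "results/augmented_report")

acc <- function(d, cs, t = 0.5) {
  pred <- if (d$kind == "augmented") predictions_of(d) else binarize(d, t)
  100 * mean(pred[cs$case_id] == cs$label)
}
cat(sprintf("machine-only : %.0f%% correct\n",
            acc(ml_pool$diag, ml_pool$cases, ML_T)))
cat(sprintf("swarm-only   : %.0f%% correct\n", acc(sw_pool$diag, sw_pool$cases)))
cat(sprintf("augmented    : %.0f%% correct\n", acc(aug_pool$diag, aug_pool$cases)))
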