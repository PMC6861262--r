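#!/usr/bin/env Rscript
# Stage 3: diagnostic performance tables.
#
# Computes the five study metrics (percent correct, MAE, Brier, rank
# AUC, F1) plus sensitivity/specificity with 95% percentile-bootstrap
# CIs for: individual readers (averaged), crowd mean, crowd majority,
# each group's swarm, the pooled combined swarm, and the machine model.

suppressPackageStartupMessages(library(swarmdx))

SEED <- 1234
ML_T <- 0.04008

tab <- read_case_table("results/case_table.csv", kinds = c(machine = "ml"))
sw_tab <- read_case_table("results/swarm_table.csv",
                          kinds = c(swarm_a = "swarm", swarm_b = "swarm"))
cases <- tab$cases
readers_a <- tab$diagnoses[grep("^reader_a_", names(tab$diagnoses))]
readers_b <- tab$diagnoses[grep("^reader_b_", names(tab$diagnoses))]
swarm_a <- sw_tab$diagnoses$swarm_a
swarm_b <- sw_tab$diagnoses$swarm_b

combined <- pool_groups(cases, list(A = swarm_a, B = swarm_b),
                        source_id = "swarm_combined")

sources <- list(
  machine = tab$diagnoses$machine,
  crowd_mean_a = crowd_mean(readers_a, "crowd_mean_a"),
  crowd_mean_b = crowd_mean(readers_b, "crowd_mean_b"),
  crowd_majority_a = crowd_majority(readers_a, source_id = "crowd_majority_a"),
  crowd_majority_b = crowd_majority(readers_b, source_id = "crowd_majority_b"),
  swarm_a = swarm_a, swarm_b = swarm_b)

set.seed(SEED + 303L)
report <- rbind(
  metric_table(sources, cases, thresholds = c(machine = ML_T),
               n_boot = 1000, level = 0.95),
  metric_table(list(swarm_combined = combined$diag), combined$cases,
               n_boot = 1000, level = 0.95))
write_report(report, "results/metric_report")

# individual averages, both combined-weighting conventions
groups <- list(A = readers_a, B = readers_b)
ind <- data.frame(
  metric = c("percent_correct", "sensitivity", "specificity"),
  pooled = sapply(c("percent_correct", "sensitivity", "specificity"),
                  function(m) individual_average(groups, cases, m)),
  group_mean = sapply(c("percent_correct", "sensitivity", "specificity"),
                      function(m) individual_average(groups, cases, m,
                                                     weighting = "group_mean")))
utils::write.csv(ind, "results/individual_average.csv", row.names = FALSE)

pc <- subset(report, metric == "percent_correct")
cat("percent correct [95% CI]:\n")
for (i in seq_len(nrow(pc)))
  cat(sprintf("  %-18s %5.1f [%.1f, %.1f]\n", pc$source_id[i],
              pc$value[i], pc$ci_lo[i], pc$ci_hi[i]))
cat(sprintf("individual average (pooled over 13 readers): %.1f%% correct\n",
            ind$pooled[1]))
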