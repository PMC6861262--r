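#!/usr/bin/env Rscript
# Stage 2: simulate one real-time swarm session per reader group.
#
# Each of the 50 cases is deliberated by the group as a closed-loop
# swarm; the squared-impulse interpolation turns the session's per-bin
# impulse profile into a refined probability. Per-case traces are
# persisted as JSON.

suppressPackageStartupMessages(library(swarmdx))

SEED <- 1234
tab <- read_case_table("results/case_table.csv",
                       kinds = c(machine = "ml"))
readers_a <- tab$diagnoses[grep("^reader_a_", names(tab$diagnoses))]
readers_b <- tab$diagnoses[grep("^reader_b_", names(tab$diagnoses))]

swarm_a <- run_swarm_session(tab$cases, readers_a,
                             config = swarm_config(seed = SEED + 101L),
                             source_id = "swarm_a",
                             trace_dir = "results/traces/group_a")
swarm_b <- run_swarm_session(tab$cases, readers_b,
                             config = swarm_config(seed = SEED + 202L),
                             source_id = "swarm_b",
                             trace_dir = "results/traces/group_b")

write_case_table(tab$cases, list(swarm_a, swarm_b),
                 "results/swarm_table.csv")

for (sw in list(swarm_a, swarm_b)) {
  cm <- confusion(binarize(sw, 0.5), tab$cases)
  cat(sprintf("%s: %d/50 correct at the 50%% cutoff (sens %.2f, spec %.2f)\n",
              sw$source_id, cm$tp + cm$tn, sensitivity(cm),
              specificity(cm)))
}
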