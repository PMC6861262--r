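#!/usr/bin/env Rscript
# Stage 1: generate the study-like synthetic dataset.
#
# 50 chest-radiograph-like cases (20 positive, 30 negative for
# pneumonia), a 7-reader panel (group A) and a 6-reader panel (group B)
# operating near sensitivity 0.65 / specificity 0.85 at the human 50%
# cutoff, and a machine model calibrated to sensitivity 0.90 /
# specificity 0.767 at its 4.008% discrimination threshold.

suppressPackageStartupMessages(library(swarmdx))

SEED <- 1234
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

sc <- study_scenario(seed = SEED)
write_case_table(sc$cases,
                 c(sc$readers_a, sc$readers_b, list(sc$ml)),
                 file.path(out_dir, "case_table.csv"))

manifest <- list(
  seed = SEED, n = nrow(sc$cases),
  n_positive = n_positive(sc$cases), n_negative = n_negative(sc$cases),
  readers_a = vapply(sc$readers_a, `[[`, "", "source_id"),
  readers_b = vapply(sc$readers_b, `[[`, "", "source_id"),
  machine = sc$ml$source_id,
  reader_op = unclass(sc$reader_op), machine_op = unclass(sc$machine_op))
jsonlite::write_json(manifest, file.path(out_dir, "scenario.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("wrote %d cases (%d+/%d-) with %d readers and 1 machine source\n",
            nrow(sc$cases), n_positive(sc$cases), n_negative(sc$cases),
            length(sc$readers_a) + length(sc$readers_b)))
cat(sprintf("machine probabilities: median %.3f (compressed near t = %.5f)\n",
            median(sc$ml$probabilities), sc$machine_op$threshold))
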