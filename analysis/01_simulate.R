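#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates five subjects under the default grasp scenario (50 trials per
# condition: no movement, power grasp, precision grasp; 8-channel montage
# at 250 Hz; alpha/beta bursts over C3/C4 from 0.3 s post-onset, power >
# precision > none) and writes each subject to the epochs interchange
# layout under results/epochs/.

library(graspwave)

root_seed <- 42L
out_dir <- "results/epochs"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

for (si in 1:5) {
  sid <- sprintf("S%d", si)
  sim <- default_grasp_scenario(rng_seed = root_seed * 100L + si)
  epochs <- simulate_subject(sim, subject_id = sid)
  write_epochs(epochs, file.path(out_dir, sid))
  message(sprintf("%s: %d trials (%s)", sid, length(epochs$labels),
                  paste(names(table(epochs$labels)),
                        table(epochs$labels), collapse = ", ",
                        sep = "=")))
}
message("wrote ", out_dir)
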