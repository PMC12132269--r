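#!/usr/bin/env Rscript
# Stage 2 — preprocessing.
#
# Band-pass filters each subject's epochs to 1-30 Hz (zero-phase
# Butterworth), subtracts the 200 ms pre-onset baseline, and z-scores each
# channel within subject. Writes preprocessed epochs to
# results/preprocessed/.

library(graspwave)

cfg <- pipeline_config()
in_dir <- "results/epochs"
out_dir <- "results/preprocessed"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

for (sid in list.dirs(in_dir, recursive = FALSE, full.names = FALSE)) {
  epochs <- read_epochs(file.path(in_dir, sid))
  clean <- preprocess(epochs, cfg)
  write_epochs(clean, file.path(out_dir, sid))
  message(sprintf("%s: filtered %g-%g Hz, baseline [%g, %g) s, z-scored",
                  sid, cfg$bandpass_lo_hz, cfg$bandpass_hi_hz,
                  cfg$baseline_window_s[1], cfg$baseline_window_s[2]))
}
message("wrote ", out_dir)
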