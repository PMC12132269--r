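#!/usr/bin/env Rscript
# Stage 4 — statistical wavelet features.
#
# For every subject: Morlet transform, then mean / variance / skewness /
# kurtosis of the wavelet amplitude per channel-band over the [0, 0.8) s
# post-onset window — 8 channels x 4 bands x 4 statistics = 128 features
# per trial. Writes one CSV per subject under results/features/.

library(graspwave)

cfg <- pipeline_config()
in_dir <- "results/preprocessed"
out_dir <- "results/features"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

for (sid in list.dirs(in_dir, recursive = FALSE, full.names = FALSE)) {
  epochs <- read_epochs(file.path(in_dir, sid))
  tfr <- wavelet_transform(epochs, build_family(cfg, fs = epochs$fs))
  feats <- extract_features(tfr, cfg$feature_window_s)
  write_features(feats, file.path(out_dir, sprintf("%s.csv", sid)))
  message(sprintf("%s: %d instances x %d features", sid,
                  nrow(feats$values), ncol(feats$values)))
}
message("wrote ", out_dir)
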