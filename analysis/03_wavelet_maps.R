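#!/usr/bin/env Rscript
# Stage 3 — wavelet time-frequency and topographic maps.
#
# Computes the 4-cycle complex Morlet transform (2/9/16/23 Hz) for subject
# S1, plots the condition-mean time-frequency maps at C3 over [-1, +1] s,
# and topographic snapshots of 9/16/23 Hz power just after the 300 ms
# burst onset. Writes figures and the per-channel snapshot values under
# results/maps/.

library(graspwave)

cfg <- pipeline_config()
out_dir <- "results/maps"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

epochs <- read_epochs("results/preprocessed/S1")
family <- build_family(cfg, fs = epochs$fs)
tfr <- wavelet_transform(epochs, family)

snap_time <- cfg$topo_time_s + 0.1  # the burst envelope rises from 0.3 s

for (cond in grasp_conditions()) {
  png(file.path(out_dir, sprintf("tfr_C3_%s.png", cond)), 700, 450)
  plot_tfr_map(tfr, cond, "C3")
  dev.off()
}

rows <- list()
for (f in c(9, 16, 23)) {
  for (cond in grasp_conditions()) {
    snap <- topo_snapshot(tfr, cond, snap_time, f)
    png(file.path(out_dir, sprintf("topo_%dhz_%s.png", f, cond)), 500, 500)
    plot(snap)
    dev.off()
    rows[[length(rows) + 1]] <- data.frame(
      freq_hz = f, condition = cond,
      channel = names(snap$channel_values),
      mean_power = as.numeric(snap$channel_values)
    )
  }
  peak <- topo_snapshot(tfr, "power", snap_time, f)
  message(sprintf("power grasp, %2d Hz @ %.0f ms: peak channel %s", f,
                  1000 * snap_time,
                  names(which.max(peak$channel_values))))
}
write.csv(do.call(rbind, rows), file.path(out_dir, "topo_values.csv"),
          row.names = FALSE)
message("wrote ", out_dir)
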