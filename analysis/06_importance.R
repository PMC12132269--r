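#!/usr/bin/env Rscript
# Stage 6 — permutation feature importance.
#
# Runs permutation importance (20 repeats, held-out 20% split) on the
# gradient-boosted-trees model per subject, reports each subject's top
# features, writes the per-repeat score table, a labeled cross-subject
# mean, a boxplot of the top 10 features for S1, and per-band importance
# topographies. Outputs under results/importance/.

library(graspwave)

root_seed <- 42L
in_dir <- "results/features"
out_dir <- "results/importance"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

imps <- list()
for (sid in sub("\\.csv$", "", list.files(in_dir, pattern = "\\.csv$"))) {
  feats <- read_features(file.path(in_dir, paste0(sid, ".csv")))
  imp <- permutation_importance(
    feats, "gradient-boosted-trees",
    pipeline_config(rng_seed = root_seed * 2000L +
                      as.integer(sub("S", "", sid)))
  )
  imps[[sid]] <- imp
  message(sprintf("%s top 5: %s", sid,
                  paste(top_k(imp, 5), collapse = ", ")))
}

scores <- do.call(rbind, lapply(names(imps), function(sid) {
  r <- imps[[sid]]
  data.frame(subject = sid,
             feature = rep(r$feature_names, ncol(r$scores)),
             repeat_i = rep(seq_len(ncol(r$scores)), each = nrow(r$scores)),
             score = as.numeric(r$scores))
}))
write.csv(scores, file.path(out_dir, "scores.csv"), row.names = FALSE)

mean_imp <- Reduce(`+`, lapply(imps, function(r) r$mean_scores)) /
  length(imps)
write.csv(
  data.frame(feature = names(mean_imp),
             mean_score_across_subjects = as.numeric(mean_imp)),
  file.path(out_dir, "cross_subject_mean.csv"), row.names = FALSE
)

png(file.path(out_dir, "importance_box_S1.png"), 900, 500)
plot_importance_box(imps$S1)
dev.off()
for (band in pipeline_config()$band_names) {
  png(file.path(out_dir, sprintf("topo_importance_%s.png", band)), 500, 500)
  plot(topo_importance(imps$S1, band))
  dev.off()
}
message("wrote ", out_dir)
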