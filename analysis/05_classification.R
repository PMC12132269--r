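#!/usr/bin/env Rscript
# Stage 5 — cross-validated classification.
#
# Evaluates the four model families (RBF-kernel SVM, random forest,
# gradient-boosted trees, LDA) on the multiclass task and the three binary
# contrasts with stratified 5-fold cross-validation (features standardized
# inside each fold), per subject. Writes the subjects-by-models accuracy
# tables under results/tables/.

library(graspwave)

root_seed <- 42L
in_dir <- "results/features"
out_dir <- "results/tables"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

models <- c("max-margin-kernel", "random-forest",
            "gradient-boosted-trees", "linear-discriminant")
results <- list()
for (sid in sub("\\.csv$", "", list.files(in_dir, pattern = "\\.csv$"))) {
  feats <- read_features(file.path(in_dir, paste0(sid, ".csv")))
  cfg <- pipeline_config(
    rng_seed = root_seed * 1000L + as.integer(sub("S", "", sid))
  )
  for (task in all_tasks()) {
    for (m in models) {
      results[[length(results) + 1]] <- run_cv(feats, task, m, cfg)
    }
  }
  message(sid, ": 4 tasks x 4 models done")
}

is_multi <- vapply(results, function(r) r$task$name == "multiclass", TRUE)
tab_multi <- summarize_cv(results[is_multi])
tab_bin <- summarize_cv(results[!is_multi])
write.csv(tab_multi, file.path(out_dir, "multiclass.csv"),
          row.names = FALSE)
write.csv(tab_bin, file.path(out_dir, "binary.csv"), row.names = FALSE)

message("multiclass accuracies (%):")
print(tab_multi, digits = 4)
message("wrote ", out_dir)
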