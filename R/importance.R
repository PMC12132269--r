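#' Permutation feature importance
#'
#' Cross-validated permutation importance: instances are split into
#' `n_splits` seeded stratified folds; for each fold the model is fit on
#' the remaining folds (features standardized with training statistics
#' only) and its baseline accuracy measured on the held-out fold. Each of
#' the `n_permutation_repeats` shuffle repeats is assigned round-robin to
#' a fold; the repeat shuffles every feature column of that fold's
#' held-out data (one seeded permutation) and records the per-feature
#' accuracy drop. Averaging drops over repeats — and hence over held-out
#' folds — removes the split-realization noise a single small holdout
#' suffers from. Positive scores mean the model relied on the feature;
#' scores near zero (possibly negative) mean it did not.
#'
#' With `n_splits = 1` the estimator degenerates to a single stratified
#' holdout split of fraction `holdout_frac`.
#'
#' @param features A [extract_features()] result.
#' @param model_name Classifier family (default: gradient-boosted trees;
#'   pass the family that won the cross-validated comparison to mirror the
#'   usual reporting practice).
#' @param cfg A [pipeline_config()] supplying `rng_seed` and
#'   `n_permutation_repeats`.
#' @param n_splits Number of stratified folds importance is averaged over.
#' @param holdout_frac Held-out fraction when `n_splits = 1`.
#' @return An object of class `gw_importance`: `scores` (feature x
#'   repeat matrix of accuracy drops), `mean_scores`, `baseline_accuracy`
#'   (mean over the used folds), `ranking`, and
#'   `band_channel_aggregate` (band x channel matrix of mean scores over
#'   each pair's four statistics).
#' @export
permutation_importance <- function(features,
                                   model_name = "gradient-boosted-trees",
                                   cfg = pipeline_config(),
                                   n_splits = 5L,
                                   holdout_frac = 0.2) {
  model_name <- resolve_model_name(model_name)
  y <- features$labels
  if (length(unique(y)) < 2) {
    stop_validation("permutation_importance: need at least 2 classes")
  }
  if (cfg$n_permutation_repeats < 1) {
    stop_validation("permutation_importance: n_repeats must be >= 1")
  }
  x <- features$values
  n_feat <- ncol(x)
  n_rep <- cfg$n_permutation_repeats

  if (n_splits >= 2L) {
    if (any(table(y) < n_splits)) {
      stop_validation(
        "permutation_importance: every class needs >= n_splits instances"
      )
    }
    fold <- stratified_folds(y, n_splits, derive_seed(cfg$rng_seed, 301L))
  } else {
    # single stratified holdout of fraction holdout_frac (fold 1 = held out)
    fold <- rep(2L, length(y))
    with_seed(derive_seed(cfg$rng_seed, 301L), {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        fold[sample(idx, max(1L, round(holdout_frac * length(idx))))] <- 1L
      }
    })
  }
  rep_fold <- ((seq_len(n_rep) - 1L) %% max(n_splits, 1L)) + 1L
  used_folds <- sort(unique(rep_fold))

  scores <- matrix(NA_real_, n_feat, n_rep,
                   dimnames = list(features$feature_names, NULL))
  baselines <- numeric(length(used_folds))
  for (k in seq_along(used_folds)) {
    fi <- used_folds[k]
    te <- fold == fi
    std <- standardize_pair(x[!te, , drop = FALSE], x[te, , drop = FALSE])
    model <- make_model(model_name, derive_seed(cfg$rng_seed, 302L + fi))
    model <- fit_model(model, std$train, y[!te])
    y_test <- y[te]
    n_test <- nrow(std$test)
    baseline <- mean(predict_model(model, std$test) == y_test)
    baselines[k] <- baseline
    with_seed(derive_seed(cfg$rng_seed, 400L + fi), {
      for (rep_i in which(rep_fold == fi)) {
        perm <- sample(n_test)
        # stack the one-column-shuffled copies and predict in one call
        big <- std$test[rep(seq_len(n_test), n_feat), , drop = FALSE]
        for (j in seq_len(n_feat)) {
          big[(j - 1L) * n_test + seq_len(n_test), j] <- std$test[perm, j]
        }
        hits <- predict_model(model, big) == rep(y_test, n_feat)
        scores[, rep_i] <- baseline - colMeans(matrix(hits, nrow = n_test))
      }
    })
  }
  baseline <- mean(baselines)
  mean_scores <- rowMeans(scores)
  ord <- order(-mean_scores, features$feature_names)
  parsed <- parse_feature_name(features$feature_names)
  bands <- unique(parsed$band)
  chans <- unique(parsed$channel)
  agg <- matrix(NA_real_, length(bands), length(chans),
                dimnames = list(bands, chans))
  for (b in bands) {
    for (ch in chans) {
      agg[b, ch] <- mean(mean_scores[parsed$band == b & parsed$channel == ch])
    }
  }
  structure(
    list(scores = scores, mean_scores = mean_scores,
         feature_names = features$feature_names,
         ranking = features$feature_names[ord],
         baseline_accuracy = baseline,
         band_channel_aggregate = agg,
         model_name = model_name,
         n_repeats = cfg$n_permutation_repeats,
         rng_seed = cfg$rng_seed,
         subject_id = features$subject_id),
    class = "gw_importance"
  )
}

#' Top-k features by mean importance
#'
#' Ranking is by decreasing mean accuracy drop, ties broken by name.
#'
#' @param result A [permutation_importance()] result.
#' @param k Number of features.
#' @return Character vector of feature names.
#' @export
top_k <- function(result, k = 10) {
  head(result$ranking, k)
}

#' @export
print.gw_importance <- function(x, ...) {
  cat(sprintf(
    "<gw_importance> %s / %s: baseline accuracy %.1f%%, %d repeats\n  top 5: %s\n",
    x$subject_id, x$model_name, 100 * x$baseline_accuracy, x$n_repeats,
    paste(top_k(x, 5), collapse = ", ")
  ))
  invisible(x)
}

#' Topographic map of per-band feature importance
#'
#' Per-channel value = the band/channel aggregate importance (mean over the
#' pair's four statistics), interpolated over the scalp with the same
#' thin-plate operator as [topo_snapshot()].
#'
#' @param result A [permutation_importance()] result.
#' @param band Band label present in the aggregate.
#' @param montage A [montage()] covering the aggregate's channels.
#' @param grid_n Grid resolution.
#' @return A `gw_topomap` (see [topo_snapshot()]).
#' @export
topo_importance <- function(result, band, montage = default_montage(),
                            grid_n = 67) {
  agg <- result$band_channel_aggregate
  if (!(band %in% rownames(agg))) {
    stop_validation("topo_importance: unknown band '%s' (have %s)",
                    band, paste(rownames(agg), collapse = ", "))
  }
  vals <- agg[band, montage$channel_names]
  grid <- tps_interpolate(montage$positions_2d, vals, grid_n = grid_n)
  structure(
    list(channel_values = setNames(as.numeric(vals),
                                   montage$channel_names),
         x = grid$x, y = grid$y, z = grid$z,
         band = band, montage = montage),
    class = "gw_topomap"
  )
}
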