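MODEL_FAMILIES <- c("max-margin-kernel", "random-forest",
                    "gradient-boosted-trees", "linear-discriminant")

MODEL_ALIASES <- c(
  svm = "max-margin-kernel", rf = "random-forest",
  xgboost = "gradient-boosted-trees", gbt = "gradient-boosted-trees",
  lda = "linear-discriminant"
)

#' Classification task specification
#'
#' The four evaluation tasks: the three-class problem and the three
#' pairwise binary contrasts. Chance level is 1 / number of classes
#' (labels are balanced by design).
#'
#' @param name One of `multiclass`, `none_vs_power`, `none_vs_precision`,
#'   `power_vs_precision`.
#' @return An object of class `gw_task` with `name`, `included_labels` and
#'   `chance_level`.
#' @export
task_spec <- function(name = c("multiclass", "none_vs_power",
                               "none_vs_precision", "power_vs_precision")) {
  name <- match.arg(name)
  included <- switch(
    name,
    multiclass = GRASP_CONDITIONS,
    none_vs_power = c("no_movement", "power"),
    none_vs_precision = c("no_movement", "precision"),
    power_vs_precision = c("power", "precision")
  )
  structure(
    list(name = name, included_labels = included,
         chance_level = 1 / length(included)),
    class = "gw_task"
  )
}

#' All four task specifications
#' @return Named list of [task_spec()] objects.
#' @export
all_tasks <- function() {
  n <- c("multiclass", "none_vs_power", "none_vs_precision",
         "power_vs_precision")
  setNames(lapply(n, task_spec), n)
}

resolve_model_name <- function(name) {
  if (name %in% names(MODEL_ALIASES)) name <- MODEL_ALIASES[[name]]
  if (!(name %in% MODEL_FAMILIES)) {
    stop_validation("unknown model family '%s'; expected one of %s",
                    name, paste(MODEL_FAMILIES, collapse = ", "))
  }
  name
}

#' Construct a trainable classifier
#'
#' The four model families used throughout: an RBF-kernel max-margin
#' classifier (support vector machine), a random forest, gradient-boosted
#' trees, and linear discriminant analysis. Hyperparameters are library
#' defaults (RBF kernel for the max-margin model; 300 trees for the
#' forest; 60 boosting rounds, depth 3, learning rate 0.3 for the boosted
#' trees); stochastic families are seeded so construction + fit +
#' predict is deterministic.
#'
#' @param name Family name (aliases `svm`, `rf`, `xgboost`/`gbt`, `lda`
#'   accepted).
#' @param rng_seed Integer seed for the stochastic families.
#' @return An object of class `gw_model`; see [fit_model()] and
#'   [predict_model()].
#' @export
make_model <- function(name, rng_seed = 42L) {
  structure(
    list(name = resolve_model_name(name), rng_seed = as.integer(rng_seed),
         fit = NULL, classes = NULL),
    class = "gw_model"
  )
}

#' Fit a classifier
#'
#' @param model A [make_model()].
#' @param x Numeric feature matrix (instances x features).
#' @param y Per-instance labels.
#' @return The model with its fit attached.
#' @export
fit_model <- function(model, x, y) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- factor(y)
  model$classes <- levels(y)
  # some backends read the session RNG even when given a seed argument;
  # pin it so fits are reproducible regardless of call history
  model$fit <- with_seed(model$rng_seed, switch(
    model$name,
    "max-margin-kernel" = e1071::svm(x, y, kernel = "radial", scale = FALSE),
    "random-forest" = ranger::ranger(
      x = x, y = y, num.trees = 300, seed = model$rng_seed,
      num.threads = 1
    ),
    "gradient-boosted-trees" = {
      nc <- nlevels(y)
      params <- if (nc > 2) {
        list(objective = "multi:softmax", num_class = nc)
      } else {
        list(objective = "binary:logistic")
      }
      dm <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L,
                                 nthread = 1)
      xgboost::xgb.train(
        params = c(params, list(max_depth = 3, eta = 0.3, nthread = 1,
                                seed = model$rng_seed)),
        data = dm, nrounds = 60, verbose = 0
      )
    },
    "linear-discriminant" = suppressWarnings(MASS::lda(x, grouping = y))
  ))
  model
}

#' Predict with a fitted classifier
#'
#' @param model A fitted [gw_model][fit_model()].
#' @param x Numeric feature matrix.
#' @return Character vector of predicted labels.
#' @export
predict_model <- function(model, x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (is.null(model$fit)) stop_validation("predict_model: model not fitted")
  switch(
    model$name,
    "max-margin-kernel" = as.character(predict(model$fit, x)),
    # vote ties are broken randomly at prediction time; pin that too
    "random-forest" = with_seed(
      model$rng_seed,
      as.character(predict(model$fit, data = x, num.threads = 1,
                           seed = model$rng_seed)$predictions)
    ),
    "gradient-boosted-trees" = {
      p <- predict(model$fit, xgboost::xgb.DMatrix(x, nthread = 1))
      if (length(model$classes) > 2) {
        model$classes[p + 1L]
      } else {
        model$classes[as.integer(p > 0.5) + 1L]
      }
    },
    "linear-discriminant" = as.character(predict(model$fit, x)$class)
  )
}

# Seeded stratified fold assignment: within each class, instances are
# shuffled and dealt round-robin, so per-fold class counts differ from the
# global proportion by at most one instance.
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  fold
}

# Standardize train columns; apply train means/sds to test. Constant
# columns are left centered but unscaled.
standardize_pair <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(
    train = sweep(sweep(train, 2, mu), 2, sdv, "/"),
    test = sweep(sweep(test, 2, mu), 2, sdv, "/")
  )
}

#' Stratified k-fold cross-validated accuracy
#'
#' Restricts the feature table to the task's labels, assigns seeded
#' stratified folds, and for each fold standardizes features on the
#' training split only (no leakage), fits the model, and scores accuracy
#' on the held-out fold. Every instance is tested exactly once.
#'
#' @param features A [extract_features()] result (or compatible list).
#' @param task A [task_spec()].
#' @param model_name Classifier family (see [make_model()]).
#' @param cfg A [pipeline_config()] supplying `cv_folds` and `rng_seed`.
#' @return An object of class `gw_cv_result` with `fold_accuracies`,
#'   `mean_accuracy`, `sd_accuracy`, the fold assignment, task, model and
#'   subject id.
#' @export
run_cv <- function(features, task, model_name, cfg = pipeline_config()) {
  model_name <- resolve_model_name(model_name)
  keep <- features$labels %in% task$included_labels
  x <- features$values[keep, , drop = FALSE]
  y <- features$labels[keep]
  k <- cfg$cv_folds
  counts <- table(y)
  if (length(counts) < length(task$included_labels) || any(counts < k)) {
    stop_validation(
      "run_cv: need >= %d instances of each of %s", k,
      paste(task$included_labels, collapse = ", ")
    )
  }
  fold <- stratified_folds(y, k, derive_seed(cfg$rng_seed, 101L))
  acc <- numeric(k)
  for (fi in seq_len(k)) {
    tr <- fold != fi
    std <- standardize_pair(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])
    model <- make_model(model_name, derive_seed(cfg$rng_seed, 200L + fi))
    model <- fit_model(model, std$train, y[tr])
    pred <- predict_model(model, std$test)
    acc[fi] <- mean(pred == y[!tr])
  }
  structure(
    list(task = task, model_name = model_name,
         fold_accuracies = acc, mean_accuracy = mean(acc),
         sd_accuracy = sd(acc), fold = fold, rng_seed = cfg$rng_seed,
         subject_id = features$subject_id),
    class = "gw_cv_result"
  )
}

#' @export
print.gw_cv_result <- function(x, ...) {
  cat(sprintf(
    "<gw_cv_result> %s / %s / %s: mean accuracy %.1f%% (sd %.1f) over %d folds\n",
    x$subject_id, x$task$name, x$model_name,
    100 * x$mean_accuracy, 100 * x$sd_accuracy, length(x$fold_accuracies)
  ))
  invisible(x)
}

#' Summarize cross-validation results across subjects
#'
#' Builds the standard results table: one row per subject, one column per
#' model family (multiclass) or per task/model pair (binary tasks), plus
#' `Mean` and `STD` rows, with accuracies in percent.
#'
#' @param results List of [run_cv()] results sharing one task (or, for
#'   binary tables, any mix of the three binary tasks).
#' @return Data frame with a `subject` column and accuracy columns (%).
#' @export
summarize_cv <- function(results) {
  if (!length(results)) stop_validation("summarize_cv: no results")
  tasks <- unique(vapply(results, function(r) r$task$name, ""))
  is_binary <- all(tasks != "multiclass")
  if (!is_binary && length(tasks) > 1) {
    stop_validation("summarize_cv: cannot mix multiclass with binary tasks")
  }
  subjects <- sort(unique(vapply(results, function(r) r$subject_id, "")))
  col_of <- function(r) {
    if (is_binary && length(tasks) > 1) {
      paste(r$task$name, r$model_name, sep = ".")
    } else {
      r$model_name
    }
  }
  cols <- unique(vapply(results, col_of, ""))
  tab <- matrix(NA_real_, nrow = length(subjects), ncol = length(cols),
                dimnames = list(subjects, cols))
  for (r in results) {
    tab[r$subject_id, col_of(r)] <- 100 * r$mean_accuracy
  }
  body <- as.data.frame(tab)
  out <- rbind(
    body,
    Mean = colMeans(tab),
    STD = apply(tab, 2, sd)
  )
  if (length(subjects) == 1) out["STD", ] <- 0
  data.frame(subject = rownames(out), out, row.names = NULL,
             check.names = FALSE)
}
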