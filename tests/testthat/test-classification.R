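blob_data <- function(n = 100, sep = 6, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n / 2 * 4), ncol = 4),
               matrix(rnorm(n / 2 * 4, mean = sep), ncol = 4))
    list(x = x, y = rep(c("power", "precision"), each = n / 2))
  })
}

test_that("all four model families construct, fit and separate easy data", {
  d <- blob_data()
  for (name in c("max-margin-kernel", "random-forest",
                 "gradient-boosted-trees", "linear-discriminant")) {
    model <- make_model(name, rng_seed = 5)
    fitted <- fit_model(model, d$x, d$y)
    expect_equal(mean(predict_model(fitted, d$x) == d$y), 1.0)
  }
  expect_error(make_model("nearest-centroid"), "unknown model family")
  # aliases resolve to the canonical names
  expect_identical(make_model("xgboost")$name, "gradient-boosted-trees")
  expect_identical(make_model("svm")$name, "max-margin-kernel")
})

test_that("stochastic families are deterministic under a fixed seed", {
  d <- blob_data(n = 80, sep = 1, seed = 2)   # overlapping: predictions nontrivial
  probe <- withr::with_seed(3, matrix(rnorm(40 * 4), ncol = 4))
  for (name in c("random-forest", "gradient-boosted-trees")) {
    p1 <- predict_model(fit_model(make_model(name, 11), d$x, d$y), probe)
    p2 <- predict_model(fit_model(make_model(name, 11), d$x, d$y), probe)
    expect_identical(p1, p2)
  }
})

test_that("task specifications define labels and chance levels", {
  expect_equal(task_spec("multiclass")$chance_level, 1 / 3)
  expect_equal(task_spec("none_vs_power")$chance_level, 1 / 2)
  expect_setequal(task_spec("power_vs_precision")$included_labels,
                  c("power", "precision"))
  expect_equal(length(all_tasks()), 4)
  expect_error(task_spec("grip_vs_rest"))
})

test_that("stratified folds partition instances with balanced classes", {
  labels <- rep(grasp_conditions(), each = 50)
  fold <- graspwave:::stratified_folds(labels, 5, seed = 9)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(length(fold), 150)
  for (fi in 1:5) {
    counts <- table(labels[fold == fi])
    expect_true(all(abs(counts - 10) <= 1))
  }
  # every instance appears in exactly one fold by construction
  expect_equal(sum(table(fold)), 150)
})

test_that("cross-validation tests every instance once and summarizes folds", {
  fx <- default_pipeline()
  cv <- run_cv(fx$feats, task_spec("power_vs_precision"),
               "linear-discriminant", fx$cfg)
  expect_equal(length(cv$fold_accuracies), 5)
  expect_true(all(cv$fold_accuracies >= 0 & cv$fold_accuracies <= 1))
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracies))
  expect_equal(cv$sd_accuracy, sd(cv$fold_accuracies))
  expect_equal(length(cv$fold), 100)          # 50 power + 50 precision
})

test_that("cross-validation refuses starved classes", {
  small <- fake_features(
    withr::with_seed(4, matrix(rnorm(8 * 6), ncol = 6)),
    labels = c(rep("power", 4), rep("precision", 4))
  )
  expect_error(run_cv(small, task_spec("power_vs_precision"),
                      "linear-discriminant", pipeline_config(cv_folds = 5)),
               "need >= 5")
})

test_that("result tables mirror the subjects-by-models layout", {
  fake_cv <- function(sid, model, acc, task = task_spec("multiclass")) {
    structure(list(task = task, model_name = model,
                   fold_accuracies = rep(acc, 5), mean_accuracy = acc,
                   sd_accuracy = 0, rng_seed = 1, subject_id = sid),
              class = "gw_cv_result")
  }
  results <- list()
  accs <- matrix(seq(0.6, 0.99, length.out = 20), 5, 4)
  models <- c("max-margin-kernel", "random-forest",
              "gradient-boosted-trees", "linear-discriminant")
  for (si in 1:5) {
    for (mi in 1:4) {
      results[[length(results) + 1]] <-
        fake_cv(sprintf("S%d", si), models[mi], accs[si, mi])
    }
  }
  tab <- summarize_cv(results)
  expect_equal(nrow(tab), 7)                  # 5 subjects + Mean + STD
  expect_equal(ncol(tab), 5)                  # subject column + 4 models
  body <- as.matrix(tab[1:5, -1])
  expect_equal(unname(as.numeric(tab[6, -1])), unname(colMeans(body)))
  expect_equal(unname(as.numeric(tab[7, -1])),
               unname(apply(body, 2, sd)))

  single <- summarize_cv(list(fake_cv("S1", "random-forest", 0.8)))
  expect_equal(single[single$subject == "Mean", "random-forest"], 80)
  expect_equal(single[single$subject == "STD", "random-forest"], 0)

  expect_error(
    summarize_cv(list(fake_cv("S1", "random-forest", 0.8),
                      fake_cv("S1", "random-forest", 0.9,
                              task_spec("none_vs_power")))),
    "mix"
  )
})

test_that("accuracy is monotone-ish in class separation for one family", {
  # coarse two-point check; the full effect-size grid runs in the
  # acceptance suite
  fx <- default_pipeline()
  cfg <- fx$cfg
  weak <- default_grasp_scenario(effect_scale = 0.25, rng_seed = 7)
  tfr_w <- wavelet_transform(
    preprocess(simulate_subject(weak, subject_id = "S1"), cfg), fx$family
  )
  feats_w <- extract_features(tfr_w, cfg$feature_window_s)
  acc_w <- run_cv(feats_w, task_spec("multiclass"),
                  "gradient-boosted-trees", cfg)$mean_accuracy
  acc_s <- run_cv(fx$feats, task_spec("multiclass"),
                  "gradient-boosted-trees", cfg)$mean_accuracy
  expect_gt(acc_s, acc_w)
})
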