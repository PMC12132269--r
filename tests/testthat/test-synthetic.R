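quick_sim <- function(..., effects = list(), seed = 1) {
  sim_config(n_trials_per_class = 5L, epoch_window_s = c(-1, 1),
             effects = effects, rng_seed = seed, ...)
}

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- quick_sim(seed = 11)
  e1 <- simulate_subject(cfg)
  e2 <- simulate_subject(cfg)
  expect_identical(e1$data, e2$data)
  expect_identical(e1$labels, e2$labels)
  cfg2 <- quick_sim(seed = 12)
  expect_false(identical(simulate_subject(cfg2)$data, e1$data))
})

test_that("default grasp scenario matches the study conditions", {
  sim <- default_grasp_scenario()
  expect_s3_class(sim, "gw_sim_config")
  expect_equal(sim$n_trials_per_class, 50L)
  expect_equal(sim$fs, 250)
  for (ef in sim$effects) {
    expect_equal(ef$onset_s, 0.3)
    expect_true(ef$channel %in% c("C3", "C4"))
    expect_true(ef$center_freq_hz %in% c(9, 16))
    a <- ef$amplitude_by_class
    expect_true(a[["power"]] > a[["precision"]])
    expect_identical(unname(a[["no_movement"]]), 0)
  }
})

test_that("unknown effect channels are rejected", {
  ef <- effect_spec("XX", 9, 0.3, 0.5,
                    c(no_movement = 0, power = 1, precision = 0.5))
  expect_error(simulate_subject(quick_sim(effects = list(ef))),
               "XX")
})

test_that("effect specs require all three class amplitudes", {
  expect_error(effect_spec("C3", 9, 0.3, 0.5, c(power = 1, precision = 1)),
               "no_movement")
  expect_error(effect_spec("C3", 9, 0.3, -1,
                           c(no_movement = 0, power = 1, precision = 1)),
               "duration")
})

test_that("background spectral slope is recovered by log-log regression", {
  for (alpha in c(0.5, 1.5)) {
    cfg <- sim_config(n_trials_per_class = 34L, epoch_window_s = c(-1, 1),
                      background_exponent = alpha, rng_seed = 21)
    e <- simulate_subject(cfg)
    n <- dim(e$data)[3]
    freqs <- seq_len(n %/% 2) * e$fs / n
    # mean periodogram at channel 1 over all trials
    spec <- rowMeans(vapply(seq_len(dim(e$data)[1]), function(tr) {
      Mod(fft(e$data[tr, 1, ]))[2:(n %/% 2 + 1)]^2
    }, numeric(n %/% 2)))
    sel <- freqs >= 2 & freqs <= 30
    slope <- coef(lm(log(spec[sel]) ~ log(freqs[sel])))[2]
    expect_lt(abs(-slope - alpha), 0.3)
  }
})

test_that("injected burst energy scales quadratically with amplitude", {
  amp <- function(a) c(no_movement = a, power = a, precision = a)
  mean_power <- function(a) {
    ef <- if (a > 0) list(effect_spec("C3", 9, -0.3, 0.5, amp(a))) else list()
    cfg <- sim_config(n_trials_per_class = 15L, epoch_window_s = c(-1, 1),
                      effects = ef, rng_seed = 31)
    e <- simulate_subject(cfg)
    fam <- build_family(pipeline_config(center_freqs_hz = 9,
                                        band_names = "alpha"), fs = e$fs)
    tfr <- wavelet_transform(e, fam)
    sel <- tfr$times_s >= -0.3 & tfr$times_s < 0.2
    mean(tfr$power[, match("C3", e$montage$channel_names), 1, sel])
  }
  # amplitudes well above background so the noise-burst cross term is small
  p0 <- mean_power(0)
  p1 <- mean_power(30)
  p2 <- mean_power(60)
  ratio <- (p2 - p0) / (p1 - p0)
  expect_gt(ratio, 4 * 0.9)
  expect_lt(ratio, 4 * 1.1)
})

test_that("equal class amplitudes leave class band powers indistinguishable", {
  amp <- c(no_movement = 5, power = 5, precision = 5)
  rejections <- 0L
  for (seed in 1:10) {
    cfg <- sim_config(
      n_trials_per_class = 30L, epoch_window_s = c(-1, 1),
      effects = list(effect_spec("C3", 9, -0.2, 0.4, amp)),
      rng_seed = 100 + seed
    )
    e <- simulate_subject(cfg)
    fam <- build_family(pipeline_config(center_freqs_hz = 9,
                                        band_names = "alpha"), fs = e$fs)
    tfr <- wavelet_transform(e, fam)
    sel <- tfr$times_s >= -0.2 & tfr$times_s < 0.2
    pw <- apply(tfr$power[, match("C3", e$montage$channel_names), 1, sel],
                1, mean)
    p <- t.test(pw[e$labels == "power"], pw[e$labels == "precision"])$p.value
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 2L)
})

test_that("class-mean alpha power at the injected channel follows the amplitudes", {
  fx <- default_pipeline()
  tfr <- fx$tfr
  ci <- match("C3", tfr$montage$channel_names)
  fi <- which(tfr$freqs_hz == 9)
  sel <- tfr$times_s >= 0.3 & tfr$times_s < 0.8
  m <- vapply(grasp_conditions(), function(cond) {
    mean(tfr$power[tfr$labels == cond, ci, fi, sel])
  }, 0)
  expect_gt(m[["power"]], m[["precision"]])
  expect_gt(m[["precision"]], m[["no_movement"]])
})
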