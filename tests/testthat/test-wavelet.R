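one_channel_epochs <- function(x, fs = 250) {
  m <- montage("Cz", rbind(c(0, 0)))
  epoch_set(array(x, c(1, 1, length(x))), fs = fs, t0_offset = 0,
            labels = "power", montage = m)
}

test_that("Morlet kernels have the closed-form width and unit energy", {
  cfg <- pipeline_config()
  fam <- build_family(cfg, fs = 250)
  expect_equal(fam$sigma_t_s[fam$center_freqs_hz == 9],
               4 / (2 * pi * 9), tolerance = 1e-12)
  expect_true(all(c(9, 16, 23) %in% fam$center_freqs_hz))
  expect_equal(length(fam$kernels), 4)
  for (k in fam$kernels) {
    expect_equal(sum(Mod(k)^2) / 250, 1, tolerance = 1e-9)
    expect_equal(length(k) %% 2, 1)   # symmetric support about t = 0
  }
  bad <- cfg
  bad$center_freqs_hz <- c(-3, 9)
  bad$band_names <- c("a", "b")
  expect_error(build_family(bad), "positive")
})

test_that("FFT convolution matches the brute-force oracle", {
  cfg <- pipeline_config(center_freqs_hz = c(9, 23),
                         band_names = c("alpha", "beta_high"))
  fam <- build_family(cfg, fs = 250)
  for (seed in 1:5) {
    x <- withr::with_seed(seed, rnorm(256))
    tfr <- wavelet_transform(one_channel_epochs(x), fam)
    for (fi in 1:2) {
      oracle <- direct_conv_same(x, fam$kernels[[fi]])
      expect_lt(max(abs(sqrt(tfr$power[1, 1, fi, ]) - Mod(oracle))), 1e-9)
    }
  }
})

test_that("the transform is frequency selective and null-preserving", {
  fam <- build_family(pipeline_config(), fs = 250)
  t <- (0:1023) / 250
  tfr <- wavelet_transform(one_channel_epochs(sin(2 * pi * 9 * t)), fam)
  mean_valid_power <- vapply(seq_along(tfr$freqs_hz), function(fi) {
    mean(tfr$power[1, 1, fi, tfr$valid_mask[fi, ]])
  }, 0)
  expect_equal(tfr$freqs_hz[which.max(mean_valid_power)], 9)

  tfr0 <- wavelet_transform(one_channel_epochs(numeric(1024)), fam)
  expect_equal(max(tfr0$power), 0)
})

test_that("power respects stationarity, sign and scaling symmetries", {
  fam <- build_family(pipeline_config(center_freqs_hz = 9,
                                      band_names = "alpha"), fs = 250)
  t <- (0:1499) / 250
  x <- sin(2 * pi * 9 * t)
  tfr <- wavelet_transform(one_channel_epochs(x), fam)
  valid <- tfr$valid_mask[1, ]
  p <- tfr$power[1, 1, 1, valid]
  expect_lt(sd(p) / mean(p), 0.01)           # constant in time

  tfr_neg <- wavelet_transform(one_channel_epochs(-x), fam)
  expect_equal(tfr_neg$power, tfr$power, tolerance = 1e-12)

  x_shift <- sin(2 * pi * 9 * t + 1.1)       # phase shift
  tfr_shift <- wavelet_transform(one_channel_epochs(x_shift), fam)
  expect_lt(abs(mean(sqrt(tfr_shift$power[1, 1, 1, valid])) /
                  mean(sqrt(tfr$power[1, 1, 1, valid])) - 1), 0.01)

  tfr2 <- wavelet_transform(one_channel_epochs(2 * x), fam)
  expect_equal(tfr2$power, 4 * tfr$power, tolerance = 1e-12)
})

test_that("valid mask excludes at least the kernel half-support at each edge", {
  fam <- build_family(pipeline_config(), fs = 250)
  e <- one_channel_epochs(rnorm(1024))
  tfr <- wavelet_transform(e, fam)
  for (fi in seq_along(tfr$freqs_hz)) {
    first_valid <- min(which(tfr$valid_mask[fi, ]))
    expect_gte((first_valid - 1) / 250, tfr$support_s[fi] - 1e-9)
  }
  # mismatched sampling rates are rejected
  e2 <- e; e2$fs <- 500
  expect_error(wavelet_transform(e2, fam), "fs")
})

test_that("condition averaging is a labeled mean", {
  fx <- default_pipeline()
  tfr <- fx$tfr
  one <- which(tfr$labels == "power")[1]
  avg1 <- average_tfr(tfr, "power", labels = replace(
    rep("no_movement", length(tfr$labels)), one, "power"
  ))
  expect_equal(avg1, {
    a <- tfr$power[one, , , ]
    dimnames(a) <- dimnames(avg1)
    a
  }, tolerance = 1e-12)
  expect_error(average_tfr(tfr, "power", labels = rep("precision",
                                                      length(tfr$labels))),
               "no trials")
  # invariant to permuting labels within the condition
  sel <- tfr$labels == "power"
  expect_equal(average_tfr(tfr, "power"),
               average_tfr(tfr, "power",
                           labels = replace(tfr$labels, which(sel),
                                            tfr$labels[sel])),
               tolerance = 1e-12)
})

test_that("thin-plate interpolation is exact at the electrodes", {
  m <- default_montage()
  vals <- withr::with_seed(1, rnorm(8))
  at_nodes <- graspwave:::tps_eval(m$positions_2d, vals, m$positions_2d)
  expect_equal(at_nodes, vals, tolerance = 1e-8)
  grid <- tps_interpolate(m$positions_2d, vals, grid_n = 21)
  expect_true(anyNA(grid$z))                       # masked outside the head
  expect_true(all(is.finite(grid$z[outer(grid$x^2, grid$y^2, `+`) <= 1])))
})

test_that("topographic snapshots localize the injected effect", {
  fx <- default_pipeline()
  # just after the 300 ms burst onset (the simulated envelope rises from
  # exactly 0.3 s, so sample it once it carries power)
  snap <- topo_snapshot(fx$tfr, "power", fx$cfg$topo_time_s + 0.1, 9)
  expect_true(names(which.max(snap$channel_values)) %in% c("C3", "C4"))
  # without an effect, no channel dominates
  null_snap <- topo_snapshot(fx$tfr, "no_movement", fx$cfg$topo_time_s + 0.1, 9)
  v <- null_snap$channel_values
  expect_lt(sd(v) / mean(v), 0.25)
  # grid reproduces the electrode scalars at their positions
  ev <- graspwave:::tps_eval(fx$tfr$montage$positions_2d,
                             snap$channel_values,
                             fx$tfr$montage$positions_2d)
  expect_equal(unname(ev), unname(snap$channel_values), tolerance = 1e-8)
})

test_that("edge-contaminated snapshot times are rejected", {
  fx <- default_pipeline()
  expect_error(topo_snapshot(fx$tfr, "power", 2.25, 2), "edge-contaminated")
  expect_error(topo_snapshot(fx$tfr, "power", 0.3, 10.5), "not among")
})
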