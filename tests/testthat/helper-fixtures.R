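# Shared fixtures and independent oracles. The expensive default-scenario
# pipeline run is computed once per session and reused across test files.

.fixtures <- new.env(parent = emptyenv())

# Full default-scenario pipeline for one subject (50 trials/condition),
# memoized: raw epochs, preprocessed epochs, TFR, features.
default_pipeline <- function() {
  if (is.null(.fixtures$pipeline)) {
    cfg <- pipeline_config()
    sim <- default_grasp_scenario(rng_seed = 7)
    epochs_raw <- simulate_subject(sim, subject_id = "S1")
    epochs <- preprocess(epochs_raw, cfg)
    family <- build_family(cfg, fs = sim$fs)
    tfr <- wavelet_transform(epochs, family)
    feats <- extract_features(tfr, cfg$feature_window_s)
    .fixtures$pipeline <- list(
      cfg = cfg, sim = sim, family = family,
      epochs_raw = epochs_raw, epochs = epochs, tfr = tfr, feats = feats
    )
  }
  .fixtures$pipeline
}

# Small random epoch set for round-trip / shape properties.
random_epochs <- function(n_trials = 6, n_samples = 100, seed = 1,
                          fs = 250) {
  m <- default_montage()
  withr::with_seed(seed, {
    data <- array(rnorm(n_trials * 8 * n_samples),
                  dim = c(n_trials, 8, n_samples))
    labels <- sample(grasp_conditions(), n_trials, replace = TRUE)
    epoch_set(data, fs = fs, t0_offset = -0.2, labels = labels,
              montage = m, subject_id = "Sx")
  })
}

# Brute-force 'same'-length complex convolution (explicit loop): the
# independent oracle for the FFT path.
direct_conv_same <- function(x, k) {
  n <- length(x)
  m <- length(k)
  half <- (m - 1) %/% 2
  out <- complex(n)
  for (s in seq_len(n)) {
    # full-convolution term: out_full[s + half] = sum_i x[i] k[s + half - i + 1]
    i_lo <- max(1L, s + half - m + 1L)
    i_hi <- min(n, s + half)
    i <- i_lo:i_hi
    out[s] <- sum(x[i] * k[s + half - i + 1L])
  }
  out
}

# Independent two-pass moment reference (population conventions).
reference_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  c(mean = mu, variance = m2, skewness = m3 / m2^1.5,
    kurtosis = m4 / m2^2 - 3)
}

# Minimal hand-built TFR object for feature-level tests.
fake_tfr <- function(power, freqs, bands, labels, montage,
                     times, fs = 250) {
  structure(
    list(power = power, freqs_hz = freqs, band_names = bands,
         times_s = times,
         valid_mask = matrix(TRUE, length(freqs), length(times)),
         support_s = rep(0, length(freqs)), fs = fs, labels = labels,
         montage = montage, subject_id = "Sx"),
    class = "gw_tfr"
  )
}

# Feature-table stub with canonical names, for classifier/importance tests.
fake_features <- function(values, labels, names = NULL) {
  if (is.null(names)) {
    stats <- c("mean", "variance", "skewness", "kurtosis")
    pool <- as.character(outer(
      outer(default_montage()$channel_names,
            c("low", "alpha", "beta_low", "beta_high"), paste, sep = "."),
      stats, paste, sep = "."
    ))
    names <- pool[seq_len(ncol(values))]
  }
  colnames(values) <- names
  structure(
    list(values = values, feature_names = names, labels = labels,
         subject_id = "Sx"),
    class = "gw_features"
  )
}
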