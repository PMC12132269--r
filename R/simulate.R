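#' Class-dependent oscillatory burst specification
#'
#' Describes one ground-truth effect injected by the simulator: a
#' Hann-windowed sinusoidal burst at a single electrode and carrier
#' frequency, whose amplitude depends on the trial's condition. This is how
#' the generator emulates event-related synchronization (a post-onset band
#' power increase) with known spatial, spectral and temporal placement.
#'
#' @param channel Electrode label (must exist in the simulation montage).
#' @param center_freq_hz Burst carrier frequency (Hz).
#' @param onset_s Burst onset (s) relative to movement onset.
#' @param duration_s Burst duration (s), > 0.
#' @param amplitude_by_class Named numeric vector giving the burst amplitude
#'   (same units as the background noise, >= 0) for each of the three
#'   conditions.
#'
#' @return An object of class `gw_effect`.
#' @export
effect_spec <- function(channel, center_freq_hz, onset_s, duration_s,
                        amplitude_by_class) {
  if (duration_s <= 0) stop_validation("effect_spec: duration_s must be > 0")
  missing_cls <- setdiff(GRASP_CONDITIONS, names(amplitude_by_class))
  if (length(missing_cls)) {
    stop_validation("effect_spec: amplitude_by_class lacks %s",
                    paste(missing_cls, collapse = ", "))
  }
  if (any(amplitude_by_class < 0)) {
    stop_validation("effect_spec: amplitudes must be >= 0")
  }
  structure(
    list(channel = channel, center_freq_hz = center_freq_hz,
         onset_s = onset_s, duration_s = duration_s,
         amplitude_by_class = amplitude_by_class[GRASP_CONDITIONS]),
    class = "gw_effect"
  )
}

#' Synthetic-EEG simulation configuration
#'
#' @param n_trials_per_class Trials per condition (>= 1).
#' @param fs Sampling rate (Hz).
#' @param epoch_window_s Length-2 numeric (start, end) s relative to
#'   movement onset; start < 0 < end.
#' @param background_exponent Spectral slope alpha of the 1/f^alpha
#'   background.
#' @param background_scale Background noise RMS amplitude (microvolt-scale
#'   arbitrary units).
#' @param effects List of [effect_spec()] objects.
#' @param onset_jitter_s Half-width of the uniform per-trial burst-onset
#'   jitter (s).
#' @param rng_seed Integer seed; fixes the generated data exactly.
#'
#' @return An object of class `gw_sim_config`.
#' @export
sim_config <- function(n_trials_per_class = 50L,
                       fs = 250,
                       epoch_window_s = c(-2.3, 2.3),
                       background_exponent = 1,
                       background_scale = 10,
                       effects = list(),
                       onset_jitter_s = 0.04,
                       rng_seed = 1L) {
  if (n_trials_per_class < 1) {
    stop_validation("sim_config: n_trials_per_class must be >= 1")
  }
  if (!(epoch_window_s[1] < 0 && epoch_window_s[2] > 0)) {
    stop_validation("sim_config: epoch window must satisfy start < 0 < end")
  }
  if (fs <= 0) stop_validation("sim_config: fs must be positive")
  structure(
    list(n_trials_per_class = as.integer(n_trials_per_class), fs = fs,
         epoch_window_s = as.numeric(epoch_window_s),
         background_exponent = background_exponent,
         background_scale = background_scale,
         effects = effects, onset_jitter_s = onset_jitter_s,
         rng_seed = as.integer(rng_seed)),
    class = "gw_sim_config"
  )
}

#' Default grasp-decoding simulation scenario
#'
#' The standard study conditions emulated by the generator: 50 trials per
#' condition at 250 Hz, epochs spanning (-2.3, +2.3) s around movement
#' onset (wide enough that the [-1, +1] s time-frequency maps and the
#' [0, 0.8) s feature window are free of wavelet edge effects at all four
#' analysis frequencies), 1/f background, and alpha (9 Hz) + low-beta
#' (16 Hz) bursts over the central motor channels C3 and C4 starting 0.3 s
#' after onset. Burst amplitudes are ordered power > precision >
#' no-movement (zero), stronger contralaterally (C3) and in alpha than in
#' beta, emulating event-related synchronization during grasping.
#'
#' @param effect_scale Multiplier on every burst amplitude — the effect-size
#'   knob (1 = default; 0 = no class information).
#' @param n_trials_per_class Trials per condition.
#' @param rng_seed Integer seed.
#'
#' @return A [sim_config()].
#' @export
default_grasp_scenario <- function(effect_scale = 1,
                                   n_trials_per_class = 50L,
                                   rng_seed = 1L) {
  if (effect_scale < 0) {
    stop_validation("default_grasp_scenario: effect_scale must be >= 0")
  }
  amp <- function(a) {
    c(no_movement = 0, power = a, precision = 0.6 * a) * effect_scale
  }
  effects <- list(
    effect_spec("C3", 9, 0.3, 0.5, amp(14.0)),
    effect_spec("C3", 16, 0.3, 0.5, amp(11.2)),
    effect_spec("C4", 9, 0.3, 0.5, amp(9.8)),
    effect_spec("C4", 16, 0.3, 0.5, amp(7.8))
  )
  sim_config(
    n_trials_per_class = n_trials_per_class,
    fs = 250,
    epoch_window_s = c(-2.3, 2.3),
    background_exponent = 1,
    background_scale = 10,
    effects = effects,
    onset_jitter_s = 0.04,
    rng_seed = rng_seed
  )
}

# One epoch of 1/f^alpha colored noise via FFT synthesis with random phases,
# scaled so the theoretical RMS equals `scale`.
colored_noise <- function(n, fs, exponent, scale) {
  freqs <- seq_len(floor(n / 2)) * fs / n
  amps <- freqs^(-exponent / 2)
  nyq <- n %% 2 == 0
  n_half <- length(amps)
  phases <- runif(if (nyq) n_half - 1 else n_half, 0, 2 * pi)
  pos <- if (nyq) {
    c(amps[-n_half] * exp(1i * phases), amps[n_half] * sign(runif(1) - 0.5))
  } else {
    amps * exp(1i * phases)
  }
  spec <- complex(n)
  spec[2:(n_half + 1)] <- pos
  if (n_half + 2 <= n) {
    spec[(n_half + 2):n] <- Conj(rev(pos[seq_len(n - n_half - 1)]))
  }
  x <- Re(fft(spec, inverse = TRUE)) / n
  # each conjugate pair contributes 2*A^2/n^2 to Var; a real Nyquist bin A^2/n^2
  var_th <- if (nyq) {
    (2 * sum(amps[-n_half]^2) + amps[n_half]^2) / n^2
  } else {
    2 * sum(amps^2) / n^2
  }
  x * scale / sqrt(var_th)
}

# Hann-windowed sinusoidal burst sampled on time axis `t` (s).
burst_waveform <- function(t, f, onset, duration, amplitude, phase) {
  u <- (t - onset) / duration
  env <- ifelse(u >= 0 & u < 1, 0.5 * (1 - cos(2 * pi * u)), 0)
  amplitude * env * sin(2 * pi * f * (t - onset) + phase)
}

#' Simulate one subject's epoch set
#'
#' Generates `n_trials_per_class` trials per condition in seeded random
#' order. Every channel of every trial carries independent 1/f^alpha
#' background noise; each [effect_spec()] adds a Hann-windowed sinusoidal
#' burst at its channel with the amplitude mapped from the trial's label,
#' onset jittered uniformly within `onset_jitter_s` and carrier phase
#' randomized per trial (so class information lives in power, not in
#' phase-locked averages). Bit-identical output for a fixed `rng_seed`.
#'
#' @param cfg A [sim_config()].
#' @param montage A [montage()]; every effect channel must appear in it.
#' @param subject_id Subject identifier stored in the result.
#'
#' @return A [epoch_set()] with `3 * n_trials_per_class` trials.
#' @export
simulate_subject <- function(cfg, montage = default_montage(),
                             subject_id = "S1") {
  effect_chans <- vapply(cfg$effects, `[[`, "", "channel")
  unknown <- setdiff(effect_chans, montage$channel_names)
  if (length(unknown)) {
    stop_validation("simulate_subject: effect channel(s) %s not in montage",
                    paste(unique(unknown), collapse = ", "))
  }
  n_ch <- length(montage$channel_names)
  n_samp <- round((cfg$epoch_window_s[2] - cfg$epoch_window_s[1]) * cfg$fs)
  t <- cfg$epoch_window_s[1] + (seq_len(n_samp) - 1) / cfg$fs
  n_trials <- 3L * cfg$n_trials_per_class
  with_seed(cfg$rng_seed, {
    labels <- sample(rep(GRASP_CONDITIONS, each = cfg$n_trials_per_class))
    data <- array(0, dim = c(n_trials, n_ch, n_samp))
    for (tr in seq_len(n_trials)) {
      for (ch in seq_len(n_ch)) {
        data[tr, ch, ] <- colored_noise(
          n_samp, cfg$fs, cfg$background_exponent, cfg$background_scale
        )
      }
      for (ef in cfg$effects) {
        a <- ef$amplitude_by_class[[labels[tr]]]
        jitter <- runif(1, -cfg$onset_jitter_s, cfg$onset_jitter_s)
        phase <- runif(1, 0, 2 * pi)
        if (a > 0) {
          ch <- match(ef$channel, montage$channel_names)
          data[tr, ch, ] <- data[tr, ch, ] + burst_waveform(
            t, ef$center_freq_hz, ef$onset_s + jitter, ef$duration_s,
            a, phase
          )
        }
      }
    }
    epoch_set(data, fs = cfg$fs, t0_offset = cfg$epoch_window_s[1],
              labels = labels, montage = montage, subject_id = subject_id)
  })
}
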