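#' Complex Morlet wavelet family
#'
#' Builds one complex Morlet kernel per center frequency:
#' `k(t) = exp(i 2 pi f t) * exp(-t^2 / (2 sigma_t^2))` with
#' `sigma_t = n_cycles / (2 pi f)`, truncated at `+/- 4 sigma_t` (odd
#' length, symmetric about t = 0) and normalized to unit energy
#' (`sum(|k|^2) * dt == 1`), which makes power comparable across
#' frequencies.
#'
#' @param cfg A [pipeline_config()] supplying `center_freqs_hz` and
#'   `n_cycles`.
#' @param fs Sampling rate (Hz) the kernels are sampled at.
#' @return An object of class `gw_wavelets` with elements
#'   `center_freqs_hz`, `n_cycles`, `fs`, `kernels` (list of complex
#'   vectors), `sigma_t_s` and `support_s` (per-frequency half-width of the
#'   truncated kernel, seconds).
#' @export
#' @examples
#' fam <- build_family(pipeline_config(), fs = 250)
#' fam$sigma_t_s[fam$center_freqs_hz == 9] # 4 / (2 * pi * 9) ~ 0.0707 s
build_family <- function(cfg, fs = 250) {
  if (any(cfg$center_freqs_hz <= 0)) {
    stop_validation("build_family: center frequencies must be positive")
  }
  sigma_t <- cfg$n_cycles / (2 * pi * cfg$center_freqs_hz)
  kernels <- lapply(seq_along(cfg$center_freqs_hz), function(i) {
    f <- cfg$center_freqs_hz[i]
    half <- ceiling(4 * sigma_t[i] * fs)
    t <- (-half:half) / fs
    k <- exp(1i * 2 * pi * f * t) * exp(-t^2 / (2 * sigma_t[i]^2))
    k / sqrt(sum(Mod(k)^2) / fs)
  })
  structure(
    list(
      center_freqs_hz = cfg$center_freqs_hz,
      band_names = cfg$band_names,
      n_cycles = cfg$n_cycles,
      fs = fs,
      kernels = kernels,
      sigma_t_s = sigma_t,
      support_s = vapply(kernels, function(k) (length(k) - 1) / 2 / fs, 0)
    ),
    class = "gw_wavelets"
  )
}

#' @export
print.gw_wavelets <- function(x, ...) {
  cat(sprintf(
    "<gw_wavelets> %d-cycle Morlet kernels at %s Hz @ %g Hz (half-support %s s)\n",
    x$n_cycles, paste(x$center_freqs_hz, collapse = "/"), x$fs,
    paste(sprintf("%.2f", x$support_s), collapse = "/")
  ))
  invisible(x)
}

#' Wavelet time-frequency transform
#'
#' Convolves every (trial, channel) time series with each Morlet kernel
#' ('same'-length FFT convolution) and stores the squared magnitude of the
#' complex coefficients as power. `valid_mask[f, s]` flags samples at least
#' one kernel half-support away from both epoch edges at frequency `f`,
#' i.e. free of convolution edge effects.
#'
#' @param epochs A [epoch_set()].
#' @param family A [build_family()] with matching sampling rate.
#' @return An object of class `gw_tfr` with `power` indexed
#'   (trial, channel, frequency, sample), axes `freqs_hz` / `times_s`,
#'   `valid_mask` (frequency x sample), and the epochs' labels, montage and
#'   subject id carried along. Amplitude is `sqrt(power)`; see
#'   [tfr_amplitude()].
#' @export
wavelet_transform <- function(epochs, family) {
  if (!isTRUE(all.equal(epochs$fs, family$fs))) {
    stop_validation("wavelet_transform: epochs fs %g != family fs %g",
                    epochs$fs, family$fs)
  }
  d <- dim(epochs$data)
  n_samp <- d[3]
  n_freq <- length(family$kernels)
  m <- vapply(family$kernels, length, 0L)
  nf <- stats::nextn(n_samp + max(m) - 1L, 2)
  kern_fft <- lapply(family$kernels, function(k) fft(c(k, complex(nf - length(k)))))
  power <- array(0, dim = c(d[1], d[2], n_freq, n_samp))
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      xf <- fft(c(epochs$data[tr, ch, ], numeric(nf - n_samp)))
      for (fi in seq_len(n_freq)) {
        conv <- fft(xf * kern_fft[[fi]], inverse = TRUE) / nf
        offset <- (m[fi] - 1L) %/% 2L
        power[tr, ch, fi, ] <- Mod(conv[(offset + 1):(offset + n_samp)])^2
      }
    }
  }
  half <- (m - 1L) %/% 2L
  valid_mask <- t(vapply(half, function(h) {
    s <- seq_len(n_samp)
    s > h & s <= n_samp - h
  }, logical(n_samp)))
  structure(
    list(
      power = power,
      freqs_hz = family$center_freqs_hz,
      band_names = family$band_names,
      times_s = epoch_times(epochs),
      valid_mask = valid_mask,
      support_s = family$support_s,
      fs = epochs$fs,
      labels = epochs$labels,
      montage = epochs$montage,
      subject_id = epochs$subject_id
    ),
    class = "gw_tfr"
  )
}

#' Wavelet amplitude
#'
#' @param tfr A [wavelet_transform()] result.
#' @return Array of `sqrt(power)`, same shape as `tfr$power`.
#' @export
tfr_amplitude <- function(tfr) sqrt(tfr$power)

#' @export
print.gw_tfr <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf(
    "<gw_tfr> subject %s: %d trials x %d channels x %d freqs (%s Hz) x %d samples\n",
    x$subject_id, d[1], d[2], d[3],
    paste(x$freqs_hz, collapse = "/"), d[4]
  ))
  invisible(x)
}

#' Condition-mean time-frequency power
#'
#' @param tfr A [wavelet_transform()] result.
#' @param condition Condition label to average.
#' @param labels Per-trial labels; defaults to those stored in `tfr`.
#' @return Array (channel, frequency, sample) of mean power over the
#'   condition's trials.
#' @export
average_tfr <- function(tfr, condition, labels = tfr$labels) {
  sel <- which(labels == condition)
  if (!length(sel)) {
    stop_validation("average_tfr: no trials with condition '%s'", condition)
  }
  out <- apply(tfr$power[sel, , , , drop = FALSE], c(2, 3, 4), mean)
  dimnames(out) <- list(tfr$montage$channel_names, tfr$freqs_hz, NULL)
  out
}

# Nearest sample index to a time point.
nearest_sample <- function(times, time_s) which.min(abs(times - time_s))

#' Topographic snapshot of condition-mean wavelet power
#'
#' Per-channel condition-mean power at one (time, frequency) point, plus an
#' interpolated scalp grid (thin-plate spline over the unit head disc,
#' exact at electrode positions, masked outside the head circle).
#'
#' @param tfr A [wavelet_transform()] result.
#' @param condition Condition label.
#' @param time_s Snapshot time (s relative to onset); mapped to the nearest
#'   sample, which must be free of edge effects at `freq_hz`.
#' @param freq_hz One of the family's center frequencies.
#' @param labels Per-trial labels; defaults to those stored in `tfr`.
#' @param montage Montage; defaults to the one stored in `tfr`.
#' @param grid_n Interpolation grid resolution per axis.
#' @return An object of class `gw_topomap`: named `channel_values`, grid
#'   vectors `x`, `y` and matrix `z` (NA outside the head circle), and the
#'   snapshot coordinates actually used.
#' @export
topo_snapshot <- function(tfr, condition, time_s, freq_hz,
                          labels = tfr$labels, montage = tfr$montage,
                          grid_n = 67) {
  fi <- which(abs(tfr$freqs_hz - freq_hz) < 1e-9)
  if (!length(fi)) {
    stop_validation("topo_snapshot: %g Hz not among the analysis frequencies (%s)",
                    freq_hz, paste(tfr$freqs_hz, collapse = ", "))
  }
  si <- nearest_sample(tfr$times_s, time_s)
  if (!tfr$valid_mask[fi, si]) {
    stop_validation(
      "topo_snapshot: t = %g s is edge-contaminated at %g Hz (valid span [%g, %g] s)",
      time_s, freq_hz,
      min(tfr$times_s[tfr$valid_mask[fi, ]]),
      max(tfr$times_s[tfr$valid_mask[fi, ]])
    )
  }
  sel <- which(labels == condition)
  if (!length(sel)) {
    stop_validation("topo_snapshot: no trials with condition '%s'", condition)
  }
  vals <- apply(tfr$power[sel, , fi, si, drop = FALSE], 2, mean)
  vals <- setNames(as.numeric(vals), montage$channel_names)
  grid <- tps_interpolate(montage$positions_2d, vals, grid_n = grid_n)
  structure(
    list(channel_values = vals, x = grid$x, y = grid$y, z = grid$z,
         time_s = tfr$times_s[si], freq_hz = tfr$freqs_hz[fi],
         condition = condition, montage = montage),
    class = "gw_topomap"
  )
}
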