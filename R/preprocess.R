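# Apply a function over every (trial, channel) time series of an epoch set.
map_trials <- function(epochs, f) {
  d <- dim(epochs$data)
  out <- epochs$data
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      out[tr, ch, ] <- f(epochs$data[tr, ch, ])
    }
  }
  epochs$data <- out
  epochs
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward-backward
#' ([signal::filtfilt()]) independently per trial and channel, so the
#' filter introduces no group delay (post-onset latencies are not shifted).
#'
#' @param epochs A [epoch_set()].
#' @param lo_hz,hi_hz Corner frequencies; `0 < lo_hz < hi_hz < fs/2`.
#' @return A filtered [epoch_set()] of identical shape.
#' @export
bandpass <- function(epochs, lo_hz = 1, hi_hz = 30) {
  if (!(lo_hz > 0 && lo_hz < hi_hz && hi_hz < epochs$fs / 2)) {
    stop_validation(
      "bandpass: need 0 < lo_hz < hi_hz < fs/2 (= %g)", epochs$fs / 2
    )
  }
  bf <- signal::butter(4, c(lo_hz, hi_hz) / (epochs$fs / 2), type = "pass")
  map_trials(epochs, function(x) signal::filtfilt(bf, x))
}

#' Baseline correction
#'
#' Subtracts, per trial and channel, the mean over the baseline window
#' (default: the 200 ms immediately before movement onset). Afterwards the
#' corrected signal's mean over that window is 0 to float tolerance.
#'
#' @param epochs A [epoch_set()].
#' @param window_s Length-2 numeric (start, end) s relative to onset;
#'   half-open `[start, end)`, must lie inside the epoch and end at or
#'   before onset.
#' @return A corrected [epoch_set()].
#' @export
baseline_correct <- function(epochs, window_s = c(-0.2, 0)) {
  idx <- window_sample_idx(epochs, window_s)
  if (window_s[2] > 0) {
    stop_validation("baseline_correct: window must end at or before onset")
  }
  map_trials(epochs, function(x) x - mean(x[idx]))
}

# Sample indices covered by the half-open window [start, end) in seconds.
window_sample_idx <- function(epochs, window_s) {
  t <- epoch_times(epochs)
  if (window_s[1] < t[1] - 1e-9 ||
        window_s[2] > t[length(t)] + 1 / epochs$fs + 1e-9) {
    stop_validation(
      "window [%g, %g) s outside epoch span [%g, %g) s",
      window_s[1], window_s[2], t[1], t[length(t)] + 1 / epochs$fs
    )
  }
  idx <- which(t >= window_s[1] - 1e-9 & t < window_s[2] - 1e-9)
  if (!length(idx)) stop_validation("window contains no samples")
  idx
}

#' Z-score normalization
#'
#' Standardizes each channel within a subject, pooling samples over all of
#' that subject's trials: after the transform every channel has pooled mean
#' 0 and pooled standard deviation 1.
#'
#' @param epochs A [epoch_set()].
#' @return A standardized [epoch_set()].
#' @export
zscore <- function(epochs) {
  d <- dim(epochs$data)
  for (ch in seq_len(d[2])) {
    v <- epochs$data[, ch, ]
    s <- sd(as.numeric(v))
    if (!is.finite(s) || s == 0) {
      stop_validation(
        "zscore: channel %s has zero variance", epochs$montage$channel_names[ch]
      )
    }
    epochs$data[, ch, ] <- (v - mean(v)) / s
  }
  epochs
}

#' Pluggable artifact-removal hook
#'
#' Placeholder stage where users of real recordings can insert artifact
#' removal (e.g. an ICA-based cleaner) between filtering and baseline
#' correction. The default is the identity.
#'
#' @param epochs A [epoch_set()].
#' @return `epochs`, unchanged.
#' @export
artifact_hook_identity <- function(epochs) epochs

#' Standard preprocessing pipeline
#'
#' Band-pass filter, optional artifact hook, baseline correction, then
#' z-score normalization — in that order.
#'
#' @param epochs A [epoch_set()].
#' @param cfg A [pipeline_config()].
#' @param artifact_hook Function `epochs -> epochs` run between filtering
#'   and baseline correction; defaults to the identity.
#' @return A preprocessed [epoch_set()].
#' @export
preprocess <- function(epochs, cfg = pipeline_config(),
                       artifact_hook = artifact_hook_identity) {
  epochs |>
    bandpass(cfg$bandpass_lo_hz, cfg$bandpass_hi_hz) |>
    artifact_hook() |>
    baseline_correct(cfg$baseline_window_s) |>
    zscore()
}
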