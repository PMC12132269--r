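#' Pipeline configuration
#'
#' Bundles every tunable analysis parameter. Defaults reproduce the
#' pipeline's standard settings: 1-30 Hz band-pass, 200 ms pre-onset
#' baseline, 4-cycle complex Morlet wavelets at 2/9/16/23 Hz (bands
#' low / alpha / beta_low / beta_high), moment features over the
#' [0, 0.8) s post-onset window, topographic snapshots at 300 ms,
#' stratified 5-fold cross-validation, and 20 permutation-importance
#' repeats.
#'
#' @param bandpass_lo_hz,bandpass_hi_hz Band-pass corner frequencies (Hz).
#' @param baseline_window_s Length-2 numeric, (start, end) s relative to
#'   onset; must lie before onset.
#' @param n_cycles Wavelet cycles (sets time-frequency trade-off via
#'   `sigma_t = n_cycles / (2 * pi * f)`).
#' @param center_freqs_hz Strictly increasing wavelet center frequencies,
#'   all within the band-pass.
#' @param band_names Band labels parallel to `center_freqs_hz`; used in
#'   feature names, so must not contain ".".
#' @param feature_window_s Length-2 numeric, (start, end) s window over
#'   which amplitude moments are computed.
#' @param topo_time_s Time point (s) for topographic snapshots.
#' @param cv_folds Cross-validation fold count (>= 2).
#' @param rng_seed Root seed for all stochastic stages.
#' @param n_permutation_repeats Shuffles per feature in permutation
#'   importance.
#'
#' @return An object of class `gw_config` (a validated list).
#' @export
pipeline_config <- function(bandpass_lo_hz = 1,
                            bandpass_hi_hz = 30,
                            baseline_window_s = c(-0.2, 0),
                            n_cycles = 4,
                            center_freqs_hz = c(2, 9, 16, 23),
                            band_names = c("low", "alpha", "beta_low",
                                           "beta_high"),
                            feature_window_s = c(0, 0.8),
                            topo_time_s = 0.3,
                            cv_folds = 5,
                            rng_seed = 42L,
                            n_permutation_repeats = 20L) {
  cfg <- structure(
    list(
      bandpass_lo_hz = bandpass_lo_hz, bandpass_hi_hz = bandpass_hi_hz,
      baseline_window_s = as.numeric(baseline_window_s),
      n_cycles = n_cycles,
      center_freqs_hz = as.numeric(center_freqs_hz),
      band_names = as.character(band_names),
      feature_window_s = as.numeric(feature_window_s),
      topo_time_s = topo_time_s,
      cv_folds = as.integer(cv_folds),
      rng_seed = as.integer(rng_seed),
      n_permutation_repeats = as.integer(n_permutation_repeats)
    ),
    class = "gw_config"
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    if (!(bandpass_lo_hz > 0 && bandpass_lo_hz < bandpass_hi_hz)) {
      stop_validation("config: need 0 < bandpass_lo_hz < bandpass_hi_hz")
    }
    if (is.unsorted(center_freqs_hz, strictly = TRUE)) {
      stop_validation("config: center_freqs_hz must be strictly increasing")
    }
    if (any(center_freqs_hz < bandpass_lo_hz |
              center_freqs_hz > bandpass_hi_hz)) {
      stop_validation("config: center frequencies must lie in the band-pass")
    }
    if (length(band_names) != length(center_freqs_hz)) {
      stop_validation("config: band_names must parallel center_freqs_hz")
    }
    if (any(grepl(".", band_names, fixed = TRUE))) {
      stop_validation("config: band names must not contain '.'")
    }
    if (cv_folds < 2) {
      stop_validation("config: cv_folds must be >= 2")
    }
    if (n_cycles <= 0) {
      stop_validation("config: n_cycles must be positive")
    }
    if (length(baseline_window_s) != 2 ||
          baseline_window_s[1] >= baseline_window_s[2]) {
      stop_validation("config: baseline window must be (start, end), start < end")
    }
    if (baseline_window_s[2] > 0) {
      stop_validation("config: baseline window must end at or before onset")
    }
    if (length(feature_window_s) != 2 ||
          feature_window_s[1] >= feature_window_s[2]) {
      stop_validation("config: feature window must be (start, end), start < end")
    }
    if (n_permutation_repeats < 1) {
      stop_validation("config: n_permutation_repeats must be >= 1")
    }
  })
  invisible(cfg)
}

#' @export
print.gw_config <- function(x, ...) {
  cat(sprintf(
    "<gw_config> band-pass %g-%g Hz; %d-cycle wavelets at %s Hz (%s);\n  baseline [%g, %g) s; features over [%g, %g) s; topo @ %g s; %d-fold CV; seed %d\n",
    x$bandpass_lo_hz, x$bandpass_hi_hz, x$n_cycles,
    paste(x$center_freqs_hz, collapse = "/"),
    paste(x$band_names, collapse = "/"),
    x$baseline_window_s[1], x$baseline_window_s[2],
    x$feature_window_s[1], x$feature_window_s[2],
    x$topo_time_s, x$cv_folds, x$rng_seed
  ))
  invisible(x)
}
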