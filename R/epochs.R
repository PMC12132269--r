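#' EEG epoch set
#'
#' Container for segmented multichannel EEG: a numeric array indexed
#' (trial, channel, sample) plus sampling rate, epoch timing, per-trial
#' condition labels and the electrode montage. Sample index `s` (1-based)
#' corresponds to time `t0_offset + (s - 1) / fs` seconds relative to
#' movement onset (`t = 0`); epoch windows are half-open `[start, end)`.
#'
#' @param data Numeric array, dims (n_trials, n_channels, n_samples).
#'   Microvolt-scale units (unitless after z-scoring).
#' @param fs Sampling rate, Hz.
#' @param t0_offset Time (s) of the first sample relative to movement onset;
#'   negative means the epoch starts before onset.
#' @param labels Per-trial condition, each one of
#'   `r paste(grasp_conditions(), collapse = ", ")`.
#' @param montage A [montage()] whose channel count matches `dim(data)[2]`.
#' @param subject_id Subject identifier string.
#'
#' @return An object of class `gw_epochs`.
#' @export
epoch_set <- function(data, fs, t0_offset, labels, montage,
                      subject_id = "S1") {
  if (length(dim(data)) != 3) {
    stop_validation("epoch_set: data must be a (trial, channel, sample) array")
  }
  if (dim(data)[1] < 1) {
    stop_validation("epoch_set: empty trial axis")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop_validation("epoch_set: fs must be a positive scalar")
  }
  labels <- as.character(labels)
  if (length(labels) != dim(data)[1]) {
    stop_validation(
      "epoch_set: %d labels for %d trials", length(labels), dim(data)[1]
    )
  }
  bad <- setdiff(unique(labels), GRASP_CONDITIONS)
  if (length(bad)) {
    stop_validation(
      "epoch_set: unknown label(s) %s; expected one of %s",
      paste(bad, collapse = ", "), paste(GRASP_CONDITIONS, collapse = ", ")
    )
  }
  if (!inherits(montage, "gw_montage")) {
    stop_validation("epoch_set: montage must be a gw_montage")
  }
  if (length(montage$channel_names) != dim(data)[2]) {
    stop_validation(
      "epoch_set: montage has %d channels but data has %d",
      length(montage$channel_names), dim(data)[2]
    )
  }
  structure(
    list(
      data = data, fs = fs, t0_offset = t0_offset,
      labels = labels, montage = montage,
      subject_id = as.character(subject_id)
    ),
    class = "gw_epochs"
  )
}

#' Time axis of an epoch set
#'
#' @param epochs A [epoch_set()].
#' @return Numeric vector of per-sample times (s) relative to movement onset.
#' @export
epoch_times <- function(epochs) {
  epochs$t0_offset + (seq_len(dim(epochs$data)[3]) - 1) / epochs$fs
}

#' @export
print.gw_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<gw_epochs> subject %s: %d trials x %d channels x %d samples @ %g Hz, t in [%.3f, %.3f) s\n",
    x$subject_id, d[1], d[2], d[3], x$fs,
    x$t0_offset, x$t0_offset + d[3] / x$fs
  ))
  print(table(factor(x$labels, levels = GRASP_CONDITIONS)))
  invisible(x)
}

#' Write an epoch set to the interchange layout
#'
#' Writes a directory with `epochs.bin` — the raw data as 64-bit
#' little-endian floats in trial-major C order (sample index fastest, then
#' channel, then trial) — and `meta.json` holding fs, t0_offset, channel
#' names, montage coordinates and reference, labels, and subject id. Byte
#' output is deterministic for a fixed input.
#'
#' @param epochs A valid [epoch_set()].
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  if (!inherits(epochs, "gw_epochs")) {
    stop_validation("write_epochs: not a gw_epochs object")
  }
  if (dim(epochs$data)[1] < 1) {
    stop_validation("write_epochs: refusing to write an empty trial axis")
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs$data)
  # aperm to (sample, channel, trial): column-major write order is then
  # sample-fastest within channel within trial, i.e. trial-major C order.
  con <- file(file.path(path, "epochs.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(epochs$data, c(3, 2, 1))), con,
           size = 8, endian = "little")
  meta <- list(
    fs = epochs$fs,
    t0_offset = epochs$t0_offset,
    n_trials = d[1], n_channels = d[2], n_samples = d[3],
    channels = epochs$montage$channel_names,
    positions_2d = unname(apply(epochs$montage$positions_2d, 1, as.numeric,
                                simplify = FALSE)),
    reference = epochs$montage$reference,
    labels = epochs$labels,
    subject_id = epochs$subject_id
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an epoch set from the interchange layout
#'
#' Inverse of [write_epochs()]: metadata round-trips exactly and the data
#' array is bit-identical.
#'
#' @param path Directory containing `epochs.bin` and `meta.json`.
#' @return A [epoch_set()].
#' @export
read_epochs <- function(path) {
  meta_path <- file.path(path, "meta.json")
  bin_path <- file.path(path, "epochs.bin")
  if (!file.exists(meta_path)) {
    stop_validation("read_epochs: missing meta.json in %s", path)
  }
  if (!file.exists(bin_path)) {
    stop_validation("read_epochs: missing epochs.bin in %s", path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("fs", "t0_offset", "n_trials", "n_channels", "n_samples",
                  "channels", "labels", "subject_id")) {
    if (is.null(meta[[field]])) {
      stop_validation("read_epochs: meta.json lacks required field '%s'",
                      field)
    }
  }
  n <- meta$n_trials * meta$n_channels * meta$n_samples
  con <- file(bin_path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  if (length(raw) != n) {
    stop_validation("read_epochs: epochs.bin truncated (%d of %d values)",
                    length(raw), n)
  }
  data <- aperm(
    array(raw, dim = c(meta$n_samples, meta$n_channels, meta$n_trials)),
    c(3, 2, 1)
  )
  pos <- meta$positions_2d
  pos <- if (is.list(pos)) do.call(rbind, lapply(pos, as.numeric)) else
    matrix(as.numeric(pos), ncol = 2)
  m <- montage(meta$channels, pos, reference = meta$reference)
  epoch_set(data, fs = meta$fs, t0_offset = meta$t0_offset,
            labels = meta$labels, montage = m, subject_id = meta$subject_id)
}
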