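FEATURE_STATS <- c("mean", "variance", "skewness", "kurtosis")

# Population moments of a series: mean, biased variance, skewness
# m3/m2^1.5, excess kurtosis m4/m2^2 - 3.
amp_moments <- function(x) {
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 == 0) {
    return(c(mean = m, variance = 0, skewness = NA_real_,
             kurtosis = NA_real_))
  }
  c(mean = m, variance = m2,
    skewness = mean(d^3) / m2^1.5,
    kurtosis = mean(d^4) / m2^2 - 3)
}

#' Canonical feature name
#'
#' Features are named `<channel>.<band>.<stat>`, e.g. `C3.alpha.kurtosis`.
#'
#' @param channel Electrode label.
#' @param band Band label (no "." allowed).
#' @param stat One of `mean`, `variance`, `skewness`, `kurtosis`.
#' @return The canonical name string.
#' @export
feature_name <- function(channel, band, stat) {
  if (!all(stat %in% FEATURE_STATS)) {
    stop_validation("feature_name: unknown stat '%s'",
                    paste(setdiff(stat, FEATURE_STATS), collapse = ", "))
  }
  if (any(grepl(".", c(channel, band), fixed = TRUE))) {
    stop_validation("feature_name: channel/band must not contain '.'")
  }
  paste(channel, band, stat, sep = ".")
}

#' Parse a canonical feature name
#'
#' @param name Feature name as produced by [feature_name()].
#' @return Data frame with columns `channel`, `band`, `stat`.
#' @export
parse_feature_name <- function(name) {
  parts <- strsplit(name, ".", fixed = TRUE)
  bad <- lengths(parts) != 3
  if (any(bad)) {
    stop_validation("parse_feature_name: malformed name(s) %s",
                    paste(name[bad], collapse = ", "))
  }
  m <- do.call(rbind, parts)
  data.frame(channel = m[, 1], band = m[, 2], stat = m[, 3])
}

#' Statistical wavelet-amplitude features
#'
#' For every trial, channel and frequency band, computes the four
#' statistical moments (mean, population variance, skewness, excess
#' kurtosis) of the wavelet amplitude time series restricted to the
#' feature window — with 8 channels and 4 bands, 128 named features per
#' instance. The window must be free of convolution edge effects at every
#' analysis frequency.
#'
#' @param tfr A [wavelet_transform()] result.
#' @param window_s Length-2 numeric (start, end) s, half-open.
#' @return An object of class `gw_features`: numeric matrix `values`
#'   (instance x feature) with canonical column names, `feature_names`,
#'   per-instance `labels`, and `subject_id`.
#' @export
extract_features <- function(tfr, window_s = c(0, 0.8)) {
  t <- tfr$times_s
  idx <- which(t >= window_s[1] - 1e-9 & t < window_s[2] - 1e-9)
  if (!length(idx)) {
    stop_validation("extract_features: window contains no samples")
  }
  invalid <- !tfr$valid_mask[, idx, drop = FALSE]
  if (any(invalid)) {
    fbad <- tfr$freqs_hz[rowSums(invalid) > 0]
    stop_validation(
      "extract_features: window [%g, %g) s overlaps edge-contaminated samples at %s Hz",
      window_s[1], window_s[2], paste(fbad, collapse = ", ")
    )
  }
  d <- dim(tfr$power)
  chans <- tfr$montage$channel_names
  bands <- tfr$band_names
  names_out <- unlist(lapply(seq_along(chans), function(ci) {
    unlist(lapply(seq_along(bands), function(bi) {
      feature_name(chans[ci], bands[bi], FEATURE_STATS)
    }))
  }))
  values <- matrix(NA_real_, nrow = d[1], ncol = length(names_out),
                   dimnames = list(NULL, names_out))
  for (tr in seq_len(d[1])) {
    col <- 0L
    for (ci in seq_len(d[2])) {
      for (bi in seq_len(d[3])) {
        amp <- sqrt(tfr$power[tr, ci, bi, idx])
        mom <- amp_moments(amp)
        if (anyNA(mom)) {
          stop_validation(
            "extract_features: zero-variance amplitude (trial %d, channel %s, band %s); skewness/kurtosis undefined",
            tr, chans[ci], bands[bi]
          )
        }
        values[tr, col + 1:4] <- mom
        col <- col + 4L
      }
    }
  }
  structure(
    list(values = values, feature_names = names_out,
         labels = tfr$labels, subject_id = tfr$subject_id),
    class = "gw_features"
  )
}

#' @export
print.gw_features <- function(x, ...) {
  cat(sprintf("<gw_features> subject %s: %d instances x %d features\n",
              x$subject_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Convert a feature table to a data frame
#'
#' @param x A [extract_features()] result.
#' @param ... Unused.
#' @return Data frame of features plus `label` and `subject_id` columns.
#' @export
as.data.frame.gw_features <- function(x, ...) {
  df <- as.data.frame(x$values)
  df$label <- x$labels
  df$subject_id <- x$subject_id
  df
}

#' Write / read a feature table as CSV
#'
#' The CSV has one column per feature (canonical names) plus `label` and
#' `subject_id`.
#'
#' @param features A [extract_features()] result.
#' @param path CSV file path.
#' @return `path` invisibly (write); a `gw_features` (read).
#' @export
write_features <- function(features, path) {
  write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta_cols <- c("label", "subject_id")
  feat_cols <- setdiff(names(df), meta_cols)
  structure(
    list(values = as.matrix(df[, feat_cols, drop = FALSE]),
         feature_names = feat_cols,
         labels = df$label,
         subject_id = unique(df$subject_id)[1]),
    class = "gw_features"
  )
}
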