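#' Plot a topographic scalp map
#'
#' Filled image of the interpolated grid with the head circle, electrode
#' markers and labels overlaid (base graphics).
#'
#' @param x A `gw_topomap` from [topo_snapshot()] or [topo_importance()].
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @export
plot.gw_topomap <- function(x, main = NULL, ...) {
  if (is.null(main)) {
    main <- if (!is.null(x$freq_hz)) {
      sprintf("%s, %g Hz @ %.0f ms", x$condition, x$freq_hz,
              1000 * x$time_s)
    } else {
      sprintf("importance, %s band", x$band)
    }
  }
  graphics::image(x$x, x$y, x$z, asp = 1, axes = FALSE,
                  xlab = "", ylab = "", main = main,
                  col = grDevices::hcl.colors(64, "Viridis"), ...)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th))
  pos <- x$montage$positions_2d
  graphics::points(pos[, 1], pos[, 2], pch = 21, bg = "white")
  graphics::text(pos[, 1], pos[, 2], labels = rownames(pos), pos = 3,
                 cex = 0.7)
  invisible(x)
}

#' Plot a condition-mean time-frequency map for one channel
#'
#' @param tfr A [wavelet_transform()] result.
#' @param condition Condition label.
#' @param channel Electrode label.
#' @param tlim Time range (s) to display.
#' @param main Plot title.
#' @export
plot_tfr_map <- function(tfr, condition, channel, tlim = c(-1, 1),
                         main = NULL) {
  avg <- average_tfr(tfr, condition)
  ci <- match(channel, tfr$montage$channel_names)
  if (is.na(ci)) stop_validation("plot_tfr_map: unknown channel %s", channel)
  sel <- tfr$times_s >= tlim[1] & tfr$times_s <= tlim[2]
  z <- t(avg[ci, , sel])
  if (is.null(main)) main <- sprintf("%s @ %s", condition, channel)
  graphics::image(tfr$times_s[sel], seq_along(tfr$freqs_hz), z,
                  xlab = "time (s)", ylab = "frequency (Hz)", axes = FALSE,
                  main = main, col = grDevices::hcl.colors(64, "Viridis"))
  graphics::axis(1)
  graphics::axis(2, at = seq_along(tfr$freqs_hz), labels = tfr$freqs_hz)
  graphics::abline(v = 0, lty = 2, col = "white")
  graphics::box()
  invisible(tfr)
}

#' Boxplot of top permutation-importance features
#'
#' @param result A [permutation_importance()] result.
#' @param k Number of top features to show.
#' @param main Plot title.
#' @export
plot_importance_box <- function(result, k = 10, main = "Permutation feature importance") {
  feats <- top_k(result, k)
  m <- t(result$scores[feats, , drop = FALSE])
  graphics::par(mar = c(9, 4, 3, 1))
  graphics::boxplot(as.data.frame(m), las = 2, main = main,
                    names = gsub(".", " ", feats, fixed = TRUE),
                    ylab = "accuracy drop")
  graphics::abline(h = 0, lty = 3)
  invisible(result)
}
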