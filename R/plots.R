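#' Plot a HEP average
#'
#' Butterfly plot of the per-channel average waveforms with the R-peak
#' at time 0; a channel subset can be highlighted.
#'
#' @param x a `hep_average`.
#' @param channels optional channels to draw in colour (others grey).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.hep_average <- function(x, channels = NULL, ...) {
  graphics::matplot(x$times_ms, t(x$mean), type = "l", lty = 1,
                    col = "grey60",
                    xlab = "time relative to R-peak (ms)",
                    ylab = expression(amplitude ~ (mu * V)),
                    main = paste0("HEP average (", x$condition, ", ",
                                  x$n_trials, " trials)"), ...)
  if (!is.null(channels)) {
    idx <- match(channels, x$labels)
    graphics::matlines(x$times_ms, t(x$mean[idx, , drop = FALSE]),
                       lty = 1, lwd = 2)
  }
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Plot a cluster permutation test result
#'
#' Image of the observed t map over channels and time with the member
#' samples of each cluster marked.
#'
#' @param x a `hep_cluster_test`.
#' @param ... unused.
#' @export
plot.hep_cluster_test <- function(x, ...) {
  tm <- x$tmap
  tx <- x$times_ms %||% seq_len(ncol(tm))
  graphics::image(tx, seq_len(nrow(tm)), t(tm),
                  col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  xlab = "time (ms)", ylab = "channel",
                  yaxt = "n", main = "paired t map with clusters")
  graphics::axis(2, at = seq_len(nrow(tm)), labels = x$labels, las = 2,
                 cex.axis = 0.6)
  for (cl in x$detail) {
    graphics::points(tx[cl$members[, 2]], cl$members[, 1], pch = 15,
                     cex = 0.4)
  }
  invisible(x)
}

#' Plot a surrogate specificity result
#'
#' Histogram of the surrogate max-|cluster-mass| distribution with the
#' original statistic marked.
#'
#' @param x a `surrogate_null`.
#' @param ... passed to [graphics::hist()].
#' @export
plot.surrogate_null <- function(x, ...) {
  graphics::hist(x$surrogate_masses,
                 breaks = max(10, x$n_surrogates %/% 5),
                 xlim = range(c(x$surrogate_masses, x$original_mass)),
                 xlab = "max |cluster mass|",
                 main = "surrogate null vs original", ...)
  graphics::abline(v = x$original_mass, col = "red", lwd = 2)
  invisible(x)
}
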