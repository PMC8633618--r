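#' Zero-phase Butterworth band-pass filter
#'
#' Fourth-order two-pass (forward and reverse) Butterworth band-pass,
#' applied per channel; the two-pass scheme removes the group delay so
#' in-band peak latencies are preserved.
#'
#' @param x numeric vector or channels x samples matrix.
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz (0 < low < high < fs/2).
#' @param order filter order per pass.
#' @param method `"filtfilt"` runs the forward-backward IIR filter;
#'   `"fft"` applies the identical two-pass magnitude response
#'   |H(w)|^2 in the frequency domain (circular boundary), which is
#'   much faster on long continuous recordings.
#' @return filtered signal, same shape as `x`.
#' @export
bandpass_filter <- function(x, fs, low = 0.5, high = 35, order = 4,
                            method = c("filtfilt", "fft")) {
  method <- match.arg(method)
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("infeasible band: need 0 < low < high < fs/2 (fs = ", fs, ")")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  one <- if (method == "filtfilt") {
    function(r) signal::filtfilt(bf, r)
  } else {
    m <- if (is.matrix(x)) ncol(x) else length(x)
    hb <- stats::fft(c(bf$b, numeric(m - length(bf$b))))
    ha <- stats::fft(c(bf$a, numeric(m - length(bf$a))))
    g2 <- Mod(hb / ha)^2  # two-pass (zero-phase) magnitude response
    function(r) Re(stats::fft(stats::fft(r) * g2, inverse = TRUE)) / m
  }
  if (is.matrix(x)) {
    out <- t(apply(x, 1, one))
    dimnames(out) <- dimnames(x)
    out
  } else {
    one(x)
  }
}

# Seeded fixed-point ICA (symmetric FastICA, tanh contrast) on channels
# x samples data, run in a PCA-reduced subspace. The scalp EEG is
# dominated by near-Gaussian background whose rotation ICA cannot (and
# need not) identify; restricting the rotation to the top principal
# components keeps the large non-Gaussian artifact sources (ocular
# activity) identifiable and the iteration well-behaved. Artifact
# removal downstream is subtractive, so reconstruction with no removed
# components is exact regardless of the reduction.
fixed_point_ica <- function(X, n_comp = min(nrow(X), 10), max_iter = 500,
                            tol = 1e-4, seed = 1) {
  Xc <- X - rowMeans(X)
  cv <- Xc %*% t(Xc) / ncol(Xc)
  eg <- eigen(cv, symmetric = TRUE)
  d <- eg$values[seq_len(n_comp)]
  if (any(d <= .Machine$double.eps * max(d))) {
    stop("ICA whitening failed: data covariance is rank-deficient below ",
         n_comp, " components")
  }
  V <- eg$vectors[, seq_len(n_comp), drop = FALSE]
  whiten <- diag(1 / sqrt(d), n_comp) %*% t(V)
  dewhiten <- V %*% diag(sqrt(d), n_comp)
  Z <- whiten %*% Xc
  n <- ncol(Z)
  set.seed(seed)
  # deflation scheme: estimate one component at a time with
  # Gram-Schmidt orthogonalization. Identifiable (non-Gaussian)
  # sources converge in a few dozen iterations; directions spanning
  # the near-Gaussian background have no preferred rotation and may
  # hit the iteration cap - they are kept (any orthonormal completion
  # is equivalent) and reported as unconverged.
  W <- matrix(0, n_comp, n_comp)
  iters <- integer(n_comp)
  converged <- logical(n_comp)
  for (j in seq_len(n_comp)) {
    w <- stats::rnorm(n_comp)
    w <- w / sqrt(sum(w^2))
    for (it in seq_len(max_iter)) {
      wz <- drop(w %*% Z)
      g <- tanh(wz)
      w_new <- drop(Z %*% g) / n - mean(1 - g^2) * w
      if (j > 1) {
        prev <- W[seq_len(j - 1), , drop = FALSE]
        w_new <- w_new - drop(t(prev) %*% (prev %*% w_new))
      }
      nrm <- sqrt(sum(w_new^2))
      if (nrm < .Machine$double.eps) break
      w_new <- w_new / nrm
      delta <- abs(1 - abs(sum(w_new * w)))
      w <- w_new
      if (delta < tol) { converged[j] <- TRUE; break }
    }
    iters[j] <- it
    W[j, ] <- w
  }
  if (!any(converged)) {
    stop("ICA did not converge: no component reached tol = ", tol,
         " within ", max_iter, " iterations (per-component deltas all above",
         " tolerance)")
  }
  unmix <- W %*% whiten          # components = unmix %*% centred data
  mix <- dewhiten %*% t(W)       # artifact estimate = mix[, j] %*% S[j, ]
  list(unmixing = unmix, mixing = mix, n_iter = iters,
       converged = converged, n_comp = n_comp)
}

#' Remove rapid-eye-movement ICA components from EEG
#'
#' Fits a seeded fixed-point ICA on the EEG concatenated across all
#' selected segments, ranks components by the absolute correlation of
#' their time course with the (band-passed) EOG channel, flags those
#' above `corr_thresh`, and removes at most `max_remove` of them (the
#' top ones by correlation) from the whole continuous recording. EOG
#' and ECG channels are left untouched; cardiac artifacts are
#' deliberately not removed by ICA (they are handled by the
#' ECG-confound analyses instead).
#'
#' @param recording a `psg_recording` (EEG channels are cleaned).
#' @param segments a non-empty `segment_set` defining the data the ICA
#'   is fit on.
#' @param corr_thresh absolute EOG-correlation threshold for flagging.
#' @param max_remove maximum number of components removed (default 4).
#' @param n_comp dimensionality of the PCA-reduced subspace the ICA
#'   rotation is estimated in.
#' @param seed RNG seed for the ICA initialisation.
#' @return list with `recording` (cleaned copy) and `decomposition`
#'   (class `ica_decomposition`): unmixing/mixing matrices, per-
#'   component EOG correlations, and the removed component indices.
#' @export
remove_em_components <- function(recording, segments, corr_thresh = 0.4,
                                 max_remove = 4, n_comp = NULL, seed = 1) {
  stopifnot(inherits(recording, "psg_recording"))
  if (length(segments) == 0) stop("segments must be non-empty")
  eeg_idx <- eeg_indices(recording)
  if (length(eeg_idx) < 2) stop("need at least 2 EEG channels for ICA")
  fs <- recording$fs
  seg <- as.data.frame(segments)
  cols <- unlist(lapply(seq_len(nrow(seg)), function(i) {
    i0 <- floor(seg$onset_s[i] * fs) + 1
    i1 <- min(ncol(recording$signals),
              i0 + round(seg$duration_s[i] * fs) - 1)
    i0:i1
  }))
  cols <- unique(cols)
  X <- recording$signals[eeg_idx, cols, drop = FALSE]
  dec <- fixed_point_ica(X, n_comp = n_comp %||% min(length(eeg_idx), 10),
                         seed = seed)
  S <- dec$unmixing %*% (X - rowMeans(X))
  eog <- get_channel(recording, recording$labels[
    which(recording$channel_types == "EOG")[1]])[cols]
  cors <- as.numeric(abs(stats::cor(t(S), eog)))
  flagged <- which(cors > corr_thresh)
  removed <- flagged[order(cors[flagged], decreasing = TRUE)]
  removed <- removed[seq_len(min(length(removed), max_remove))]

  cleaned <- recording
  if (length(removed) > 0) {
    full <- recording$signals[eeg_idx, , drop = FALSE]
    mu <- rowMeans(full)
    S_full <- dec$unmixing %*% (full - mu)
    art <- dec$mixing[, removed, drop = FALSE] %*%
      S_full[removed, , drop = FALSE]
    cleaned$signals[eeg_idx, ] <- full - art
  }
  decomposition <- structure(
    list(unmixing = dec$unmixing, mixing = dec$mixing,
         eog_correlations = cors, removed = removed,
         corr_thresh = corr_thresh, max_remove = max_remove,
         n_iter = dec$n_iter, converged = dec$converged, seed = seed),
    class = "ica_decomposition")
  list(recording = cleaned, decomposition = decomposition)
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat("ICA decomposition:", nrow(x$unmixing), "components (",
      sum(x$converged), "converged )\n")
  if (length(x$removed)) {
    cat("  removed components:",
        paste0(x$removed, " (|r|=", signif(x$eog_correlations[x$removed], 2),
               ")", collapse = ", "), "\n")
  } else {
    cat("  no components above |r| >", x$corr_thresh, "\n")
  }
  invisible(x)
}

#' Serialize an ICA decomposition to JSON
#' @param decomposition an `ica_decomposition`.
#' @param path JSON file path.
#' @export
write_ica <- function(decomposition, path) {
  jsonlite::write_json(
    list(removed = decomposition$removed,
         eog_correlations = decomposition$eog_correlations,
         corr_thresh = decomposition$corr_thresh,
         max_remove = decomposition$max_remove,
         seed = decomposition$seed,
         unmixing = decomposition$unmixing,
         mixing = decomposition$mixing),
    path, digits = NA)
  invisible(path)
}
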