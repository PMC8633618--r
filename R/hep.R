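#' Extract R-peak-locked epochs
#'
#' Cuts one trial per R-peak that falls inside a selected segment:
#' samples `[r - round(0.2 fs), r + round(0.8 fs))` relative to the peak
#' sample, i.e. a 1000 ms epoch spanning -200..+800 ms with the R-peak
#' at time 0. Trials running beyond the recording bounds or into
#' artifact-flagged spans are dropped and counted. Epochs may extend
#' past their 4-s segment into adjacent continuous data.
#'
#' @param recording a `psg_recording` (typically band-passed/cleaned).
#' @param rpeaks an `rpeak_series` sharing the recording's sampling
#'   rate.
#' @param segments a `segment_set`; only peaks inside these segments
#'   yield trials. Pass a single-state subset to build per-condition
#'   epochs.
#' @param window_ms epoch span in ms relative to the R-peak.
#' @param channels channel labels to extract; defaults to EEG channels.
#' @param artifact_spans optional data.frame (`onset_s`, `duration_s`)
#'   of spans that veto any overlapping trial.
#' @param condition condition label stored with the epochs; defaults to
#'   the single state present in `segments`.
#' @return object of class `epoch_set`: `data` (trials x channels x
#'   time), `times_ms`, `fs`, `labels`, `condition`, `peak_samples`,
#'   `n_dropped`, `baseline_corrected`.
#' @export
extract_epochs <- function(recording, rpeaks, segments,
                           window_ms = c(-200, 800), channels = NULL,
                           artifact_spans = NULL, condition = NULL) {
  stopifnot(inherits(recording, "psg_recording"),
            inherits(rpeaks, "rpeak_series"))
  if (!isTRUE(all.equal(recording$fs, rpeaks$fs))) {
    stop("recording and rpeaks must share the sampling rate")
  }
  fs <- recording$fs
  if (is.null(channels)) channels <- recording$labels[eeg_indices(recording)]
  ch_idx <- match(channels, recording$labels)
  if (anyNA(ch_idx)) stop("unknown channel(s): ",
                          paste(channels[is.na(ch_idx)], collapse = ", "))
  seg <- as.data.frame(segments)
  if (is.null(condition)) {
    st <- unique(seg$state)
    condition <- if (length(st) == 1) st else "mixed"
  }
  t_peak <- rpeaks$peak_samples / fs
  in_seg <- vapply(t_peak, function(tt) {
    any(tt >= seg$onset_s & tt < seg$onset_s + seg$duration_s)
  }, logical(1))
  peaks <- rpeaks$peak_samples[in_seg]
  pre_n <- round(-window_ms[1] / 1000 * fs)
  total_n <- round((window_ms[2] - window_ms[1]) / 1000 * fs)
  n <- ncol(recording$signals)
  start <- peaks - pre_n            # 0-based start sample
  ok <- start >= 0 & start + total_n <= n
  if (!is.null(artifact_spans) && nrow(artifact_spans) > 0) {
    t0 <- start / fs
    t1 <- (start + total_n) / fs
    hit <- vapply(seq_along(start), function(i) {
      any(t0[i] < artifact_spans$onset_s + artifact_spans$duration_s &
            t1[i] > artifact_spans$onset_s)
    }, logical(1))
    ok <- ok & !hit
  }
  n_dropped <- sum(!ok)
  peaks <- peaks[ok]; start <- start[ok]
  times_ms <- (seq_len(total_n) - 1 - pre_n) / fs * 1000
  if (length(peaks) == 0) {
    warning("no eligible R-peaks; returning empty epoch set")
    return(structure(list(
      data = array(0, c(0, length(ch_idx), total_n)),
      times_ms = times_ms, fs = fs, labels = channels,
      condition = condition, peak_samples = numeric(0),
      n_dropped = n_dropped, baseline_corrected = FALSE),
      class = "epoch_set"))
  }
  data <- array(0, c(length(peaks), length(ch_idx), total_n))
  for (i in seq_along(peaks)) {
    cols <- (start[i] + 1):(start[i] + total_n)
    data[i, , ] <- recording$signals[ch_idx, cols]
  }
  structure(list(data = data, times_ms = times_ms, fs = fs,
                 labels = channels, condition = condition,
                 peak_samples = peaks, n_dropped = n_dropped,
                 baseline_corrected = FALSE),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("Epoch set (", x$condition, "): ", dim(x$data)[1], " trials x ",
      dim(x$data)[2], " channels x ", dim(x$data)[3], " samples, ",
      x$n_dropped, " dropped\n", sep = "")
  invisible(x)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over the
#' baseline window. The default -200..-50 ms window stops before the
#' rising edge of the R wave.
#'
#' @param epochs an `epoch_set` not yet baseline-corrected.
#' @param baseline_ms baseline window in ms.
#' @return the corrected `epoch_set` with `baseline_corrected = TRUE`.
#' @export
baseline_correct <- function(epochs, baseline_ms = c(-200, -50)) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (epochs$baseline_corrected) {
    stop("epochs are already baseline-corrected")
  }
  sel <- epochs$times_ms >= baseline_ms[1] & epochs$times_ms <= baseline_ms[2]
  if (!any(sel)) stop("baseline window contains no samples")
  if (dim(epochs$data)[1] > 0) {
    base <- rowMeans(epochs$data[, , sel, drop = FALSE], dims = 2)
    epochs$data <- epochs$data - as.vector(base)  # recycles over time
  }
  epochs$baseline_corrected <- TRUE
  epochs$baseline_ms <- baseline_ms
  epochs
}

#' Average epochs into a per-subject HEP
#'
#' Arithmetic mean and standard error across trials.
#'
#' @param epochs an `epoch_set`.
#' @param subject_id optional subject identifier stored with the
#'   average.
#' @return object of class `hep_average`: `mean` and `sem` (channels x
#'   time), `n_trials`, `times_ms`, `labels`, `condition`.
#' @export
average_hep <- function(epochs, subject_id = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  nt <- dim(epochs$data)[1]
  if (nt == 0) stop("cannot average an empty epoch set")
  m <- colMeans(epochs$data, dims = 1)
  s <- if (nt >= 2) {
    v <- (colMeans(epochs$data^2, dims = 1) - m^2) * nt / (nt - 1)
    sqrt(pmax(v, 0) / nt)
  } else matrix(NA_real_, dim(epochs$data)[2], dim(epochs$data)[3])
  dimnames(m) <- list(epochs$labels, NULL)
  structure(list(mean = m, sem = s, n_trials = nt,
                 times_ms = epochs$times_ms, labels = epochs$labels,
                 condition = epochs$condition, subject_id = subject_id),
            class = "hep_average")
}

#' @export
print.hep_average <- function(x, ...) {
  cat("HEP average (", x$condition,
      if (!is.null(x$subject_id)) paste0(", subject ", x$subject_id), "): ",
      x$n_trials, " trials, ", nrow(x$mean), " channels x ",
      ncol(x$mean), " samples\n", sep = "")
  invisible(x)
}

#' Screen subjects by per-condition trial counts
#'
#' Subjects whose trial count in any condition falls below `min_trials`
#' are excluded (strictly below: exactly `min_trials` is kept), with
#' the reason recorded.
#'
#' @param counts data.frame with a `subject_id` column and one numeric
#'   column per condition, or a named list of per-subject named count
#'   vectors.
#' @param min_trials minimum artifact-free trials per condition.
#' @return list with `included`, `excluded` (subject ids) and `reasons`.
#' @export
screen_subjects <- function(counts, min_trials = 200) {
  if (!is.data.frame(counts)) {
    counts <- do.call(rbind, lapply(names(counts), function(s) {
      data.frame(subject_id = s, t(unlist(counts[[s]])))
    }))
  }
  cond_cols <- setdiff(names(counts), "subject_id")
  bad <- apply(counts[, cond_cols, drop = FALSE] < min_trials, 1, any)
  reasons <- lapply(which(bad), function(i) {
    low <- cond_cols[counts[i, cond_cols] < min_trials]
    paste0(low, " = ", counts[i, low], " < ", min_trials, collapse = "; ")
  })
  list(included = counts$subject_id[!bad],
       excluded = counts$subject_id[bad],
       reasons = stats::setNames(reasons, counts$subject_id[bad]))
}

#' Export a HEP average as CSV
#'
#' Channel x time matrix with the time axis in ms as the header row.
#'
#' @param average a `hep_average`.
#' @param path CSV file path.
#' @export
write_hep_average <- function(average, path) {
  df <- as.data.frame(average$mean)
  names(df) <- sprintf("%.3f", average$times_ms)
  df <- cbind(channel = average$labels, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
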