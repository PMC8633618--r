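#' Segment set constructor
#'
#' A collection of fixed-length labeled windows (phasic / tonic / wake)
#' with the selection metadata (thresholds, counts, seed). All selected
#' segments are guaranteed to be at least `min_gap_s` apart
#' edge-to-edge; the constructor enforces this invariant.
#'
#' @param segments data.frame with columns `onset_s`, `duration_s`,
#'   `state`.
#' @param metadata list of selection metadata.
#' @param min_gap_s minimum edge-to-edge gap to assert (use 0 to skip).
#' @return object of class `segment_set`.
#' @export
segment_set <- function(segments, metadata = list(), min_gap_s = 0) {
  segments <- as.data.frame(segments)
  if (nrow(segments) > 0) {
    stopifnot(all(c("onset_s", "duration_s", "state") %in% names(segments)))
    bad <- !segments$state %in% c("phasic", "tonic", "wake")
    if (any(bad)) stop("unknown segment state: ",
                       paste(unique(segments$state[bad]), collapse = ", "))
    segments <- segments[order(segments$onset_s), ]
    rownames(segments) <- NULL
    if (min_gap_s > 0 && nrow(segments) > 1) {
      gaps <- segments$onset_s[-1] -
        (segments$onset_s + segments$duration_s)[-nrow(segments)]
      if (any(gaps < min_gap_s - 1e-9)) {
        stop("segment spacing violation: edge-to-edge gap below ",
             min_gap_s, " s")
      }
    }
  }
  structure(list(segments = segments, metadata = metadata),
            class = "segment_set")
}

#' @export
as.data.frame.segment_set <- function(x, ...) x$segments

#' @export
length.segment_set <- function(x) nrow(x$segments)

#' @export
print.segment_set <- function(x, ...) {
  tab <- table(x$segments$state)
  cat("Segment set: ", nrow(x$segments), " segments (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Subset a segment set by state
#' @param segset a `segment_set`.
#' @param state one of "phasic", "tonic", "wake".
#' @export
subset_segments <- function(segset, state) {
  segment_set(segset$segments[segset$segments$state == state, ],
              metadata = segset$metadata)
}

#' Detect rapid eye movements on an EOG channel
#'
#' The EOG is band-pass filtered 0.5-30 Hz, amplitudes are measured
#' relative to the channel median, and contiguous excursions beyond
#' half the amplitude threshold are merged across brief sub-threshold
#' gaps (so a biphasic deflection counts as one movement). A candidate
#' qualifies as an eye movement when its peak absolute amplitude reaches
#' `amp_thresh_uv` and its above-half-peak width is shorter than
#' `max_dur_ms`.
#'
#' @param eog numeric vector, single EOG channel (uV).
#' @param fs sampling rate in Hz (>= 60 so the 30 Hz band is feasible).
#' @param amp_thresh_uv minimum peak amplitude (uV), default 100.
#' @param max_dur_ms maximum above-half-peak width (ms), default 500.
#' @param merge_gap_ms sub-threshold gap across which opposite-polarity
#'   lobes of one deflection are merged.
#' @param prefiltered set `TRUE` if `eog` is already band-passed.
#' @return data.frame of events ordered by onset with columns `onset_s`,
#'   `duration_ms` (above-half-peak width), `peak_amplitude_uv`.
#' @export
detect_eye_movements <- function(eog, fs, amp_thresh_uv = 100,
                                 max_dur_ms = 500, merge_gap_ms = 150,
                                 prefiltered = FALSE) {
  if (fs < 60) stop("fs must be >= 60 Hz for the 0.5-30 Hz EOG band")
  empty <- data.frame(onset_s = numeric(0), duration_ms = numeric(0),
                      peak_amplitude_uv = numeric(0))
  if (all(eog == 0)) return(empty)
  x <- if (prefiltered) eog else bandpass_filter(eog, fs, 0.5, 30)
  dev <- abs(x - stats::median(x))
  above <- dev >= amp_thresh_uv / 2
  if (!any(above)) return(empty)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  on <- starts[runs$values]
  off <- ends[runs$values]
  # merge excursions separated by less than merge_gap_ms
  gap_n <- merge_gap_ms / 1000 * fs
  if (length(on) > 1) {
    keep_start <- c(TRUE, on[-1] - off[-length(off)] > gap_n)
    grp <- cumsum(keep_start)
    on <- tapply(on, grp, min)
    off <- tapply(off, grp, max)
  }
  events <- lapply(seq_along(on), function(k) {
    seg <- dev[on[k]:off[k]]
    peak <- max(seg)
    if (peak < amp_thresh_uv) return(NULL)
    half_idx <- which(seg >= peak / 2)
    width_ms <- (max(half_idx) - min(half_idx) + 1) / fs * 1000
    if (width_ms >= max_dur_ms) return(NULL)
    data.frame(onset_s = (on[k] - 1) / fs, duration_ms = width_ms,
               peak_amplitude_uv = peak)
  })
  events <- do.call(rbind, events)
  if (is.null(events)) empty else events[order(events$onset_s), ]
}

# epochs of a given stage as half-open time intervals
stage_intervals <- function(hyp, stage) {
  idx <- which(hyp$stages == stage)
  if (length(idx) == 0) {
    return(data.frame(onset_s = numeric(0), end_s = numeric(0)))
  }
  # merge consecutive epochs
  brk <- c(TRUE, diff(idx) > 1)
  grp <- cumsum(brk)
  data.frame(
    onset_s = (tapply(idx, grp, min) - 1) * hyp$epoch_length_s,
    end_s = tapply(idx, grp, max) * hyp$epoch_length_s)
}

# candidate 4-s window onsets tiling intervals on a fixed stride
tile_windows <- function(intervals, segment_s, stride_s) {
  unlist(lapply(seq_len(nrow(intervals)), function(i) {
    lo <- intervals$onset_s[i]
    hi <- intervals$end_s[i] - segment_s
    if (hi < lo) return(numeric(0))
    seq(lo, hi, by = stride_s)
  }))
}

# greedy spacing-constrained selection: candidates are taken in onset
# order (ties by earliest onset), accepted when >= min_gap_s
# edge-to-edge from everything already accepted (across all states);
# per-state caps are then honoured by seeded random subsampling, which
# preserves the spacing invariant
greedy_select <- function(onsets, states, segment_s, min_gap_s, caps,
                          seed = 1) {
  ord <- order(onsets)
  onsets <- onsets[ord]; states <- states[ord]
  acc_on <- numeric(0)
  acc_st <- character(0)
  last_end <- -Inf
  for (i in seq_along(onsets)) {
    o <- onsets[i]
    if (o - last_end >= min_gap_s - 1e-9) {
      acc_on <- c(acc_on, o)
      acc_st <- c(acc_st, states[i])
      last_end <- o + segment_s
    }
  }
  keep <- rep(TRUE, length(acc_on))
  set.seed(seed)
  for (st in unique(acc_st)) {
    cap <- caps[[st]]
    idx <- which(acc_st == st)
    if (!is.null(cap) && is.finite(cap) && length(idx) > cap) {
      keep[setdiff(idx, sort(sample(idx, cap)))] <- FALSE
    }
  }
  data.frame(onset_s = acc_on[keep], state = acc_st[keep])
}

# EEG artifact veto: windows whose EEG RMS exceeds veto_factor x the
# recording median RMS (computed over same-length windows) are dropped
artifact_veto <- function(onsets, eeg_rms_fun, veto_factor = 5) {
  if (length(onsets) == 0 || is.null(eeg_rms_fun)) {
    return(rep(TRUE, length(onsets)))
  }
  r <- vapply(onsets, eeg_rms_fun, numeric(1))
  r <= veto_factor * stats::median(r)
}

#' Classify 4-s REM windows as phasic or tonic
#'
#' Sliding 4-s candidate windows (1-s stride) inside REM-scored epochs
#' are labeled phasic when they contain at least two consecutive eye
#' movements (onsets within `consec_gap_s` of each other, each movement
#' >= 100 uV and < 500 ms), and tonic when the maximum band-passed EOG
#' deflection from the window median stays below `tonic_max_uv`.
#' Windows meeting neither criterion stay unlabeled. Selected segments
#' are at least `min_gap_s` apart edge-to-edge (greedy selection over a
#' seeded random candidate order, honouring per-state caps), and a
#' window whose EEG RMS exceeds 5x the recording median is vetoed in
#' place of human artifact review.
#'
#' @param eog single EOG channel (uV).
#' @param fs sampling rate in Hz.
#' @param hyp a `hypnogram` aligned to the recording.
#' @param amp_thresh_uv eye-movement amplitude threshold (uV).
#' @param tonic_max_uv maximum EOG deflection for a tonic window (uV).
#' @param consec_gap_s maximum onset-to-onset gap between "consecutive"
#'   eye movements (REM EM bursts stay below 2 Hz, hence 1 s).
#' @param segment_s,stride_s window length and tiling stride (s).
#' @param min_gap_s minimum edge-to-edge gap between selected segments.
#' @param max_per_state per-state selection cap (e.g. 100), or `NULL`
#'   for no cap.
#' @param eeg optional EEG matrix (channels x samples) for the artifact
#'   veto.
#' @param seed RNG seed for cap sampling / candidate order.
#' @return a `segment_set` with states "phasic" and "tonic".
#' @export
classify_rem_segments <- function(eog, fs, hyp,
                                  amp_thresh_uv = 100, tonic_max_uv = 25,
                                  consec_gap_s = 1,
                                  segment_s = 4, stride_s = 1,
                                  min_gap_s = 8, max_per_state = NULL,
                                  eeg = NULL, seed = 1) {
  rem <- stage_intervals(hyp, "REM")
  meta <- list(amp_thresh_uv = amp_thresh_uv, tonic_max_uv = tonic_max_uv,
               consec_gap_s = consec_gap_s, min_gap_s = min_gap_s,
               max_per_state = max_per_state, seed = seed)
  if (nrow(rem) == 0) {
    warning("no REM epochs in hypnogram; returning empty segment set")
    return(segment_set(data.frame(onset_s = numeric(0),
                                  duration_s = numeric(0),
                                  state = character(0)), metadata = meta))
  }
  x <- bandpass_filter(eog, fs, 0.5, 30)
  ev <- detect_eye_movements(x, fs, amp_thresh_uv, prefiltered = TRUE)
  onsets <- tile_windows(rem, segment_s, stride_s)
  n_samp <- length(x)
  label_window <- function(o) {
    i0 <- floor(o * fs) + 1
    i1 <- min(n_samp, i0 + round(segment_s * fs) - 1)
    in_win <- ev$onset_s >= o & ev$onset_s < o + segment_s
    if (sum(in_win) >= 2) {
      gaps <- diff(ev$onset_s[in_win])
      if (any(gaps <= consec_gap_s)) return("phasic")
    }
    w <- x[i0:i1]
    if (max(abs(w - stats::median(w))) < tonic_max_uv) return("tonic")
    NA_character_
  }
  states <- vapply(onsets, label_window, character(1))
  keep <- !is.na(states)
  onsets <- onsets[keep]; states <- states[keep]
  # artifact veto on EEG RMS
  if (!is.null(eeg) && length(onsets) > 0) {
    rms_fun <- function(o) {
      i0 <- floor(o * fs) + 1
      i1 <- min(ncol(eeg), i0 + round(segment_s * fs) - 1)
      sqrt(mean(eeg[, i0:i1]^2))
    }
    ok <- artifact_veto(onsets, rms_fun)
    onsets <- onsets[ok]; states <- states[ok]
  }
  if (length(onsets) == 0) {
    return(segment_set(data.frame(onset_s = numeric(0),
                                  duration_s = numeric(0),
                                  state = character(0)), metadata = meta))
  }
  caps <- list(phasic = max_per_state %||% Inf,
               tonic = max_per_state %||% Inf, wake = Inf)
  sel <- greedy_select(onsets, states, segment_s, min_gap_s, caps,
                       seed = seed)
  meta$counts <- table(sel$state)
  segment_set(data.frame(onset_s = sel$onset_s, duration_s = segment_s,
                         state = sel$state),
              metadata = meta, min_gap_s = min_gap_s)
}

#' Select eyes-closed wake segments
#'
#' 4-s windows inside wake-scored epochs, preferring the wake period
#' before sleep onset and falling back to later wake epochs when the
#' pre-onset pool is too small. Windows containing eye movements above
#' the amplitude threshold are excluded (eyes-closed rest), and the
#' artifact veto, spacing rule and cap work exactly as for REM
#' segments.
#'
#' @inheritParams classify_rem_segments
#' @param min_pre_onset minimum number of pre-onset candidates before
#'   post-onset wake is drawn in.
#' @return a `segment_set` with state "wake".
#' @export
select_wake_segments <- function(eog, fs, hyp,
                                 amp_thresh_uv = 100,
                                 segment_s = 4, stride_s = 1,
                                 min_gap_s = 8, max_per_state = NULL,
                                 min_pre_onset = 10, eeg = NULL, seed = 1) {
  wk <- stage_intervals(hyp, "W")
  meta <- list(amp_thresh_uv = amp_thresh_uv, min_gap_s = min_gap_s,
               max_per_state = max_per_state, seed = seed)
  if (nrow(wk) == 0) {
    warning("no wake epochs in hypnogram; returning empty segment set")
    return(segment_set(data.frame(onset_s = numeric(0),
                                  duration_s = numeric(0),
                                  state = character(0)), metadata = meta))
  }
  first_sleep <- which(hyp$stages != "W")
  onset_time <- if (length(first_sleep)) {
    (min(first_sleep) - 1) * hyp$epoch_length_s
  } else Inf
  x <- bandpass_filter(eog, fs, 0.5, 30)
  ev <- detect_eye_movements(x, fs, amp_thresh_uv, prefiltered = TRUE)
  onsets <- tile_windows(wk, segment_s, stride_s)
  em_free <- vapply(onsets, function(o) {
    !any(ev$onset_s >= o & ev$onset_s < o + segment_s)
  }, logical(1))
  onsets <- onsets[em_free]
  pre <- onsets[onsets + segment_s <= onset_time]
  post <- onsets[onsets + segment_s > onset_time]
  onsets <- if (length(pre) >= min_pre_onset) pre else c(pre, post)
  if (!is.null(eeg) && length(onsets) > 0) {
    rms_fun <- function(o) {
      i0 <- floor(o * fs) + 1
      i1 <- min(ncol(eeg), i0 + round(segment_s * fs) - 1)
      sqrt(mean(eeg[, i0:i1]^2))
    }
    onsets <- onsets[artifact_veto(onsets, rms_fun)]
  }
  if (length(onsets) == 0) {
    return(segment_set(data.frame(onset_s = numeric(0),
                                  duration_s = numeric(0),
                                  state = character(0)), metadata = meta))
  }
  sel <- greedy_select(onsets, rep("wake", length(onsets)), segment_s,
                       min_gap_s, list(wake = max_per_state %||% Inf),
                       seed = seed)
  meta$counts <- table(sel$state)
  segment_set(data.frame(onset_s = sel$onset_s, duration_s = segment_s,
                         state = "wake"),
              metadata = meta, min_gap_s = min_gap_s)
}

#' Score segment labels against ground-truth state spans
#'
#' Compares selected segment labels with the generator's true state
#' spans. Only segments lying entirely inside a single labeled span are
#' scored (windows straddling a state boundary have no defined truth).
#' Returns the phasic-class F1 together with the confusion counts.
#'
#' @param segset a `segment_set` (phasic/tonic labels).
#' @param truth a `psg_ground_truth` or a data.frame of state spans.
#' @return list with `f1`, `precision`, `recall`, `n_scored`,
#'   `confusion`.
#' @export
segment_f1 <- function(segset, truth) {
  spans <- if (inherits(truth, "psg_ground_truth")) {
    truth$true_state_spans
  } else as.data.frame(truth)
  seg <- as.data.frame(segset)
  seg <- seg[seg$state %in% c("phasic", "tonic"), ]
  true_label <- vapply(seq_len(nrow(seg)), function(i) {
    o <- seg$onset_s[i]; e <- o + seg$duration_s[i]
    hit <- which(spans$onset_s <= o + 1e-9 &
                   spans$onset_s + spans$duration_s >= e - 1e-9 &
                   spans$state %in% c("phasic", "tonic"))
    if (length(hit) == 1) spans$state[hit] else NA_character_
  }, character(1))
  scored <- !is.na(true_label)
  pred <- seg$state[scored]
  tru <- true_label[scored]
  tp <- sum(pred == "phasic" & tru == "phasic")
  fp <- sum(pred == "phasic" & tru == "tonic")
  fn <- sum(pred == "tonic" & tru == "phasic")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(f1 = f1, precision = precision, recall = recall,
       n_scored = sum(scored),
       confusion = table(predicted = pred, truth = tru))
}
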