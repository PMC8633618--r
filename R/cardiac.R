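#' R-peak series constructor
#'
#' Holds ordered R-peak sample indices together with the sampling rate;
#' inter-beat intervals (IBIs, ms) are derived on demand. Indices are
#' 0-based so that index / fs is the peak time in seconds.
#'
#' @param peak_samples strictly increasing 0-based sample indices.
#' @param fs sampling rate in Hz.
#' @return object of class `rpeak_series`.
#' @export
rpeak_series <- function(peak_samples, fs) {
  if (fs <= 0) stop("fs must be positive")
  peak_samples <- as.numeric(peak_samples)
  if (is.unsorted(peak_samples, strictly = TRUE)) {
    stop("peak_samples must be strictly increasing")
  }
  structure(list(peak_samples = peak_samples, fs = fs),
            class = "rpeak_series")
}

#' Inter-beat intervals of an R-peak series
#' @param rpeaks an `rpeak_series`.
#' @return numeric vector of successive IBIs in milliseconds.
#' @export
ibis_ms <- function(rpeaks) {
  diff(rpeaks$peak_samples) / rpeaks$fs * 1000
}

#' @export
print.rpeak_series <- function(x, ...) {
  n <- length(x$peak_samples)
  cat("R-peak series:", n, "peaks at fs =", x$fs, "Hz\n")
  if (n >= 2) {
    ib <- ibis_ms(x)
    cat(sprintf("  mean IBI %.1f ms, SDNN %.1f ms\n",
                mean(ib), stats::sd(ib)))
  }
  invisible(x)
}

#' Detect R-peaks in a continuous ECG channel
#'
#' A Pan-Tompkins style detector: band-pass 5-30 Hz, differentiate,
#' square, moving-window integrate (150 ms), adaptive threshold with a
#' 250 ms physiologic refractory period. ECG polarity is auto-detected
#' and each detection is refined to the local extremum of the raw signal
#' within +/- 50 ms.
#'
#' @param ecg numeric vector, single ECG channel in microvolts.
#' @param fs sampling rate in Hz (>= 100).
#' @param threshold_frac fraction of the robust integrated-signal peak
#'   level used as detection threshold.
#' @return an `rpeak_series` (0-based indices). A flat signal yields an
#'   empty series with a warning.
#' @export
detect_r_peaks <- function(ecg, fs, threshold_frac = 0.35) {
  if (fs < 100) stop("fs must be >= 100 Hz for R-peak detection")
  if (stats::sd(ecg) < .Machine$double.eps * 100) {
    warning("flat ECG signal; returning empty R-peak series")
    return(rpeak_series(numeric(0), fs))
  }
  bp <- bandpass_filter(ecg, fs, low = 5, high = min(30, fs / 2 - 1))
  # polarity: dominant QRS deflection sign
  if (abs(min(bp)) > abs(max(bp))) bp <- -bp
  dd <- c(0, diff(bp))
  sq <- dd^2
  wl <- max(3L, round(0.150 * fs))
  integ <- stats::filter(sq, rep(1 / wl, wl), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)
  thr <- threshold_frac * stats::quantile(integ, 0.995, names = FALSE)
  refr <- round(0.250 * fs)
  above <- integ > thr
  # candidate = local max of the integrated signal within each run
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  cand <- integer(0)
  for (k in which(runs$values)) {
    seg <- starts[k]:ends[k]
    cand <- c(cand, seg[which.max(integ[seg])])
  }
  # enforce refractory period, keeping the stronger of two close peaks
  if (length(cand) > 1) {
    keep <- cand[1]
    for (c0 in cand[-1]) {
      if (c0 - keep[length(keep)] >= refr) {
        keep <- c(keep, c0)
      } else if (integ[c0] > integ[keep[length(keep)]]) {
        keep[length(keep)] <- c0
      }
    }
    cand <- keep
  }
  # refine to the raw-signal extremum within 50 ms; ECG polarity is
  # decided by a majority vote over the candidate windows (the R
  # deflection is the dominant extremum of its neighbourhood)
  half <- round(0.050 * fs)
  n <- length(ecg)
  ext <- vapply(cand, function(c0) {
    lo <- max(1, c0 - half); hi <- min(n, c0 + half)
    w <- ecg[lo:hi]
    c(max(w), -min(w))
  }, numeric(2))
  raw <- if (stats::median(ext[2, ]) > stats::median(ext[1, ])) -ecg else ecg
  refined <- vapply(cand, function(c0) {
    lo <- max(1, c0 - half); hi <- min(n, c0 + half)
    lo + which.max(raw[lo:hi]) - 1
  }, numeric(1))
  refined <- sort(unique(refined))
  # final refractory pass after refinement
  if (length(refined) > 1) {
    ok <- c(TRUE, diff(refined) >= refr)
    refined <- refined[ok]
  }
  rpeak_series(refined - 1, fs)
}

# restrict peaks to those lying inside the segments of a segment_set;
# returns in-scope IBIs (both endpoints inside selected segments)
inscope_ibis_ms <- function(rpeaks, segments = NULL) {
  t_s <- rpeaks$peak_samples / rpeaks$fs
  if (is.null(segments)) {
    inside <- rep(TRUE, length(t_s))
  } else {
    seg <- as.data.frame(segments)
    inside <- vapply(t_s, function(tt) {
      any(tt >= seg$onset_s & tt < seg$onset_s + seg$duration_s)
    }, logical(1))
  }
  d_ms <- diff(rpeaks$peak_samples) / rpeaks$fs * 1000
  d_ms[inside[-length(inside)] & inside[-1]]
}

#' Heart rate over selected segments
#'
#' Mean heart rate in beats per minute computed as 60000 / mean(IBI),
#' using only IBIs whose both endpoints fall inside the selected
#' segments.
#'
#' @param rpeaks an `rpeak_series`.
#' @param segments optional `segment_set` restricting the IBIs in scope.
#' @return heart rate in bpm.
#' @export
heart_rate_bpm <- function(rpeaks, segments = NULL) {
  ib <- inscope_ibis_ms(rpeaks, segments)
  if (length(ib) < 1) stop("heart rate undefined: fewer than 2 in-scope peaks")
  60000 / mean(ib)
}

#' SDNN heart-rate variability over selected segments
#'
#' Standard deviation of in-scope inter-beat intervals (sample SD, n-1
#' denominator). Because segment-restricted recordings offer variable
#' numbers of RR intervals, a normalized variant dividing by sqrt(n_rr)
#' is provided as well; the mode used is always recorded in the output.
#'
#' @param rpeaks an `rpeak_series`.
#' @param segments optional `segment_set` restricting the IBIs in scope.
#' @param normalized if `TRUE`, divide the SDNN by sqrt(number of RR
#'   intervals).
#' @return object of class `cardiac_summary` with fields `hr_bpm`,
#'   `sdnn_ms`, `n_rr`, `normalization`.
#' @export
sdnn_ms <- function(rpeaks, segments = NULL, normalized = FALSE) {
  ib <- inscope_ibis_ms(rpeaks, segments)
  if (length(ib) < 2) stop("SDNN undefined: fewer than 2 in-scope IBIs")
  s <- stats::sd(ib)
  if (normalized) s <- s / sqrt(length(ib))
  structure(
    list(hr_bpm = 60000 / mean(ib),
         sdnn_ms = s,
         n_rr = length(ib),
         normalization = if (normalized) "sdnn/sqrt(n_rr)" else "raw"),
    class = "cardiac_summary"
  )
}

#' @export
print.cardiac_summary <- function(x, ...) {
  cat(sprintf("HR %.2f bpm, SDNN %.2f ms (%s, n_rr = %d)\n",
              x$hr_bpm, x$sdnn_ms, x$normalization, x$n_rr))
  invisible(x)
}

#' Export / import R-peaks for manual review
#'
#' Writes the peaks as CSV with columns `sample_index` (0-based) and
#' `time_s` so they can be reviewed and edited externally, and reads
#' such a file back into an `rpeak_series`.
#'
#' @param rpeaks an `rpeak_series`.
#' @param path CSV file path.
#' @export
write_rpeaks <- function(rpeaks, path) {
  utils::write.csv(
    data.frame(sample_index = rpeaks$peak_samples,
               time_s = rpeaks$peak_samples / rpeaks$fs),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rpeaks
#' @param fs sampling rate in Hz of the recording the peaks refer to.
#' @export
read_rpeaks <- function(path, fs) {
  df <- utils::read.csv(path)
  rpeak_series(df$sample_index, fs)
}
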