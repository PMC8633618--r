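#' Generate surrogate R-peaks within clean segments
#'
#' For each segment the original in-segment inter-beat-interval
#' multiset is permuted and re-anchored at a uniformly random offset
#' inside the segment, so every surrogate preserves the per-segment
#' peak count, the mean rate and the IBI distribution exactly while
#' decoupling peak times from the true heartbeats. An alternative mode
#' resamples the IBIs with replacement instead of permuting them.
#'
#' @param rpeaks original `rpeak_series`.
#' @param segments a `segment_set` (run per condition or on a
#'   single-state subset; each segment is handled independently).
#' @param seed RNG seed.
#' @param method "permute" (default) or "resample".
#' @return an `rpeak_series` of surrogate peaks, all inside the
#'   segments.
#' @export
generate_surrogate_rpeaks <- function(rpeaks, segments, seed = NULL,
                                      method = c("permute", "resample")) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  fs <- rpeaks$fs
  t_peak <- rpeaks$peak_samples / fs
  seg <- as.data.frame(segments)
  out <- numeric(0)
  for (i in seq_len(nrow(seg))) {
    o <- seg$onset_s[i]; dur <- seg$duration_s[i]
    inside <- t_peak[t_peak >= o & t_peak < o + dur]
    k <- length(inside)
    if (k == 0) next
    if (k == 1) {
      out <- c(out, stats::runif(1, o, o + dur))
    } else {
      ib <- diff(inside)
      ib <- if (method == "permute") sample(ib) else
        sample(ib, replace = TRUE)
      span <- sum(ib)
      if (span >= dur) span <- dur - 1e-6
      u <- stats::runif(1, o, o + dur - span)
      out <- c(out, u + cumsum(c(0, ib)))
    }
  }
  rpeak_series(sort(round(out * fs)), fs)
}

# per-subject, per-condition HEP average around a given peak series
condition_average <- function(recording, rpeaks, segments, state,
                              epoch_ms, baseline_ms, channels = NULL) {
  segs <- subset_segments(segments, state)
  ep <- extract_epochs(recording, rpeaks, segs, window_ms = epoch_ms,
                       channels = channels, condition = state)
  if (dim(ep$data)[1] == 0) return(NULL)
  average_hep(baseline_correct(ep, baseline_ms))
}

# fast per-condition average used inside the surrogate loop: averaging
# and per-trial baseline subtraction are linear, so summing epochs into
# an accumulator and baseline-correcting the mean once is identical to
# averaging individually corrected trials
fast_condition_mean <- function(recording, rpeaks, segments, state,
                                epoch_ms, baseline_ms, ch_idx, times_ms) {
  fs <- recording$fs
  seg <- segments$segments[segments$segments$state == state, ]
  t_peak <- rpeaks$peak_samples / fs
  in_seg <- vapply(t_peak, function(tt) {
    any(tt >= seg$onset_s & tt < seg$onset_s + seg$duration_s)
  }, logical(1))
  pre_n <- round(-epoch_ms[1] / 1000 * fs)
  total_n <- round((epoch_ms[2] - epoch_ms[1]) / 1000 * fs)
  start <- rpeaks$peak_samples[in_seg] - pre_n
  start <- start[start >= 0 & start + total_n <= ncol(recording$signals)]
  if (length(start) == 0) return(NULL)
  # gather all trials in one indexing operation, then average over the
  # trial dimension
  cols <- as.vector(outer(seq_len(total_n), start, "+"))
  M <- recording$signals[ch_idx, cols, drop = FALSE]
  dim(M) <- c(length(ch_idx), total_n, length(start))
  m <- rowMeans(M, dims = 2)
  sel <- times_ms >= baseline_ms[1] & times_ms <= baseline_ms[2]
  m - rowMeans(m[, sel, drop = FALSE])
}

# stack per-subject hep_average means into subjects x channels x time
stack_averages <- function(avgs) {
  nch <- nrow(avgs[[1]]$mean)
  nt <- ncol(avgs[[1]]$mean)
  arr <- array(0, c(length(avgs), nch, nt))
  for (s in seq_along(avgs)) arr[s, , ] <- avgs[[s]]$mean
  arr
}

#' Surrogate-heartbeat specificity test
#'
#' Tests whether a condition difference is locked to heartbeats: the
#' full epoch-average-contrast analysis is rebuilt `n_surrogates`
#' times around surrogate R-peaks (drawn per participant per
#' replicate), recording the maximum absolute cluster mass of each
#' rebuilt contrast. The heartbeat-locking criterion passes when the
#' original cluster mass exceeds the `floor(0.05 n)` largest
#' surrogate masses - with the default 100 surrogates, the five
#' largest - so the probability that the difference is not locked to
#' the heartbeats is at most 5%.
#'
#' @param subjects list with one entry per subject, each a list with
#'   elements `recording` (cleaned `psg_recording`), `rpeaks`
#'   (`rpeak_series`) and `segments` (`segment_set` containing both
#'   conditions).
#' @param adjacency a `hep_adjacency` for the EEG channels.
#' @param conditions two states to contrast (default phasic vs tonic).
#' @param epoch_ms,baseline_ms epoch span and baseline window (ms).
#' @param window_ms analysis window for clustering (ms).
#' @param n_surrogates number of surrogate replicates (100 for full
#'   fidelity; smaller values are for quick runs).
#' @param n_perm Monte-Carlo permutations for the original cluster
#'   test (the surrogate replicates only need the observed cluster
#'   masses, not permutation p values).
#' @param alpha,min_neighbors cluster-forming parameters.
#' @param seed RNG seed block; surrogate draws are seeded per subject
#'   per replicate from it.
#' @return object of class `surrogate_null`: original mass and test,
#'   per-surrogate max |cluster mass|, exceedance count, and the pass
#'   flag.
#' @export
surrogate_specificity_test <- function(subjects, adjacency,
                                       conditions = c("phasic", "tonic"),
                                       epoch_ms = c(-200, 800),
                                       baseline_ms = c(-200, -50),
                                       window_ms = c(350, 650),
                                       n_surrogates = 100,
                                       n_perm = 1000,
                                       alpha = 0.05, min_neighbors = 2,
                                       seed = 1) {
  n <- length(subjects)
  fs <- subjects[[1]]$recording$fs
  pre_n <- round(-epoch_ms[1] / 1000 * fs)
  total_n <- round((epoch_ms[2] - epoch_ms[1]) / 1000 * fs)
  times_ms <- (seq_len(total_n) - 1 - pre_n) / fs * 1000
  ch_idx <- lapply(subjects, function(sb) eeg_indices(sb$recording))
  nch <- length(ch_idx[[1]])
  get_arrays <- function(peaks_list) {
    A <- array(0, c(n, nch, total_n))
    B <- array(0, c(n, nch, total_n))
    for (s in seq_len(n)) {
      sb <- subjects[[s]]
      ma <- fast_condition_mean(sb$recording, peaks_list[[s]], sb$segments,
                                conditions[1], epoch_ms, baseline_ms,
                                ch_idx[[s]], times_ms)
      mb <- fast_condition_mean(sb$recording, peaks_list[[s]], sb$segments,
                                conditions[2], epoch_ms, baseline_ms,
                                ch_idx[[s]], times_ms)
      if (is.null(ma) || is.null(mb)) return(NULL)
      A[s, , ] <- ma
      B[s, , ] <- mb
    }
    list(A = A, B = B, times_ms = times_ms)
  }
  orig_peaks <- lapply(subjects, `[[`, "rpeaks")
  orig <- get_arrays(orig_peaks)
  if (is.null(orig)) stop("a subject has no epochs for the original analysis")
  original_test <- cluster_permutation_test(
    orig$A, orig$B, adjacency, times_ms = orig$times_ms,
    window_ms = window_ms, n_perm = n_perm, alpha = alpha,
    min_neighbors = min_neighbors, seed = seed)
  original_mass <- if (nrow(original_test$clusters)) {
    max(abs(original_test$clusters$mass))
  } else 0
  sel <- orig$times_ms >= window_ms[1] & orig$times_ms <= window_ms[2]

  max_mass_of <- function(arrs) {
    tmap <- paired_t_map(arrs$A[, , sel, drop = FALSE],
                         arrs$B[, , sel, drop = FALSE])
    fc <- form_clusters(tmap, adjacency, df = n - 1, alpha = alpha,
                        min_neighbors = min_neighbors)
    if (length(fc$clusters)) {
      max(abs(vapply(fc$clusters, `[[`, numeric(1), "mass")))
    } else 0
  }
  masses <- numeric(n_surrogates)
  for (r in seq_len(n_surrogates)) {
    draw <- function(redraw = 0) {
      lapply(seq_len(n), function(s) {
        generate_surrogate_rpeaks(
          subjects[[s]]$rpeaks, subjects[[s]]$segments,
          seed = seed + 7919L * r + 104729L * s + redraw)
      })
    }
    arrs <- get_arrays(draw())
    if (is.null(arrs)) arrs <- get_arrays(draw(redraw = 1L))
    if (is.null(arrs)) {
      stop("surrogate replicate ", r,
           " produced no epochs for a subject (after one redraw)")
    }
    masses[r] <- max_mass_of(arrs)
  }
  # k/n preserves the 5% bound of the top-5-of-100 rule: the
  # probability that an exchangeable original beats the k-th largest
  # of n surrogates is k/(n+1) <= 5%
  k_top <- max(1L, floor(0.05 * n_surrogates))
  sorted <- sort(masses, decreasing = TRUE)
  pass <- original_mass > sorted[k_top]
  structure(
    list(original_mass = original_mass, surrogate_masses = masses,
         n_surrogates = n_surrogates, exceedance = sum(masses >= original_mass),
         k_top = k_top, pass = pass, original_test = original_test,
         conditions = conditions, seed = seed),
    class = "surrogate_null")
}

#' @export
print.surrogate_null <- function(x, ...) {
  cat("Surrogate-heartbeat specificity test (", x$conditions[1], " vs ",
      x$conditions[2], ", ", x$n_surrogates, " surrogates)\n", sep = "")
  cat(sprintf("  original max |cluster mass| = %.2f\n", x$original_mass))
  cat(sprintf("  surrogate masses: median %.2f, top-%d threshold %.2f\n",
              stats::median(x$surrogate_masses), x$k_top,
              sort(x$surrogate_masses, decreasing = TRUE)[x$k_top]))
  cat("  heartbeat-locked:", if (x$pass) "PASS" else "FAIL",
      sprintf("(%d/%d surrogates >= original)\n", x$exceedance,
              x$n_surrogates))
  invisible(x)
}

#' Serialize a surrogate test result to JSON
#' @param x a `surrogate_null`.
#' @param path JSON file path.
#' @export
write_surrogate_result <- function(x, path) {
  jsonlite::write_json(
    list(original_mass = x$original_mass,
         surrogate_masses = x$surrogate_masses,
         n_surrogates = x$n_surrogates, exceedance = x$exceedance,
         k_top = x$k_top, pass = x$pass, conditions = x$conditions,
         seed = x$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
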