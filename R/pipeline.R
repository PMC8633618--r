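#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end study. Two study modes mirror
#' the two recording protocols the pipeline supports: `"study1"` caps
#' the selection at 100 segments per REM microstate (19 EEG channels,
#' 1024 Hz in the original protocol), `"study2"` requires a minimum
#' total duration per state instead (17 channels, no frontopolar row,
#' 512 Hz). `"custom"` applies the caps given explicitly. Exactly one
#' input source must be configured: a synthetic cohort (list of
#' `synth_config` argument lists, one per subject, or a count plus
#' shared arguments) or file paths to EDF recordings with hypnogram
#' CSVs.
#'
#' @param mode "study1", "study2" or "custom".
#' @param n_subjects synthetic-cohort size (ignored when paths are
#'   given).
#' @param synth_args shared arguments passed to [synth_config()] for
#'   every synthetic subject (per-subject seeds are derived from
#'   `seed`).
#' @param edf_paths,hypnogram_paths per-subject input files
#'   (alternative to the synthetic cohort).
#' @param window_ms analysis window for the cluster contrasts (ms post
#'   R-peak).
#' @param epoch_ms,baseline_ms epoch span and baseline window (ms).
#' @param n_perm Monte-Carlo permutations for cluster tests.
#' @param n_surrogates surrogate replicates for the specificity test.
#' @param min_trials minimum artifact-free trials per condition for a
#'   subject to enter the group analysis.
#' @param max_segments_per_state per-state selection cap (study1 mode
#'   sets 100).
#' @param min_state_s minimum summed duration per state (study2 mode
#'   sets 360 s).
#' @param ica_corr_thresh,ica_max_remove eye-movement ICA flagging
#'   parameters.
#' @param min_neighbors,alpha cluster-forming parameters.
#' @param seed master seed; every stage derives its seed from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("custom", "study1", "study2"),
                            n_subjects = 12,
                            synth_args = list(),
                            edf_paths = NULL, hypnogram_paths = NULL,
                            window_ms = c(350, 650),
                            epoch_ms = c(-200, 800),
                            baseline_ms = c(-200, -50),
                            n_perm = 5000,
                            n_surrogates = 100,
                            min_trials = 200,
                            max_segments_per_state = NULL,
                            min_state_s = NULL,
                            ica_corr_thresh = 0.4,
                            ica_max_remove = 4,
                            min_neighbors = 2,
                            alpha = 0.05,
                            seed = 1) {
  mode <- match.arg(mode)
  if (mode == "study1") max_segments_per_state <- max_segments_per_state %||% 100
  if (mode == "study2") min_state_s <- min_state_s %||% 360
  if (window_ms[2] <= window_ms[1]) {
    stop("invalid analysis window: end must exceed start")
  }
  if (window_ms[1] < epoch_ms[1] || window_ms[2] > epoch_ms[2]) {
    stop("analysis window must lie within the epoch span")
  }
  if (!is.null(edf_paths) && length(synth_args) > 0) {
    stop("configure exactly one input source (EDF paths or synthesis)")
  }
  if (!is.null(edf_paths) && (is.null(hypnogram_paths) ||
                              length(hypnogram_paths) != length(edf_paths))) {
    stop("each EDF path needs a matching hypnogram path")
  }
  structure(
    list(mode = mode, n_subjects = n_subjects, synth_args = synth_args,
         edf_paths = edf_paths, hypnogram_paths = hypnogram_paths,
         window_ms = window_ms, epoch_ms = epoch_ms,
         baseline_ms = baseline_ms, n_perm = n_perm,
         n_surrogates = n_surrogates, min_trials = min_trials,
         max_segments_per_state = max_segments_per_state,
         min_state_s = min_state_s,
         ica_corr_thresh = ica_corr_thresh,
         ica_max_remove = ica_max_remove,
         min_neighbors = min_neighbors, alpha = alpha,
         seed = as.integer(seed)),
    class = "pipeline_config")
}

stage <- function(name, subject, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed for subject ", subject, ": ",
         conditionMessage(e), call. = FALSE)
  })
}

# process one subject: input -> segments -> filtering -> ICA -> peaks
# -> per-condition EEG and ECG averages
process_subject <- function(i, config) {
  seed_i <- config$seed + 1000L * i
  if (!is.null(config$edf_paths)) {
    rec <- stage("read_edf", i, read_edf(config$edf_paths[i]))
    hyp <- stage("read_hypnogram", i, read_hypnogram(config$hypnogram_paths[i]))
  } else {
    sc <- do.call(synth_config, c(config$synth_args, list(seed = seed_i)))
    synth <- stage("synthesize", i, synthesize_recording(sc))
    rec <- synth$recording
    hyp <- synth$truth$hypnogram
  }
  fs <- rec$fs
  eeg_idx <- eeg_indices(rec)
  eog <- rec$signals[which(rec$channel_types == "EOG")[1], ]
  ecg <- rec$signals[which(rec$channel_types == "ECG")[1], ]

  segs_rem <- stage("segment_rem", i, classify_rem_segments(
    eog, fs, hyp, max_per_state = config$max_segments_per_state,
    eeg = rec$signals[eeg_idx, , drop = FALSE], seed = seed_i))
  segs_wake <- stage("segment_wake", i, suppressWarnings(select_wake_segments(
    eog, fs, hyp, max_per_state = config$max_segments_per_state,
    eeg = rec$signals[eeg_idx, , drop = FALSE], seed = seed_i)))
  segs <- segment_set(rbind(as.data.frame(segs_rem), as.data.frame(segs_wake)),
                      metadata = segs_rem$metadata)
  if (!is.null(config$min_state_s)) {
    tab <- tapply(segs$segments$duration_s, segs$segments$state, sum)
    for (st in c("phasic", "tonic")) {
      if (is.na(tab[st]) || tab[st] < config$min_state_s) {
        warning("subject ", i, ": summed ", st, " duration below ",
                config$min_state_s, " s")
      }
    }
  }

  filt <- rec
  filt$signals[eeg_idx, ] <- stage("bandpass", i, bandpass_filter(
    rec$signals[eeg_idx, , drop = FALSE], fs, 0.5, min(35, fs / 2 - 1)))
  cleaned <- stage("ica", i, remove_em_components(
    filt, segs, corr_thresh = config$ica_corr_thresh,
    max_remove = config$ica_max_remove, seed = seed_i))
  rpeaks <- stage("rpeaks", i, detect_r_peaks(ecg, fs))

  ecg_label <- rec$labels[which(rec$channel_types == "ECG")[1]]
  avgs <- list(); ecg_avgs <- list(); counts <- list()
  for (st in c("phasic", "tonic", "wake")) {
    if (!st %in% segs$segments$state) {
      counts[[st]] <- 0
      next
    }
    a <- stage(paste0("epochs_", st), i, suppressWarnings(condition_average(
      cleaned$recording, rpeaks, segs, st,
      config$epoch_ms, config$baseline_ms)))
    e <- stage(paste0("ecg_epochs_", st), i, suppressWarnings(
      condition_average(cleaned$recording, rpeaks, segs, st,
                        config$epoch_ms, config$baseline_ms,
                        channels = ecg_label)))
    counts[[st]] <- if (is.null(a)) 0 else a$n_trials
    avgs[[st]] <- a
    ecg_avgs[[st]] <- e
  }
  hr <- list(); sdnn <- list()
  for (st in c("phasic", "tonic")) {
    sub <- subset_segments(segs, st)
    hr[[st]] <- tryCatch(heart_rate_bpm(rpeaks, sub), error = function(e) NA)
    sdnn[[st]] <- tryCatch(sdnn_ms(rpeaks, sub)$sdnn_ms,
                           error = function(e) NA)
  }
  list(id = i, recording = cleaned$recording, rpeaks = rpeaks,
       segments = segs, averages = avgs, ecg_averages = ecg_avgs,
       counts = counts, hr = hr, sdnn = sdnn,
       ica = cleaned$decomposition,
       eeg_labels = rec$labels[eeg_idx])
}

#' Run the end-to-end HEP microstate study
#'
#' Executes the full analysis in the study's order: segment selection,
#' filtering and eye-movement ICA, R-peak detection, R-peak-locked
#' epoching with baseline correction, subject screening by trial
#' count, the phasic-vs-tonic / phasic-vs-wake / tonic-vs-wake
#' cluster-based permutation contrasts, the ECG-artifact confound
#' suite on the best phasic-vs-tonic cluster (windowed ECG amplitude
#' contrast, repeated-measures ANCOVA with the ECG contrast covariate,
#' contrast correlation, full-range pointwise ECG permutation test
#' with FDR), cardiac summaries (HR, SDNN), and the
#' surrogate-heartbeat specificity test.
#'
#' @param config a `pipeline_config`.
#' @return object of class `study_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  n_sub <- if (!is.null(config$edf_paths)) length(config$edf_paths) else
    config$n_subjects
  subjects <- lapply(seq_len(n_sub), process_subject, config = config)

  counts_df <- do.call(rbind, lapply(subjects, function(s) {
    data.frame(subject_id = s$id,
               phasic = s$counts$phasic %||% 0,
               tonic = s$counts$tonic %||% 0)
  }))
  screening <- screen_subjects(counts_df, min_trials = config$min_trials)
  keep <- counts_df$subject_id %in% screening$included
  if (sum(keep) < 3) {
    stop("fewer than 3 subjects survive the ", config$min_trials,
         "-trial screening")
  }
  included <- subjects[keep]
  adjacency <- build_adjacency(included[[1]]$eeg_labels)
  times_ms <- included[[1]]$averages$phasic$times_ms

  arr_of <- function(state) {
    stack_averages(lapply(included, function(s) s$averages[[state]]))
  }
  contrasts <- list()
  A_ph <- arr_of("phasic"); A_to <- arr_of("tonic")
  contrasts$phasic_vs_tonic <- cluster_permutation_test(
    A_ph, A_to, adjacency, times_ms = times_ms,
    window_ms = config$window_ms, n_perm = config$n_perm,
    alpha = config$alpha, min_neighbors = config$min_neighbors,
    seed = config$seed)
  wake_ok <- vapply(included, function(s) {
    !is.null(s$averages$wake) &&
      s$averages$wake$n_trials >= config$min_trials
  }, logical(1))
  if (sum(wake_ok) >= 3) {
    A_w <- stack_averages(lapply(included[wake_ok],
                                 function(s) s$averages$wake))
    sub_ph <- arr_of("phasic")[wake_ok, , , drop = FALSE]
    sub_to <- arr_of("tonic")[wake_ok, , , drop = FALSE]
    contrasts$phasic_vs_wake <- cluster_permutation_test(
      sub_ph, A_w, adjacency, times_ms = times_ms,
      window_ms = config$window_ms, n_perm = config$n_perm,
      alpha = config$alpha, min_neighbors = config$min_neighbors,
      seed = config$seed + 1L)
    contrasts$tonic_vs_wake <- cluster_permutation_test(
      sub_to, A_w, adjacency, times_ms = times_ms,
      window_ms = config$window_ms, n_perm = config$n_perm,
      alpha = config$alpha, min_neighbors = config$min_neighbors,
      seed = config$seed + 2L)
  }

  # ECG confound suite on the best phasic-vs-tonic cluster
  confounds <- NULL
  best <- contrasts$phasic_vs_tonic$clusters
  if (nrow(best) > 0 && best$p[1] < config$alpha) {
    cl_win <- c(best$start_ms[1], best$end_ms[1])
    cl_channels <- strsplit(best$channels[1], ",")[[1]]
    hep_ph <- vapply(included, function(s) {
      window_mean_amplitude(s$averages$phasic, cl_win, cl_channels)
    }, numeric(1))
    hep_to <- vapply(included, function(s) {
      window_mean_amplitude(s$averages$tonic, cl_win, cl_channels)
    }, numeric(1))
    ecg_ph <- vapply(included, function(s) {
      window_mean_amplitude(s$ecg_averages$phasic, cl_win)
    }, numeric(1))
    ecg_to <- vapply(included, function(s) {
      window_mean_amplitude(s$ecg_averages$tonic, cl_win)
    }, numeric(1))
    confounds <- list(
      cluster_window_ms = cl_win,
      ecg_amplitude_contrast = compare_conditions_scalar(ecg_ph, ecg_to),
      ancova = rm_ancova_condition(hep_ph, hep_to, ecg_ph - ecg_to),
      contrast_correlation = tryCatch(
        pearson_contrast_correlation(hep_ph - hep_to, ecg_ph - ecg_to),
        error = function(e) NULL))
  }
  # full-range pointwise ECG comparison
  ecg_mat <- function(state) {
    do.call(rbind, lapply(included, function(s) {
      as.numeric(s$ecg_averages[[state]]$mean)
    }))
  }
  pw <- pointwise_permutation_test(ecg_mat("phasic"), ecg_mat("tonic"),
                                   n_perm = config$n_perm,
                                   seed = config$seed + 3L)
  ecg_pointwise <- list(
    t = pw$t, p_uncorrected = pw$p,
    n_uncorrected_sig = sum(pw$p < 0.05),
    fdr_mask = bh_fdr(pw$p, q = 0.05),
    n_fdr_sig = sum(bh_fdr(pw$p, q = 0.05)))

  cardiac <- data.frame(
    subject_id = vapply(included, `[[`, numeric(1), "id"),
    hr_phasic = vapply(included, function(s) s$hr$phasic, numeric(1)),
    hr_tonic = vapply(included, function(s) s$hr$tonic, numeric(1)),
    sdnn_phasic = vapply(included, function(s) s$sdnn$phasic, numeric(1)),
    sdnn_tonic = vapply(included, function(s) s$sdnn$tonic, numeric(1)))

  surrogate <- surrogate_specificity_test(
    lapply(included, function(s) {
      list(recording = s$recording, rpeaks = s$rpeaks,
           segments = s$segments)
    }),
    adjacency, conditions = c("phasic", "tonic"),
    epoch_ms = config$epoch_ms, baseline_ms = config$baseline_ms,
    window_ms = config$window_ms, n_surrogates = config$n_surrogates,
    n_perm = config$n_perm, alpha = config$alpha,
    min_neighbors = config$min_neighbors, seed = config$seed + 4L)

  log <- list(
    n_subjects_in = n_sub,
    n_subjects_included = sum(keep),
    excluded = screening$excluded,
    exclusion_reasons = screening$reasons,
    trial_counts = counts_df,
    segments_per_subject = lapply(subjects, function(s) {
      table(s$segments$segments$state)
    }),
    ica_removed = vapply(subjects, function(s) length(s$ica$removed),
                         numeric(1)))
  structure(
    list(contrasts = contrasts, confounds = confounds,
         ecg_pointwise = ecg_pointwise, cardiac = cardiac,
         surrogate = surrogate, screening = screening, log = log,
         config = config),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("==== HEP microstate study report ====\n")
  cat("Subjects:", x$log$n_subjects_included, "included of",
      x$log$n_subjects_in, "\n\n")
  for (nm in names(x$contrasts)) {
    cat("--", gsub("_", " ", nm), "--\n")
    print(x$contrasts[[nm]])
  }
  if (!is.null(x$confounds)) {
    cat("\n-- ECG confound controls (cluster ",
        x$confounds$cluster_window_ms[1], "-",
        x$confounds$cluster_window_ms[2], " ms) --\n", sep = "")
    cat("ECG amplitude contrast: ")
    print(x$confounds$ecg_amplitude_contrast)
    print(x$confounds$ancova)
    if (!is.null(x$confounds$contrast_correlation)) {
      cc <- x$confounds$contrast_correlation
      cat(sprintf("HEP-vs-ECG contrast correlation: r = %.3f, p = %.3g\n",
                  cc$r, cc$p))
    }
  }
  cat("\n-- full-range pointwise ECG test --\n")
  cat(x$ecg_pointwise$n_uncorrected_sig, "of",
      length(x$ecg_pointwise$p_uncorrected),
      "time points p < 0.05 uncorrected;",
      x$ecg_pointwise$n_fdr_sig, "survive FDR\n")
  cat(sprintf("\n-- cardiac activity --\nHR phasic %.1f +/- %.1f, tonic %.1f +/- %.1f bpm\n",
              mean(x$cardiac$hr_phasic), stats::sd(x$cardiac$hr_phasic),
              mean(x$cardiac$hr_tonic), stats::sd(x$cardiac$hr_tonic)))
  cat(sprintf("SDNN phasic %.1f +/- %.1f, tonic %.1f +/- %.1f ms\n",
              mean(x$cardiac$sdnn_phasic), stats::sd(x$cardiac$sdnn_phasic),
              mean(x$cardiac$sdnn_tonic), stats::sd(x$cardiac$sdnn_tonic)))
  cat("\n")
  print(x$surrogate)
  invisible(x)
}

#' Serialize a study report to JSON
#'
#' Writes every number of the report in machine-readable form; all
#' values are traceable to module outputs, nothing is recomputed.
#'
#' @param report a `study_report`.
#' @param path JSON file path.
#' @export
write_study_report <- function(report, path) {
  jsonlite::write_json(
    list(
      contrasts = lapply(report$contrasts, function(ct) ct$clusters),
      confounds = if (!is.null(report$confounds)) list(
        cluster_window_ms = report$confounds$cluster_window_ms,
        ecg_contrast = unclass(report$confounds$ecg_amplitude_contrast),
        ancova = unclass(report$confounds$ancova),
        correlation = report$confounds$contrast_correlation),
      ecg_pointwise = list(
        n_uncorrected_sig = report$ecg_pointwise$n_uncorrected_sig,
        n_fdr_sig = report$ecg_pointwise$n_fdr_sig),
      cardiac = report$cardiac,
      surrogate = list(original_mass = report$surrogate$original_mass,
                       exceedance = report$surrogate$exceedance,
                       pass = report$surrogate$pass),
      screening = list(included = report$screening$included,
                       excluded = report$screening$excluded),
      seed = report$config$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
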