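# shared fixtures built in code

# quiet defaults for fast structural tests
quiet_config <- function(duration_s = 180, fs = 128, seed = 1, ...) {
  synth_config(duration_s = duration_s, fs = fs, wake_s = 0, seed = seed, ...)
}

# a biphasic EOG deflection: one full sine cycle
biphasic <- function(amplitude_uv, duration_ms, fs) {
  n <- round(duration_ms / 1000 * fs)
  amplitude_uv * sin(2 * pi * seq(0, 1, length.out = n))
}

# cohort of continuous recordings for surrogate runs, using the
# generator's ground-truth segments and R-peaks (segmentation and
# detection have their own tests); `effect` toggles the
# heartbeat-locked component while the tonic > phasic background band
# power difference stays at its defaults. The default sizes give
# ~300 trials per condition per subject, the study's trial scale.
make_surrogate_cohort <- function(seed, effect = TRUE, n_subjects = 12,
                                  duration_s = 2000, fs = 100) {
  hs <- if (effect) NULL else {
    list(phasic = list(amplitude_uv = 0),
         tonic = list(amplitude_uv = 0))
  }
  lapply(seq_len(n_subjects), function(i) {
    sy <- synthesize_recording(synth_config(
      duration_s = duration_s, fs = fs, wake_s = 0,
      phasic_span_s = 40, tonic_span_s = 40,
      hep_spec = hs, seed = seed + i))
    spans <- sy$truth$true_state_spans
    spans <- spans[spans$state %in% c("phasic", "tonic"), ]
    segs <- do.call(rbind, lapply(seq_len(nrow(spans)), function(k) {
      data.frame(onset_s = spans$onset_s[k] + c(0, 12, 24, 36),
                 duration_s = 4, state = spans$state[k])
    }))
    rec <- sy$recording
    eeg <- which(rec$channel_types == "EEG")
    rec$signals[eeg, ] <- bandpass_filter(rec$signals[eeg, , drop = FALSE],
                                          fs, 0.5, 35, method = "fft")
    list(recording = rec,
         rpeaks = rpeak_series(sy$truth$true_rpeaks, fs),
         segments = segment_set(segs, min_gap_s = 8))
  })
}

adjacency19 <- function() build_adjacency(ten_twenty_positions()$label)
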