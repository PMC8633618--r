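test_that("RR series: zero-variance, determinism, and moment control", {
  # zero variance: exact 1 s spacing
  rr <- generate_rr_series(1000, 0, 10, fs = 1000)
  expect_true(all(diff(rr$peak_samples) == 1000))
  expect_true(length(rr$peak_samples) %in% 9:10)

  # determinism
  a <- generate_rr_series(1000, 55, 60, fs = 512, seed = 42)
  b <- generate_rr_series(1000, 55, 60, fs = 512, seed = 42)
  expect_identical(a$peak_samples, b$peak_samples)

  # law of large numbers against direct moment computation
  rr <- generate_rr_series(1000, 55, 3600, fs = 512, seed = 7)
  ib <- diff(rr$peak_samples) / 512 * 1000
  expect_lt(abs(mean(ib) - 1000) / 1000, 0.01)
  expect_lt(abs(sd(ib) - 55) / 55, 0.05)

  # truncation respected
  expect_true(all(ib >= 250 & ib <= 2000))

  expect_error(generate_rr_series(1000, 55, -5, fs = 512), "positive")
  expect_error(generate_rr_series(200, 10, 10, fs = 512), "250")
})

test_that("ECG synthesis: beat morphology and T-wave ablation", {
  # single beat at t = 1 s, fs = 1000: argmax at sample index 1000
  rr <- rpeak_series(1000, 1000)
  ecg <- synthesize_ecg(rr, 1000)
  expect_equal(which.max(ecg) - 1, 1000)

  # T-wave ablation empties the 250-450 ms post-R window
  ecg0 <- synthesize_ecg(rr, 1000, t_amp_uv = 0)
  win <- 1000 + (250:450) + 1
  expect_lt(max(abs(ecg0[win])), 1e-6)
  # with the T-wave present the same window carries substantial energy
  expect_gt(max(abs(synthesize_ecg(rr, 1000)[win])), 100)

  # too-short IBI for the template errors
  expect_error(synthesize_ecg(rpeak_series(c(0, 100), 1000), 1000), "QRS")
})

test_that("ECG synthesis round-trips through the R-peak detector", {
  rr <- generate_rr_series(1000, 55, 300, fs = 256, seed = 11)
  ecg <- synthesize_ecg(rr, 256, noise_rms_uv = 5, seed = 12)
  det <- detect_r_peaks(ecg, 256)
  expect_equal(length(det$peak_samples), length(rr$peak_samples))
  err_ms <- abs(det$peak_samples - rr$peak_samples) / 256 * 1000
  expect_lte(max(err_ms), 10)
})

test_that("synthetic recording is deterministic and internally consistent", {
  s1 <- synthesize_recording(quiet_config(seed = 3))
  s2 <- synthesize_recording(quiet_config(seed = 3))
  expect_identical(s1$recording$signals, s2$recording$signals)
  expect_identical(s1$truth, s2$truth)

  # ground-truth R-peaks are the per-beat maxima of the ECG channel
  ecg <- s1$recording$signals["ECG", ]
  ok <- vapply(s1$truth$true_rpeaks[2:60], function(p) {
    w <- ecg[(p - 10):(p + 12)]  # 1-based window around 0-based peak p
    which.max(w) == 12           # position of 1-based index p + 1
  }, logical(1))
  expect_true(all(ok))

  # EM events lie only inside phasic spans
  spans <- s1$truth$true_state_spans
  ph <- spans[spans$state == "phasic", ]
  ev <- s1$truth$true_em_events
  in_phasic <- vapply(seq_len(nrow(ev)), function(i) {
    any(ev$onset_s[i] >= ph$onset_s &
          ev$onset_s[i] + ev$duration_ms[i] / 1000 <=
            ph$onset_s + ph$duration_s)
  }, logical(1))
  expect_true(all(in_phasic))

  # configuration validation
  expect_error(synth_config(duration_s = -1), "positive")
  expect_error(synth_config(ecg_leak_fraction = 0.02), "0.01")
  expect_error(synth_config(mean_ibi_ms = 200), "refractory")
})

test_that("cardiac-field leakage stays below the configured fraction", {
  cfg <- quiet_config(
    seed = 5,
    noise_spec = list(eeg_rms_uv = 1e-9, eog_rms_uv = 1e-9, ecg_rms_uv = 0),
    em_spec = list(amplitude_uv = 1e-9),
    hep_spec = list(phasic = list(amplitude_uv = 0),
                    tonic = list(amplitude_uv = 0)),
    band_power_spec = list(alpha_rms_uv = c(phasic = 0, tonic = 0),
                           beta_rms_uv = c(phasic = 0, tonic = 0)))
  sy <- synthesize_recording(cfg)
  ecg_max <- max(abs(sy$recording$signals["ECG", ]))
  for (ch in c(1, 10, 19)) {
    ratio <- max(abs(sy$recording$signals[ch, ])) / ecg_max
    expect_lte(ratio, 0.005 + 1e-9)
  }
})

test_that("tonic spans carry more 10-14 Hz and 15-28 Hz power than phasic", {
  sy <- synthesize_recording(quiet_config(duration_s = 600, seed = 9))
  spans <- sy$truth$true_state_spans
  fs <- sy$recording$fs
  band_power <- function(state, lo, hi) {
    sp <- spans[spans$state == state, ]
    mean(vapply(seq_len(nrow(sp)), function(i) {
      i0 <- floor(sp$onset_s[i] * fs) + 1
      s <- spec.pgram(sy$recording$signals["Cz", i0:(i0 + 4 * fs - 1)],
                      plot = FALSE, taper = 0.1)
      f <- s$freq * fs
      mean(s$spec[f >= lo & f <= hi])
    }, numeric(1)))
  }
  expect_gt(band_power("tonic", 10, 14) / band_power("phasic", 10, 14), 1)
  expect_gt(band_power("tonic", 15, 28) / band_power("phasic", 15, 28), 1)
})

test_that("cohort simulator injects the configured condition difference", {
  co <- simulate_hep_cohort(n_subjects = 30, fs = 256, effect_uv = 2,
                            seed = 6)
  co2 <- simulate_hep_cohort(n_subjects = 30, fs = 256, effect_uv = 2,
                             seed = 6)
  expect_identical(co$phasic, co2$phasic)
  d <- apply(co$phasic - co$tonic, c(2, 3), mean)
  peak_ch <- which(co$labels == "Fz")
  sel <- co$times_ms >= 590 & co$times_ms <= 610
  # with 30 subjects the mean difference approaches the injected bump
  expect_lt(abs(max(d[peak_ch, sel]) - 2), 0.5)
  # far from the bump the mean difference is near zero
  expect_lt(max(abs(d[, co$times_ms < 300])), 1)
})
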