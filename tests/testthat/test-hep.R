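make_flat_recording <- function(fs = 1000, dur = 10, nch = 3, value = 0) {
  continuous_recording(matrix(value, nch, fs * dur), fs,
                       c("Fz", "Cz", "ECG"))
}

test_that("epoch extraction implements the -200..+800 ms window exactly", {
  fs <- 1000
  sig <- matrix(seq_len(3 * 10 * fs), 3, byrow = TRUE)  # ramp per channel
  rec <- continuous_recording(sig, fs, c("Fz", "Cz", "ECG"))
  segs <- segment_set(data.frame(onset_s = 4, duration_s = 4,
                                 state = "phasic"))
  rp <- rpeak_series(5000, fs)
  ep <- extract_epochs(rec, rp, segs)
  expect_equal(dim(ep$data), c(1, 2, 1000))
  # samples 4800..5799 (0-based) from the continuous recording
  expect_equal(ep$data[1, 1, ], sig[1, 4801:5800])
  # R-peak maps to time 0
  expect_equal(ep$times_ms[which(ep$times_ms == 0)], 0)
  expect_equal(unname(ep$data[1, 1, ep$times_ms == 0]), sig[1, 5001])

  # peak too close to the recording start: dropped and counted
  rp2 <- rpeak_series(c(100, 5000), fs)
  segs2 <- segment_set(data.frame(onset_s = c(0, 4), duration_s = 4,
                                  state = "phasic"))
  ep2 <- extract_epochs(rec, rp2, segs2)
  expect_equal(dim(ep2$data)[1], 1)
  expect_equal(ep2$n_dropped, 1)

  # peaks only outside segments: empty set with warning
  expect_warning(
    ep3 <- extract_epochs(rec, rpeak_series(2000, fs), segs), "eligible")
  expect_equal(dim(ep3$data)[1], 0)

  # artifact-flagged span vetoes overlapping trials
  expect_warning(
    ep4 <- extract_epochs(rec, rp, segs,
                          artifact_spans = data.frame(onset_s = 5.5,
                                                      duration_s = 0.1)),
    "eligible")
  expect_equal(dim(ep4$data)[1], 0)
  expect_equal(ep4$n_dropped, 1)
})

test_that("baseline correction subtracts the -200..-50 ms mean per trial", {
  fs <- 1000
  rec <- make_flat_recording(value = 2)
  rec$signals[1, 5001:9999] <- 5  # step from 2 to 5 uV at t > 0
  segs <- segment_set(data.frame(onset_s = 4, duration_s = 4,
                                 state = "tonic"))
  ep <- extract_epochs(rec, rpeak_series(5000, fs), segs)
  bc <- baseline_correct(ep)
  expect_true(bc$baseline_corrected)
  # pre-stimulus value 2 - 2 = 0, post-stimulus 5 - 2 = 3
  expect_equal(unname(bc$data[1, 1, bc$times_ms == -100]), 0)
  expect_equal(unname(bc$data[1, 1, bc$times_ms == 400]), 3)
  expect_error(baseline_correct(bc), "already")

  # random epochs: corrected baseline means vanish
  set.seed(5)
  rec$signals[1:2, ] <- rnorm(2 * 10 * fs, 3, 10)
  ep <- extract_epochs(rec, rpeak_series(c(3000, 5000, 7000), fs),
                       segment_set(data.frame(onset_s = c(2, 4, 6),
                                              duration_s = 4,
                                              state = "tonic")))
  bc <- baseline_correct(ep)
  sel <- bc$times_ms >= -200 & bc$times_ms <= -50
  expect_lt(max(abs(rowMeans(bc$data[, , sel], dims = 2))), 1e-9)
})

test_that("averaging is linear and bookkeeping is exact", {
  fs <- 500
  set.seed(6)
  rec <- continuous_recording(matrix(rnorm(2 * 20 * fs), 2), fs,
                              c("Fz", "ECG"))
  segs <- segment_set(data.frame(onset_s = c(2, 6, 10, 14), duration_s = 4,
                                 state = "phasic"))
  peaks <- rpeak_series(c(1500, 3500, 5500, 7500), fs)
  ep <- extract_epochs(rec, peaks, segs, channels = "Fz")
  av <- average_hep(ep)
  expect_equal(av$n_trials, 4)

  # adding a constant to all trials shifts the average by that constant
  ep2 <- ep
  ep2$data <- ep$data + 3
  expect_equal(average_hep(ep2)$mean, av$mean + 3)

  # identical trials: mean equals the trial, SEM = 0
  ep3 <- ep
  for (i in 1:4) ep3$data[i, , ] <- ep$data[1, , ]
  av3 <- average_hep(ep3)
  expect_equal(av3$mean[1, ], ep$data[1, 1, ])
  expect_equal(max(av3$sem), 0)

  # kept + dropped = eligible peaks
  rp_all <- rpeak_series(c(100, 1500, 3500, 5500, 7500), fs)
  segs_all <- segment_set(data.frame(onset_s = c(0, 2, 6, 10, 14),
                                     duration_s = 4, state = "phasic"))
  ep4 <- extract_epochs(rec, rp_all, segs_all, channels = "Fz")
  expect_equal(dim(ep4$data)[1] + ep4$n_dropped, 5)
})

test_that("noise-free injected component is recovered by averaging", {
  cfg <- quiet_config(
    duration_s = 300, seed = 43, ibi_sd_ms = 0,
    noise_spec = list(eeg_rms_uv = 1e-9, eog_rms_uv = 1e-9, ecg_rms_uv = 0),
    em_spec = list(amplitude_uv = 1e-9),
    band_power_spec = list(alpha_rms_uv = c(phasic = 0, tonic = 0),
                           beta_rms_uv = c(phasic = 0, tonic = 0)),
    ecg_leak_fraction = 1e-9)
  sy <- synthesize_recording(cfg)
  rp <- rpeak_series(sy$truth$true_rpeaks, sy$recording$fs)
  spans <- sy$truth$true_state_spans
  ph <- spans[spans$state == "phasic", ]
  segs <- segment_set(data.frame(onset_s = ph$onset_s,
                                 duration_s = ph$duration_s,
                                 state = "phasic"))
  av <- average_hep(baseline_correct(extract_epochs(sy$recording, rp, segs)))
  sel <- av$times_ms >= 595 & av$times_ms <= 605
  # Fz carries the full 1.5 uV default amplitude
  expect_lt(abs(max(av$mean["Fz", sel]) - 1.5) / 1.5, 0.01)
})

test_that("subject screening excludes strictly below the trial minimum", {
  counts <- data.frame(subject_id = c("s1", "s2", "s3"),
                       phasic = c(199, 200, 500),
                       tonic = c(500, 200, 150))
  sc <- screen_subjects(counts, min_trials = 200)
  expect_setequal(sc$excluded, c("s1", "s3"))
  expect_identical(sc$included, "s2")
  expect_match(sc$reasons[["s1"]], "phasic = 199")
})
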