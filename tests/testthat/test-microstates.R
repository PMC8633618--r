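test_that("eye-movement detection applies amplitude and width criteria", {
  fs <- 128
  z <- numeric(10 * fs)
  expect_equal(nrow(detect_eye_movements(z, fs)), 0)

  # one biphasic deflection, 120 uV peak, 300 ms: exactly one event
  x <- z
  x[(2 * fs):(2 * fs + round(0.3 * fs) - 1)] <- biphasic(120, 300, fs)
  ev <- detect_eye_movements(x, fs, prefiltered = TRUE)
  expect_equal(nrow(ev), 1)
  expect_gte(ev$peak_amplitude_uv, 100)
  expect_lt(ev$duration_ms, 500)
  expect_lt(abs(ev$onset_s - 2), 0.1)

  # same amplitude but 800 ms wide: rejected by the duration criterion
  x <- z
  x[(2 * fs):(2 * fs + round(0.8 * fs) - 1)] <- biphasic(120, 800, fs)
  expect_equal(nrow(detect_eye_movements(x, fs, prefiltered = TRUE)), 0)

  # sub-threshold amplitude: rejected
  x <- z
  x[(2 * fs):(2 * fs + round(0.3 * fs) - 1)] <- biphasic(80, 300, fs)
  expect_equal(nrow(detect_eye_movements(x, fs, prefiltered = TRUE)), 0)

  # detection still works through the 0.5-30 Hz band-pass
  x <- z
  x[(2 * fs):(2 * fs + round(0.3 * fs) - 1)] <- biphasic(140, 300, fs)
  expect_equal(nrow(detect_eye_movements(x, fs)), 1)

  expect_error(detect_eye_movements(z, fs = 50), "60")
})

test_that("REM window classification follows the phasic/tonic criteria", {
  fs <- 128
  hyp <- hypnogram(rep("REM", 2))
  z <- numeric(60 * fs)

  # two 120 uV / 300 ms movements 0.8 s apart: the window is phasic
  x <- z
  for (t0 in c(1.2, 2.0)) {
    i <- round(t0 * fs):(round(t0 * fs) + round(0.3 * fs) - 1)
    x[i] <- biphasic(120, 300, fs)
  }
  segs <- classify_rem_segments(x, fs, hyp)
  df <- as.data.frame(segs)
  expect_equal(df$state[df$onset_s == 0], "phasic")
  expect_true(all(df$state[df$onset_s > 4] == "tonic"))

  # 20 uV deflection stays under the tonic bound: all tonic
  x <- z
  x[round(1.5 * fs):(round(1.5 * fs) + round(0.3 * fs) - 1)] <-
    biphasic(20, 300, fs)
  segs <- classify_rem_segments(x, fs, hyp)
  expect_true(all(as.data.frame(segs)$state == "tonic"))

  # single 60 uV slow deflection: neither phasic nor tonic
  x <- z
  x[round(1.5 * fs):(round(1.5 * fs) + round(0.4 * fs) - 1)] <-
    biphasic(60, 400, fs)
  segs <- classify_rem_segments(x, fs, hyp)
  df <- as.data.frame(segs)
  expect_false(any(df$state == "phasic"))
  expect_true(all(df$onset_s >= 1.8 | df$onset_s + 4 <= 1.5))

  # no REM epochs: empty set with warning
  expect_warning(
    s0 <- classify_rem_segments(z, fs, hypnogram(rep("N2", 2))), "REM")
  expect_equal(length(s0), 0)
})

test_that("segment selection keeps 8 s spacing and caps honour the seed", {
  sy <- synthesize_recording(quiet_config(duration_s = 600, seed = 21))
  eog <- sy$recording$signals["EOG", ]
  segs <- classify_rem_segments(eog, 128, sy$truth$hypnogram, seed = 4)
  df <- as.data.frame(segs)
  gaps <- df$onset_s[-1] - (df$onset_s + df$duration_s)[-nrow(df)]
  expect_true(all(gaps >= 8 - 1e-9))

  capped <- classify_rem_segments(eog, 128, sy$truth$hypnogram,
                                  max_per_state = 5, seed = 4)
  expect_true(all(table(as.data.frame(capped)$state) <= 5))
  again <- classify_rem_segments(eog, 128, sy$truth$hypnogram,
                                 max_per_state = 5, seed = 4)
  expect_identical(as.data.frame(capped), as.data.frame(again))
})

test_that("raising the amplitude threshold never increases phasic counts", {
  sy <- synthesize_recording(quiet_config(duration_s = 600, seed = 22))
  eog <- sy$recording$signals["EOG", ]
  counts <- vapply(c(80, 100, 160), function(th) {
    df <- as.data.frame(classify_rem_segments(eog, 128, sy$truth$hypnogram,
                                              amp_thresh_uv = th, seed = 1))
    sum(df$state == "phasic")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("wake selection prefers pre-sleep-onset eyes-closed windows", {
  fs <- 128
  hyp <- hypnogram(c(rep("W", 4), rep("REM", 4), rep("W", 4)))
  set.seed(1)
  eog <- rnorm(12 * 30 * fs, 0, 5)
  segs <- select_wake_segments(eog, fs, hyp)
  df <- as.data.frame(segs)
  expect_gt(nrow(df), 0)
  expect_true(all(df$state == "wake"))
  expect_true(all(df$onset_s + df$duration_s <= 120))

  expect_warning(
    s0 <- select_wake_segments(eog, fs, hypnogram(rep("REM", 12))), "wake")
  expect_equal(length(s0), 0)
})
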