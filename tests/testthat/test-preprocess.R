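test_that("band-pass filter: stopband, passband, zero phase", {
  fs <- 256
  t <- seq(0, 10, by = 1 / fs)[-1]

  # DC offset is removed
  y <- bandpass_filter(rep(10, length(t)), fs)
  trim <- (2 * fs):(length(t) - 2 * fs)
  expect_lt(mean(abs(y[trim])), 0.1)

  # 10 Hz unit sinusoid passes within 1%
  y <- bandpass_filter(sin(2 * pi * 10 * t), fs)
  expect_lt(abs(max(y[trim]) - 1), 0.01)

  # symmetric in-band pulse keeps its peak latency (zero phase)
  x <- exp(-((t - 5)^2) / (2 * 0.05^2))
  y <- bandpass_filter(x, fs)
  expect_equal(which.max(y), which.max(x))

  # matrix input filters each row
  m <- rbind(sin(2 * pi * 10 * t), rep(5, length(t)))
  ym <- bandpass_filter(m, fs)
  expect_equal(dim(ym), dim(m))
  expect_lt(mean(abs(ym[2, trim])), 0.1)

  expect_error(bandpass_filter(t, fs = 60, low = 0.5, high = 35),
               "infeasible")

  # the FFT method reproduces the two-pass response away from edges
  set.seed(40)
  x2 <- rnorm(length(t))
  y_iir <- bandpass_filter(x2, fs)
  y_fft <- bandpass_filter(x2, fs, method = "fft")
  expect_lt(max(abs((y_iir - y_fft)[trim])), 0.05 * sd(y_iir))
})

test_that("eye-movement ICA removes the ocular source and only that", {
  sy <- synthesize_recording(quiet_config(duration_s = 480, seed = 41))
  rec <- sy$recording
  fs <- rec$fs
  eog <- rec$signals["EOG", ]
  segs <- classify_rem_segments(eog, fs, sy$truth$hypnogram, seed = 1)
  filt <- rec
  filt$signals[1:19, ] <- bandpass_filter(rec$signals[1:19, ], fs, 0.5, 35)
  out <- remove_em_components(filt, segs, seed = 2)
  expect_lte(length(out$decomposition$removed), 4)

  # frontal-EEG / EOG coupling during phasic segments drops by >= 50%
  ph <- as.data.frame(subset_segments(segs, "phasic"))
  cols <- unlist(lapply(seq_len(nrow(ph)), function(i) {
    i0 <- floor(ph$onset_s[i] * fs) + 1
    i0:(i0 + 4 * fs - 1)
  }))
  pre <- abs(cor(filt$signals["Fp1", cols], eog[cols]))
  post <- abs(cor(out$recording$signals["Fp1", cols], eog[cols]))
  expect_lte(post, 0.5 * pre)

  # EOG and ECG channels untouched
  expect_identical(out$recording$signals["EOG", ], filt$signals["EOG", ])
  expect_identical(out$recording$signals["ECG", ], filt$signals["ECG", ])

  # cleaning does not increase total EEG variance on the fitted span
  v_pre <- sum(apply(filt$signals[1:19, cols], 1, var))
  v_post <- sum(apply(out$recording$signals[1:19, cols], 1, var))
  expect_lte(v_post, v_pre * (1 + 1e-9))
})

test_that("ICA flagging respects the threshold and the removal cap", {
  sy <- synthesize_recording(quiet_config(duration_s = 480, seed = 42))
  rec <- sy$recording
  segs <- classify_rem_segments(rec$signals["EOG", ], rec$fs,
                                sy$truth$hypnogram, seed = 1)

  # nothing exceeds an impossible threshold: exact reconstruction
  out <- remove_em_components(rec, segs, corr_thresh = 1.01, seed = 2)
  expect_length(out$decomposition$removed, 0)
  expect_equal(out$recording$signals, rec$signals)

  # a permissive threshold flags many components but at most 4 are
  # removed, and they are the top 4 by |EOG correlation|
  out2 <- remove_em_components(rec, segs, corr_thresh = 0.001, seed = 2)
  cors <- out2$decomposition$eog_correlations
  expect_length(out2$decomposition$removed, 4)
  expect_setequal(out2$decomposition$removed,
                  order(cors, decreasing = TRUE)[1:4])

  expect_error(remove_em_components(rec, segment_set(
    data.frame(onset_s = numeric(0), duration_s = numeric(0),
               state = character(0)))), "non-empty")
})
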