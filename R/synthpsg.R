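#' Synthetic polysomnography configuration
#'
#' Bundles every generative assumption of the synthetic recording:
#' cardiac rhythm, ECG morphology, cardiac-field leakage into the scalp,
#' eye-movement bursts confined to phasic REM, state-dependent high-alpha
#' (10-14 Hz) and beta (15-28 Hz) background power, 1/f noise, and an
#' injectable heartbeat-locked EEG component whose amplitude differs
#' between REM microstates. Defaults emulate an overnight montage at a
#' desk-friendly scale: ~60 bpm with SDNN around 55 ms, cardiac-field
#' leakage below 1% of the chest ECG, and a +1.5 microvolt
#' fronto-central heartbeat-locked bump centred 600 ms post-R in phasic
#' REM only.
#'
#' @param duration_s total recording duration in seconds (rounded up to
#'   whole 30-s epochs).
#' @param fs sampling rate in Hz (integer).
#' @param eeg_labels EEG channel labels (10-20 names); an EOG and an ECG
#'   channel are always appended.
#' @param wake_s seconds of eyes-closed wake at the start of the
#'   recording (rounded to whole 30-s epochs); the remainder is REM.
#' @param mean_ibi_ms,ibi_sd_ms inter-beat interval mean and SD (ms);
#'   IBIs are drawn from a normal truncated to [250, 2000] ms.
#' @param ecg_leak_fraction per-channel ceiling on the ratio of leaked
#'   cardiac-field artifact amplitude to chest ECG amplitude (< 0.01).
#' @param hep_spec per-state heartbeat-locked component: a list with
#'   elements `phasic`, `tonic`, `wake`, each a list of `amplitude_uv`,
#'   `center_ms`, `width_ms` (Gaussian sigma); plus `topography`, a
#'   named weight vector over EEG channels (defaults to a
#'   fronto-central template).
#' @param em_spec eye-movement burst parameters: `amplitude_uv` (>= 100),
#'   `duration_ms` (< 500), `burst_size` (>= 2 consecutive movements),
#'   `gap_s` (onset-to-onset gap inside a burst), `interval_s` (burst
#'   start-to-start interval within a phasic span).
#' @param band_power_spec per-state RMS (microvolts) of band-limited
#'   background activity: a list with `alpha_rms_uv` and `beta_rms_uv`,
#'   each a named vector with `phasic` and `tonic` entries (tonic
#'   elevated by default, as in REM microstate EEG).
#' @param noise_spec list with `exponent` (1/f slope), `eeg_rms_uv`,
#'   `eog_rms_uv`, `ecg_rms_uv`.
#' @param phasic_span_s,tonic_span_s,buffer_s layout of the alternating
#'   REM microstate spans and the unlabeled buffer between them.
#' @param seed integer RNG seed; the whole recording is a deterministic
#'   function of the configuration.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(duration_s = 900,
                         fs = 200,
                         eeg_labels = ten_twenty_positions()$label,
                         wake_s = 120,
                         mean_ibi_ms = 1000,
                         ibi_sd_ms = 55,
                         ecg_leak_fraction = 0.005,
                         hep_spec = NULL,
                         em_spec = NULL,
                         band_power_spec = NULL,
                         noise_spec = NULL,
                         phasic_span_s = 20,
                         tonic_span_s = 20,
                         buffer_s = 12,
                         seed = 1) {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (fs <= 0 || fs != round(fs)) stop("fs must be a positive integer")
  if (mean_ibi_ms <= 250) stop("mean_ibi_ms must exceed the 250 ms refractory")
  if (ecg_leak_fraction >= 0.01) {
    stop("ecg_leak_fraction must stay below 0.01 (cardiac-field premise)")
  }
  default_hep <- list(
    phasic = list(amplitude_uv = 1.5, center_ms = 600, width_ms = 40),
    tonic = list(amplitude_uv = 0, center_ms = 600, width_ms = 40),
    wake = list(amplitude_uv = 0, center_ms = 600, width_ms = 40),
    topography = frontocentral_weights(eeg_labels)
  )
  hep_spec <- utils::modifyList(default_hep, hep_spec %||% list())
  if (!all(is.finite(hep_spec$topography))) {
    stop("hep topography weights must be finite")
  }
  em_spec <- utils::modifyList(
    list(amplitude_uv = 150, duration_ms = 250, burst_size = 3,
         gap_s = 0.4, interval_s = 2.5),
    em_spec %||% list())
  band_power_spec <- utils::modifyList(
    list(alpha_rms_uv = c(phasic = 2, tonic = 4),
         beta_rms_uv = c(phasic = 1.5, tonic = 3)),
    band_power_spec %||% list())
  noise_spec <- utils::modifyList(
    list(exponent = 1, eeg_rms_uv = 15, eog_rms_uv = 5, ecg_rms_uv = 5),
    noise_spec %||% list())
  wake_s <- 30 * round(wake_s / 30)
  duration_s <- 30 * ceiling(duration_s / 30)
  if (wake_s >= duration_s) stop("wake_s must be shorter than duration_s")
  structure(
    list(duration_s = duration_s, fs = as.integer(fs),
         eeg_labels = eeg_labels,
         channel_labels = c(eeg_labels, "EOG", "ECG"),
         wake_s = wake_s,
         mean_ibi_ms = mean_ibi_ms, ibi_sd_ms = ibi_sd_ms,
         ecg_leak_fraction = ecg_leak_fraction,
         hep_spec = hep_spec, em_spec = em_spec,
         band_power_spec = band_power_spec, noise_spec = noise_spec,
         phasic_span_s = phasic_span_s, tonic_span_s = tonic_span_s,
         buffer_s = buffer_s, seed = as.integer(seed)),
    class = "synth_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a cardiac rhythm as an R-peak series
#'
#' Successive inter-beat intervals are drawn from a normal distribution
#' truncated to the physiologic range [250, 2000] ms, so that the mean
#' heart rate and the SDNN heart-rate-variability index are directly
#' controllable.
#'
#' @param mean_ibi_ms mean inter-beat interval in ms (> 250).
#' @param ibi_sd_ms IBI standard deviation in ms (>= 0).
#' @param duration_s duration to fill with beats.
#' @param fs sampling rate used to express peaks as sample indices.
#' @param seed optional RNG seed; identical seeds give identical series.
#' @return an `rpeak_series` whose peak times span at most `duration_s`.
#' @export
generate_rr_series <- function(mean_ibi_ms, ibi_sd_ms, duration_s, fs,
                               seed = NULL) {
  if (duration_s <= 0 || mean_ibi_ms <= 0) {
    stop("duration_s and mean_ibi_ms must be positive")
  }
  if (mean_ibi_ms <= 250) stop("mean_ibi_ms must exceed 250 ms")
  if (ibi_sd_ms < 0) stop("ibi_sd_ms must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n_guess <- ceiling(duration_s * 1000 / mean_ibi_ms) + 10
  draw <- function(n) {
    if (ibi_sd_ms == 0) return(rep(mean_ibi_ms, n))
    x <- stats::rnorm(n, mean_ibi_ms, ibi_sd_ms)
    bad <- x < 250 | x > 2000
    while (any(bad)) {
      x[bad] <- stats::rnorm(sum(bad), mean_ibi_ms, ibi_sd_ms)
      bad <- x < 250 | x > 2000
    }
    x
  }
  ibis <- draw(n_guess)
  t_ms <- cumsum(ibis)
  while (t_ms[length(t_ms)] < duration_s * 1000) {
    ibis <- c(ibis, draw(n_guess))
    t_ms <- cumsum(ibis)
  }
  t_ms <- t_ms[t_ms < duration_s * 1000]
  rpeak_series(round(t_ms / 1000 * fs), fs)
}

#' Synthesize a chest-ECG channel from an R-peak series
#'
#' Each beat is rendered as a QRS complex (sum of narrow Gaussians with
#' the R deflection dominant) plus a broader T-wave Gaussian at a
#' configurable post-R latency, so T-wave-proximity confound analyses
#' can be exercised. The R-peak sample is the global per-beat maximum.
#'
#' @param rpeaks an `rpeak_series` (non-empty, strictly increasing).
#' @param fs sampling rate in Hz.
#' @param r_amp_uv,q_amp_uv,s_amp_uv QRS component amplitudes (uV).
#' @param t_amp_uv T-wave amplitude (uV); set 0 to ablate the T-wave.
#' @param t_latency_ms,t_width_ms T-wave centre latency and Gaussian
#'   sigma (ms).
#' @param noise_rms_uv additive white measurement noise RMS (uV).
#' @param n_samples output length; defaults to just past the last beat.
#' @param seed optional RNG seed for the measurement noise.
#' @return numeric vector, ECG in microvolts.
#' @export
synthesize_ecg <- function(rpeaks, fs,
                           r_amp_uv = 1000, q_amp_uv = -150, s_amp_uv = -200,
                           t_amp_uv = 250, t_latency_ms = 300, t_width_ms = 60,
                           noise_rms_uv = 0, n_samples = NULL, seed = NULL) {
  pk <- rpeaks$peak_samples
  if (length(pk) == 0) stop("rpeaks must be non-empty")
  extent_ms <- t_latency_ms + 3 * t_width_ms
  if (length(pk) > 1 && min(diff(pk)) / fs * 1000 < extent_ms) {
    stop("IBI shorter than the QRS+T template (", extent_ms, " ms)")
  }
  if (is.null(n_samples)) n_samples <- max(pk) + round(fs * 0.8) + 1
  # beat template on a sample grid centred at the R peak
  lo <- -round(0.060 * fs)
  hi <- round((t_latency_ms + 3 * t_width_ms) / 1000 * fs)
  tt <- (lo:hi) / fs * 1000  # ms relative to R
  g <- function(a, mu, sig) a * exp(-((tt - mu)^2) / (2 * sig^2))
  template <- g(q_amp_uv, -25, 8) + g(r_amp_uv, 0, 10) + g(s_amp_uv, 25, 8) +
    g(t_amp_uv, t_latency_ms, t_width_ms)
  x <- numeric(n_samples)
  for (p in pk) {
    i0 <- p + lo + 1  # 0-based peak -> 1-based vector
    i1 <- p + hi + 1
    src <- seq_along(tt)
    if (i0 < 1) { src <- src[(2 - i0):length(src)]; i0 <- 1 }
    if (i1 > n_samples) { src <- src[1:(length(src) - (i1 - n_samples))]; i1 <- n_samples }
    if (length(src) > 0) x[i0:i1] <- x[i0:i1] + template[src]
  }
  if (noise_rms_uv > 0) {
    if (!is.null(seed)) set.seed(seed)
    x <- x + stats::rnorm(n_samples, 0, noise_rms_uv)
  }
  x
}

# 1/f^exponent coloured noise scaled to a target RMS
colored_noise <- function(n, exponent = 1, rms = 1) {
  m <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(m)
  X <- stats::fft(w)
  f <- c(1, seq_len(m - 1))
  f <- pmin(f, m - f + 1)  # symmetric frequency index
  scale <- f^(-exponent / 2)
  scale[1] <- 0
  x <- Re(stats::fft(X * scale, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  x / stats::sd(x) * rms
}

# band-limited Gaussian noise at unit RMS (spectral mask on white
# noise; brick-wall edges are adequate for a background generator)
band_noise <- function(n, fs, low, high) {
  m <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(stats::rnorm(m))
  f <- (seq_len(m) - 1) * fs / m
  f <- pmin(f, fs - f)  # two-sided spectrum
  X[f < low | f > high] <- 0
  y <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)] / m
  y / stats::sd(y)
}

# two independent unit-RMS band noises from one spectrum draw: the
# bands are disjoint in frequency, so the masked components are
# independent Gaussian processes
two_band_noise <- function(n, fs, band_a, band_b) {
  m <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(stats::rnorm(m))
  f <- (seq_len(m) - 1) * fs / m
  f <- pmin(f, fs - f)
  mask <- function(lo, hi) {
    Y <- X
    Y[f < lo | f > hi] <- 0
    y <- Re(stats::fft(Y, inverse = TRUE))[seq_len(n)] / m
    y / stats::sd(y)
  }
  list(a = mask(band_a[1], band_a[2]), b = mask(band_b[1], band_b[2]))
}

# biphasic eye-movement waveform: one full sine cycle, peak = amplitude
em_waveform <- function(amplitude_uv, duration_ms, fs) {
  n <- max(4L, round(duration_ms / 1000 * fs))
  amplitude_uv * sin(2 * pi * seq(0, 1, length.out = n))
}

#' Synthesize a full polysomnographic recording with ground truth
#'
#' Builds a multichannel recording (EEG per 10-20, bipolar EOG, chest
#' ECG) from a `synth_config`: 1/f background noise, state-dependent
#' 10-14 Hz and 15-28 Hz band power (elevated in tonic REM),
#' cardiac-field leakage of the ECG into every EEG channel below the
#' configured <1% bound, eye-movement bursts confined to phasic spans
#' with frontal-EEG leakage of the ocular source, and a heartbeat-locked
#' EEG component whose amplitude depends on the vigilance state. The
#' recording starts with eyes-closed wake epochs and continues with REM
#' in which labeled phasic and tonic spans alternate, separated by
#' unlabeled buffers.
#'
#' @param config a `synth_config`.
#' @return a list of class `synth_psg` with elements `recording`
#'   (a `psg_recording`) and `truth` (a `psg_ground_truth` carrying
#'   true R-peak indices, true eye-movement events, the true state
#'   spans, and the injected heartbeat-locked parameters).
#' @export
synthesize_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (!"ECG" %in% config$channel_labels || !"EOG" %in% config$channel_labels) {
    stop("configuration must include an EOG and an ECG channel")
  }
  set.seed(config$seed)
  fs <- config$fs
  n <- config$duration_s * fs
  nch_eeg <- length(config$eeg_labels)

  ## --- state layout ----------------------------------------------------
  spans <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      state = character(0), stringsAsFactors = FALSE)
  if (config$wake_s > 0) {
    spans <- rbind(spans, data.frame(onset_s = 0, duration_s = config$wake_s,
                                     state = "wake"))
  }
  t0 <- config$wake_s
  state <- "phasic"
  while (TRUE) {
    t0 <- t0 + config$buffer_s
    len <- if (state == "phasic") config$phasic_span_s else config$tonic_span_s
    if (t0 + len > config$duration_s) break
    spans <- rbind(spans, data.frame(onset_s = t0, duration_s = len,
                                     state = state))
    t0 <- t0 + len
    state <- if (state == "phasic") "tonic" else "phasic"
  }
  n_wake_ep <- config$wake_s / 30
  n_ep <- config$duration_s / 30
  hyp <- hypnogram(c(rep("W", n_wake_ep), rep("REM", n_ep - n_wake_ep)))

  state_of_sample <- rep("buffer", n)
  for (i in seq_len(nrow(spans))) {
    i0 <- floor(spans$onset_s[i] * fs) + 1
    i1 <- min(n, ceiling((spans$onset_s[i] + spans$duration_s[i]) * fs))
    state_of_sample[i0:i1] <- spans$state[i]
  }

  ## --- cardiac rhythm and chest ECG ------------------------------------
  rr <- generate_rr_series(config$mean_ibi_ms, config$ibi_sd_ms,
                           config$duration_s, fs)
  ecg <- synthesize_ecg(rr, fs, noise_rms_uv = config$noise_spec$ecg_rms_uv,
                        n_samples = n)

  ## --- EOG: noise + eye-movement bursts in phasic spans ----------------
  em <- config$em_spec
  em_source <- numeric(n)
  em_events <- list()
  phasic_spans <- spans[spans$state == "phasic", ]
  wf <- em_waveform(em$amplitude_uv, em$duration_ms, fs)
  for (i in seq_len(nrow(phasic_spans))) {
    s0 <- phasic_spans$onset_s[i]
    s1 <- s0 + phasic_spans$duration_s[i]
    burst_len <- (em$burst_size - 1) * em$gap_s + em$duration_ms / 1000
    b <- s0 + 0.5
    while (b + burst_len < s1 - 0.2) {
      for (k in seq_len(em$burst_size)) {
        onset <- b + (k - 1) * em$gap_s
        i0 <- floor(onset * fs) + 1
        idx <- i0:(i0 + length(wf) - 1)
        ok <- idx <= n
        em_source[idx[ok]] <- em_source[idx[ok]] + wf[ok]
        em_events[[length(em_events) + 1]] <-
          data.frame(onset_s = onset, duration_ms = em$duration_ms,
                     peak_amplitude_uv = em$amplitude_uv)
      }
      b <- b + em$interval_s
    }
  }
  em_events <- if (length(em_events)) do.call(rbind, em_events) else
    data.frame(onset_s = numeric(0), duration_ms = numeric(0),
               peak_amplitude_uv = numeric(0))
  eog <- em_source +
    if (config$noise_spec$eog_rms_uv > 0)
      colored_noise(n, config$noise_spec$exponent,
                    config$noise_spec$eog_rms_uv) else 0

  ## --- EEG -------------------------------------------------------------
  bp <- config$band_power_spec
  mid_alpha <- mean(bp$alpha_rms_uv)
  mid_beta <- mean(bp$beta_rms_uv)
  alpha_env <- ifelse(state_of_sample == "phasic", bp$alpha_rms_uv[["phasic"]],
               ifelse(state_of_sample == "tonic", bp$alpha_rms_uv[["tonic"]],
                      mid_alpha))
  beta_env <- ifelse(state_of_sample == "phasic", bp$beta_rms_uv[["phasic"]],
              ifelse(state_of_sample == "tonic", bp$beta_rms_uv[["tonic"]],
                     mid_beta))

  # cardiac-field leakage gains: at most ecg_leak_fraction of chest ECG
  leak_w <- seq(1, 0.3, length.out = nch_eeg)
  # ocular source leakage, decaying with distance from the frontopolar row
  pos <- ten_twenty_positions(config$eeg_labels)
  d_front <- pmin(sqrt((pos$x + 0.31)^2 + (pos$y - 0.95)^2),
                  sqrt((pos$x - 0.31)^2 + (pos$y - 0.95)^2))
  eog_gain <- 0.4 * exp(-d_front / 0.35)

  # heartbeat-locked component, per state
  hs <- config$hep_spec
  topo <- hs$topography[config$eeg_labels]
  peak_state <- state_of_sample[pmin(n, rr$peak_samples + 1)]
  hep_source <- numeric(n)  # unit-amplitude per-state envelope source
  state_amp <- c(phasic = hs$phasic$amplitude_uv,
                 tonic = hs$tonic$amplitude_uv,
                 wake = hs$wake$amplitude_uv, buffer = 0)
  for (st in c("phasic", "tonic", "wake")) {
    amp <- state_amp[[st]]
    if (amp == 0) next
    par <- hs[[st]]
    sig_n <- par$width_ms / 1000 * fs
    half <- ceiling(3 * sig_n)
    bump <- amp * exp(-((-half:half)^2) / (2 * sig_n^2))
    ctr <- round(par$center_ms / 1000 * fs)
    for (p in rr$peak_samples[peak_state == st]) {
      i0 <- p + ctr - half + 1
      idx <- i0:(i0 + length(bump) - 1)
      ok <- idx >= 1 & idx <= n
      hep_source[idx[ok]] <- hep_source[idx[ok]] + bump[ok]
    }
  }

  eeg <- matrix(0, nch_eeg, n)
  for (c0 in seq_len(nch_eeg)) {
    ch <- colored_noise(n, config$noise_spec$exponent,
                        config$noise_spec$eeg_rms_uv)
    bn <- two_band_noise(n, fs, c(10, 14), c(15, min(28, fs / 2 - 1)))
    ch <- ch + alpha_env * bn$a + beta_env * bn$b
    ch <- ch + config$ecg_leak_fraction * leak_w[c0] * ecg
    ch <- ch + eog_gain[c0] * em_source
    ch <- ch + topo[c0] * hep_source
    eeg[c0, ] <- ch
  }

  rec <- continuous_recording(
    signals = rbind(eeg, EOG = eog, ECG = ecg),
    fs = fs,
    labels = config$channel_labels,
    channel_types = c(rep("EEG", nch_eeg), "EOG", "ECG"))

  truth <- structure(
    list(true_rpeaks = rr$peak_samples,
         true_em_events = em_events,
         true_state_spans = spans,
         hypnogram = hyp,
         injected_hep = hs,
         seed = config$seed),
    class = "psg_ground_truth")
  structure(list(recording = rec, truth = truth, config = config),
            class = "synth_psg")
}

#' @export
print.synth_psg <- function(x, ...) {
  cat("Synthetic PSG:", x$config$duration_s, "s at", x$config$fs, "Hz,",
      length(x$config$channel_labels), "channels\n")
  cat("  ", length(x$truth$true_rpeaks), "true R-peaks, ",
      nrow(x$truth$true_em_events), " true eye movements\n", sep = "")
  tab <- table(x$truth$true_state_spans$state)
  cat("  state spans:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Simulate a cohort of per-subject HEP condition averages
#'
#' Generates the statistical unit of the group analysis directly:
#' per-subject, per-condition heartbeat-evoked-potential averages
#' (channels x time) with temporally smoothed, spatially correlated
#' noise and an optional condition difference injected as a Gaussian
#' bump with a fronto-central scalp topography. Under the null
#' (`effect_uv = 0`) the two conditions are exchangeable, which is what
#' the type-I-error calibration of the cluster test requires; with a
#' nonzero effect it reproduces the known-truth detection setting.
#'
#' @param n_subjects number of subjects.
#' @param channel_labels EEG channels (10-20 names).
#' @param fs sampling rate defining the epoch time axis.
#' @param epoch_ms epoch span in ms relative to the R-peak.
#' @param effect_uv condition difference (phasic minus tonic) amplitude
#'   in microvolts at the bump centre.
#' @param effect_center_ms,effect_width_ms bump centre latency and
#'   Gaussian sigma in ms.
#' @param topography named channel weight vector in [0, 1]; defaults to
#'   the fronto-central template.
#' @param noise_sd_uv between-subject SD of the averaged waveforms; the
#'   default 0.8 uV corresponds to averaging a few hundred trials of
#'   ~15 uV background EEG.
#' @param smooth_ms temporal autocorrelation scale of the noise.
#' @param spatial_mix fraction of a common (global) noise trace mixed
#'   into every channel.
#' @param seed RNG seed.
#' @return list of class `hep_cohort` with arrays `phasic` and `tonic`
#'   (subjects x channels x time), `times_ms`, and `labels`.
#' @export
simulate_hep_cohort <- function(n_subjects = 12,
                                channel_labels = ten_twenty_positions()$label,
                                fs = 512,
                                epoch_ms = c(-200, 800),
                                effect_uv = 0,
                                effect_center_ms = 600,
                                effect_width_ms = 40,
                                topography = NULL,
                                noise_sd_uv = 0.8,
                                smooth_ms = 20,
                                spatial_mix = 0.3,
                                seed = 1) {
  set.seed(seed)
  nch <- length(channel_labels)
  times_ms <- seq(epoch_ms[1], epoch_ms[2] - 1000 / fs, by = 1000 / fs)
  nt <- length(times_ms)
  topo <- topography %||% frontocentral_weights(channel_labels)
  bump <- effect_uv * exp(-((times_ms - effect_center_ms)^2) /
                            (2 * effect_width_ms^2))
  kernel_n <- max(1L, round(smooth_ms / 1000 * fs))
  kern <- stats::dnorm(seq(-3, 3, length.out = 2 * kernel_n + 1))
  kern <- kern / sum(kern)
  smooth_noise <- function() {
    e <- matrix(stats::rnorm(nch * (nt + 2 * length(kern))), nch)
    # stats::filter smooths each column: transpose once each way
    e <- t(stats::filter(t(e), kern, sides = 2))
    e <- e[, (length(kern) + 1):(length(kern) + nt), drop = FALSE]
    common <- colMeans(e)
    e <- (1 - spatial_mix) * e +
      spatial_mix * matrix(common, nch, nt, byrow = TRUE)
    e / stats::sd(e) * noise_sd_uv
  }
  ph <- array(0, c(n_subjects, nch, nt))
  to <- array(0, c(n_subjects, nch, nt))
  for (s in seq_len(n_subjects)) {
    ph[s, , ] <- smooth_noise() + outer(topo, bump)
    to[s, , ] <- smooth_noise()
  }
  structure(list(phasic = ph, tonic = to, times_ms = times_ms,
                 labels = channel_labels, effect_uv = effect_uv,
                 seed = seed),
            class = "hep_cohort")
}
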