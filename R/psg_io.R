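#' Continuous polysomnographic recording
#'
#' The pipeline's raw-input container: a channels x samples matrix of
#' physical amplitudes (microvolts) with sampling rate, unique channel
#' labels and per-channel types.
#'
#' @param signals numeric matrix, channels x samples.
#' @param fs sampling rate in Hz.
#' @param labels unique channel names (length = nrow(signals)).
#' @param channel_types one of "EEG", "EOG", "ECG" per channel; guessed
#'   from the labels when omitted.
#' @param start_time recording start as POSIXct (metadata only).
#' @return object of class `psg_recording`.
#' @export
continuous_recording <- function(signals, fs, labels,
                                 channel_types = NULL,
                                 start_time = as.POSIXct("2000-01-01 00:00:00",
                                                         tz = "UTC")) {
  signals <- as.matrix(signals)
  if (fs <= 0) stop("fs must be positive")
  if (length(labels) != nrow(signals)) {
    stop("labels must have one entry per signal row")
  }
  if (anyDuplicated(labels)) {
    stop("duplicate channel label: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (is.null(channel_types)) channel_types <- guess_channel_types(labels)
  channel_types <- match.arg(channel_types, c("EEG", "EOG", "ECG"),
                             several.ok = TRUE)
  if (length(channel_types) != length(labels)) {
    stop("channel_types must have one entry per channel")
  }
  rownames(signals) <- labels
  structure(list(signals = signals, fs = fs, labels = labels,
                 channel_types = channel_types, start_time = start_time),
            class = "psg_recording")
}

guess_channel_types <- function(labels) {
  up <- toupper(labels)
  ifelse(grepl("ECG|EKG", up), "ECG",
         ifelse(grepl("EOG|LOC|ROC", up), "EOG", "EEG"))
}

#' @export
print.psg_recording <- function(x, ...) {
  cat("PSG recording: ", nrow(x$signals), " channels x ",
      ncol(x$signals), " samples (", ncol(x$signals) / x$fs, " s at ",
      x$fs, " Hz)\n", sep = "")
  cat("  channels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

# channel accessor by label or type
get_channel <- function(recording, label) {
  i <- match(label, recording$labels)
  if (is.na(i)) stop("no channel labeled ", label)
  recording$signals[i, ]
}

eeg_indices <- function(recording) which(recording$channel_types == "EEG")

#' Write a recording to EDF
#'
#' Plain EDF (16-bit samples, physical dimension uV) with one data
#' record per second. The physical range of each channel is taken from
#' its data (symmetric, slightly padded), so round-trip error is bounded
#' by one 16-bit quantization step of that range.
#'
#' @param recording a `psg_recording`; its sample count must be a whole
#'   number of seconds.
#' @param path output file path.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "psg_recording"))
  fs <- recording$fs
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  n <- ncol(recording$signals)
  if (n %% fs != 0) {
    stop("recording length must be a whole number of seconds for EDF export")
  }
  ns <- nrow(recording$signals)
  n_rec <- n %/% fs

  pad <- function(x, width) {
    x <- substr(as.character(x), 1, width)
    formatC(x, width = width, flag = "-")
  }
  phys_max <- apply(abs(recording$signals), 1, max)
  phys_max <- ifelse(phys_max <= 0, 1, phys_max * 1.0001)
  phys_min <- -phys_max
  dig_min <- -32768
  dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  st <- recording$start_time
  header <- paste0(
    pad("0", 8),                                   # version
    pad("X X X X", 80),                            # patient id
    pad("Startdate X X X X", 80),                  # recording id
    pad(format(st, "%d.%m.%y"), 8),
    pad(format(st, "%H.%M.%S"), 8),
    pad(256 * (1 + ns), 8),                        # header bytes
    pad("", 44),                                   # reserved
    pad(n_rec, 8),
    pad("1", 8),                                   # record duration (s)
    pad(ns, 4))
  writeChar(header, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, pad, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  field(recording$labels, 16)
  field(rep("", ns), 80)                           # transducer
  field(rep("uV", ns), 8)                          # physical dimension
  field(formatC(phys_min, format = "g", digits = 7), 8)
  field(formatC(phys_max, format = "g", digits = 7), 8)
  field(rep(dig_min, ns), 8)
  field(rep(dig_max, ns), 8)
  field(rep("", ns), 80)                           # prefiltering
  field(rep(fs, ns), 8)                            # samples per record
  field(rep("", ns), 32)                           # reserved

  # re-read the header's printed physical range so the scaling used for
  # quantization matches what a reader will parse
  phys_min_r <- as.numeric(formatC(phys_min, format = "g", digits = 7))
  phys_max_r <- as.numeric(formatC(phys_max, format = "g", digits = 7))
  gain <- (phys_max_r - phys_min_r) / (dig_max - dig_min)
  dig <- round(sweep(sweep(recording$signals, 1, phys_min_r), 1, gain, "/")) +
    dig_min
  dig[dig < dig_min] <- dig_min
  dig[dig > dig_max] <- dig_max
  storage.mode(dig) <- "integer"
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads plain EDF files as written by [write_edf()] (equal sampling
#' rate across channels). Amplitudes are rescaled to physical units.
#'
#' @param path EDF file path.
#' @return a `psg_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                        # version
  rd(80); rd(80)               # patient / recording id
  date_s <- rd(8); time_s <- rd(8)
  rd(8)                        # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns <= 0) stop("malformed EDF header: bad signal count")
  rdn <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdn(16)
  if (anyDuplicated(labels)) {
    stop("duplicate channel label in EDF: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  rdn(80); rdn(8)
  phys_min <- as.numeric(rdn(8))
  phys_max <- as.numeric(rdn(8))
  dig_min <- as.numeric(rdn(8))
  dig_max <- as.numeric(rdn(8))
  rdn(80)
  spr <- as.integer(rdn(8))
  rdn(32)
  if (length(unique(spr)) != 1) {
    stop("mixed per-channel sampling rates are not supported")
  }
  fs <- spr[1] / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  sig <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = ns * spr[1], size = 2,
                     endian = "little")
    block <- matrix(block, nrow = spr[1], ncol = ns)
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    sig[, cols] <- t(block)
  }
  sig <- sweep(sweep(sig, 1, dig_min), 1, gain, "*")
  sig <- sweep(sig, 1, phys_min, "+")
  start_time <- as.POSIXct(paste(date_s, time_s), tz = "UTC",
                           format = "%d.%m.%y %H.%M.%S")
  if (is.na(start_time)) start_time <- as.POSIXct("2000-01-01", tz = "UTC")
  continuous_recording(sig, fs, labels, start_time = start_time)
}

#' Hypnogram constructor
#'
#' A per-epoch sequence of AASM sleep stages (vocabulary W, N1, N2, N3,
#' REM) with a fixed epoch length, 30 s by default.
#'
#' @param stages character vector of stages.
#' @param epoch_length_s epoch length in seconds.
#' @return object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_length_s = 30) {
  stages <- trimws(as.character(stages))
  bad <- !stages %in% c("W", "N1", "N2", "N3", "REM")
  if (any(bad)) {
    stop("unknown sleep stage token(s) at row(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(stages[bad]), collapse = ", "))
  }
  structure(list(stages = stages, epoch_length_s = epoch_length_s),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = c("W", "N1", "N2", "N3", "REM")))
  cat("Hypnogram: ", length(x$stages), " epochs of ", x$epoch_length_s,
      " s (", paste(names(tab), tab, sep = "=", collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Read / write a hypnogram CSV
#'
#' CSV with columns `epoch_index` (0-based) and `stage`; stage tokens
#' are trimmed and validated against the AASM vocabulary.
#'
#' @param path CSV file path.
#' @param epoch_length_s epoch length in seconds.
#' @return [read_hypnogram()] returns a `hypnogram`.
#' @export
read_hypnogram <- function(path, epoch_length_s = 30) {
  df <- utils::read.csv(path, strip.white = TRUE)
  if (!all(c("epoch_index", "stage") %in% names(df))) {
    stop("hypnogram CSV must have columns epoch_index, stage")
  }
  df <- df[order(df$epoch_index), ]
  hypnogram(df$stage, epoch_length_s)
}

#' @rdname read_hypnogram
#' @param hyp a `hypnogram` to serialize.
#' @export
write_hypnogram <- function(hyp, path) {
  utils::write.csv(
    data.frame(epoch_index = seq_along(hyp$stages) - 1, stage = hyp$stages),
    path, row.names = FALSE)
  invisible(path)
}

#' Read / write segment annotations as JSON
#'
#' Segments are serialized with onset, duration and state, plus the
#' selection metadata recorded by the classifier.
#'
#' @param segset a `segment_set`.
#' @param path JSON file path.
#' @export
write_segments <- function(segset, path) {
  jsonlite::write_json(
    list(segments = as.data.frame(segset), metadata = segset$metadata),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  segment_set(obj$segments, metadata = obj$metadata)
}
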