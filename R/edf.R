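# Minimal European Data Format (EDF) support: 16-bit samples, one-second
# data records, identical sampling rate on every channel. Enough to exchange
# simulated cohorts with standard biosignal tools; not a general EDF
# implementation (no annotations, no EDF+).

edf_pad <- function(s, width) {
  s <- substr(as.character(s), 1, width)
  formatC(s, width = -width, flag = " ")
}

#' Write an EEG record to an EDF file
#'
#' Samples are scaled to 16-bit integers over a symmetric physical range
#' covering the data (quantisation step `2 * phys_max / 65535`). The record
#' is truncated to a whole number of one-second data records. Timestamps are
#' fixed (01.01.00) so output is byte-reproducible.
#'
#' @param record An [eeg_record()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  fs <- record$fs
  if (fs != round(fs)) abort_invalid("EDF writer requires an integer sampling rate")
  ns <- nrow(record$data)
  n_rec <- ncol(record$data) %/% fs
  if (n_rec < 1) abort_invalid("record shorter than one EDF data record (1 s)")
  data <- record$data[, seq_len(n_rec * fs), drop = FALSE]
  phys <- max(1, ceiling(max(abs(data))))
  dig_max <- 32767L; dig_min <- -32768L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(edf_pad(s, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)
  wr(paste("X X X", record$subject_id), 80)
  wr(paste("Startdate 01-JAN-2000 X X X label",
           ifelse(is.na(record$label), "NA", record$label)), 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256 * (1 + ns), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr("1", 8)
  wr(ns, 4)
  chs <- seq_len(ns)
  for (ch in chs) wr(record$channel_names[ch], 16)
  for (ch in chs) wr("AgAgCl electrode", 80)
  for (ch in chs) wr("uV", 8)
  for (ch in chs) wr(-phys, 8)
  for (ch in chs) wr(phys, 8)
  for (ch in chs) wr(dig_min, 8)
  for (ch in chs) wr(dig_max, 8)
  for (ch in chs) wr("", 80)
  for (ch in chs) wr(fs, 8)
  for (ch in chs) wr("", 32)
  scale <- (dig_max - dig_min) / (2 * phys)
  for (r in seq_len(n_rec)) {
    cols <- (r - 1) * fs + seq_len(fs)
    for (ch in chs) {
      dig <- round((data[ch, cols] + phys) * scale) + dig_min
      dig <- pmin(pmax(dig, dig_min), dig_max)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Supports the subset this package writes: equal per-channel sampling
#' rates, 16-bit samples, no annotation channels.
#'
#' @param path EDF file path.
#' @return An [eeg_record()]. The class label is recovered from the
#'   recording-identification header field when present.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                                   # version
  patient <- rd(80)
  recording <- rd(80)
  rd(8); rd(8)                            # date, time
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)           # transducer
  for (i in seq_len(ns)) rd(8)            # dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)           # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    abort_invalid("reader supports equal per-channel sampling rates only")
  fs <- spr[1] / dur
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2, endian = "little",
                     signed = TRUE)
      cols <- (r - 1) * spr[ch] + seq_len(spr[ch])
      data[ch, cols] <- phys_min[ch] + (dig - dig_min[ch]) *
        (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
    }
  }
  label <- if (grepl("label (\\S+)", recording))
    sub(".*label (\\S+).*", "\\1", recording) else NA_character_
  subject_id <- sub("^X X X ", "", patient)
  eeg_record(data, fs = fs, subject_id = subject_id, label = label,
             channel_names = labels)
}
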