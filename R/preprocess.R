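#' Band-pass filter an EEG record
#'
#' Per-channel zero-phase Butterworth band-pass (default 0.5-32 Hz, order 5,
#' applied forward and backward). Output length equals input length.
#'
#' @param record An [eeg_record()].
#' @param low_hz,high_hz Pass-band edges in Hz.
#' @param order Butterworth prototype order.
#' @return The filtered record.
#' @export
bandpass_filter <- function(record, low_hz = 0.5, high_hz = 32, order = 5) {
  fs <- record$fs
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    abort_invalid("need 0 < low_hz < high_hz < fs/2")
  ba <- butter_design(order, c(low_hz, high_hz), fs = fs, type = "band")
  record$data <- t(apply(record$data, 1, function(x) filtfilt_ba(ba, x)))
  rownames(record$data) <- record$channel_names
  record
}

#' Cut a record into fixed-length non-overlapping segments
#'
#' Segments are taken contiguously from the start of the record, in source
#' order. Every segment of a record has the same length `L_EEG`; segments
#' are the unit of observation downstream.
#'
#' @param record An [eeg_record()].
#' @param L_EEG Segment length in samples. Values outside the 150-1000
#'   protocol range are allowed but flagged with a warning.
#' @param n_segments Number of segments to return, or `NULL` for all full
#'   segments.
#' @param offset Sample offset (0-based) at which segmentation starts.
#' @return List of `eeg_segment` objects.
#' @export
segment_record <- function(record, L_EEG, n_segments = NULL, offset = 0) {
  if (L_EEG < 1) abort_invalid("L_EEG must be positive")
  if (L_EEG < 150 || L_EEG > 1000)
    warning(sprintf("L_EEG = %d is outside the 150-1000 sample protocol range", L_EEG))
  n <- ncol(record$data) - offset
  avail <- n %/% L_EEG
  if (is.null(n_segments)) n_segments <- avail
  if (avail < n_segments)
    stop(errorCondition(sprintf(
      "record %s: %d usable samples give only %d full segments of %d; %d more sample(s) needed for %d segments",
      record$subject_id, n, avail, L_EEG,
      n_segments * L_EEG - n, n_segments),
      class = c("eegentropy_shortage", "error")))
  lapply(seq_len(n_segments) - 1L, function(k) {
    cols <- offset + k * L_EEG + seq_len(L_EEG)
    structure(list(subject_id = record$subject_id, label = record$label,
                   channel_data = record$data[, cols, drop = FALSE],
                   L_EEG = L_EEG, segment_index = k,
                   channel_names = record$channel_names, fs = record$fs),
              class = "eeg_segment")
  })
}

#' Reject segments containing over-threshold samples
#'
#' A segment is rejected iff any sample on any channel strictly exceeds the
#' threshold in magnitude (`|x| > threshold_uV`); a sample at exactly the
#' threshold is kept. Kept segments preserve their order and original
#' segment indices.
#'
#' @param segments List of segments from [segment_record()].
#' @param threshold_uV Amplitude threshold in microvolts (default 85).
#' @return List with `kept` (the surviving segments) and `rejected_count`.
#' @export
reject_artifacts <- function(segments, threshold_uV = 85) {
  if (threshold_uV <= 0 && !is.infinite(threshold_uV))
    if (threshold_uV < 0) abort_invalid("threshold_uV must be positive")
  bad <- vapply(segments, function(s) any(abs(s$channel_data) > threshold_uV),
                logical(1))
  list(kept = segments[!bad], rejected_count = sum(bad))
}

#' Preprocess a record into analysis-ready segments
#'
#' The fixed pipeline order is filter, segment, reject: zero-phase
#' Butterworth band-pass, contiguous segmentation from the record start,
#' then whole-segment amplitude-threshold rejection. The first `n_segments`
#' surviving segments are returned; a shortage error names the deficit.
#'
#' @param record An [eeg_record()].
#' @param L_EEG Segment length in samples.
#' @param n_segments Segments to keep per record.
#' @param low_hz,high_hz,order Filter settings (see [bandpass_filter()]).
#' @param threshold_uV Artifact threshold; `Inf` disables rejection.
#' @param edge_settle_s Seconds discarded at the record start before
#'   segmentation, skipping the zero-phase filter's warm-up transient
#'   (default 1 s).
#' @param artifact_mode `"reject_segment"` drops over-threshold segments;
#'   `"clip"` instead clamps samples to the threshold and keeps all segments.
#' @return List of segments, length `n_segments`.
#' @export
preprocess_record <- function(record, L_EEG = 1000, n_segments = 5,
                              low_hz = 0.5, high_hz = 32, order = 5,
                              threshold_uV = 85,
                              artifact_mode = c("reject_segment", "clip"),
                              edge_settle_s = 1) {
  artifact_mode <- match.arg(artifact_mode)
  rec <- bandpass_filter(record, low_hz, high_hz, order)
  offset <- round(edge_settle_s * record$fs)
  segs <- segment_record(rec, L_EEG, offset = offset)  # all available, then filter down
  if (artifact_mode == "clip") {
    segs <- lapply(segs, function(s) {
      s$channel_data[s$channel_data > threshold_uV] <- threshold_uV
      s$channel_data[s$channel_data < -threshold_uV] <- -threshold_uV
      s
    })
    kept <- segs
  } else {
    kept <- reject_artifacts(segs, threshold_uV)$kept
  }
  if (length(kept) < n_segments)
    stop(errorCondition(sprintf(
      "record %s: only %d of %d segments usable after artifact rejection (%d needed)",
      record$subject_id, length(kept), length(segs), n_segments),
      class = c("eegentropy_shortage", "error")))
  kept[seq_len(n_segments)]
}

#' Preprocess a whole cohort
#'
#' Applies [preprocess_record()] to each record and concatenates the
#' resulting segments.
#'
#' @param records List of [eeg_record()]s.
#' @param ... Passed to [preprocess_record()].
#' @return Flat list of segments.
#' @export
preprocess_cohort <- function(records, ...) {
  do.call(c, lapply(records, preprocess_record, ...))
}
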