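# Entropy-trajectory monitoring: track a single (channel, variant, config)
# entropy feature for one subject across visits against labelled reference
# distributions. The direction flag marks change between visits; it is an
# indicator for review, explicitly not a diagnosis.

#' Monitor a subject's entropy trajectory against class references
#'
#' For each visit record, the chosen feature's entropy is averaged over the
#' visit's segments. Reference histograms for each class are computed on
#' shared equal-width bins spanning the pooled reference range (bin count by
#' Sturges' rule), so class histograms are directly overlayable.
#'
#' @param record_stream List of [eeg_record()]s for one subject, in visit
#'   order.
#' @param channel,variant Feature coordinates (e.g. `"T8"`, `"cA3"`).
#' @param config An [entropy_config()] (default: the FuzzyEn setting used
#'   throughout the classification pipeline).
#' @param references A [feature_matrix()] containing the same feature for a
#'   labelled cohort (e.g. built by [build_features()]).
#' @param L_EEG,n_segments,... Preprocessing settings per visit; passed to
#'   [preprocess_record()].
#' @return List with `trajectory` (per-visit mean entropy), `direction`
#'   (`"increase"`, `"decrease"` or `"no change"` vs the previous visit),
#'   `bin_edges`, and `reference_hist` (per-class counts on the shared
#'   bins).
#' @export
monitor_subject <- function(record_stream, channel, variant,
                            config = entropy_config("FuzzyEn", m = 1, r = 0.15,
                                                    r2 = 5),
                            references, L_EEG = 1000, n_segments = 5, ...) {
  fname <- feature_name(channel, variant, config)
  if (!fname %in% references$feature_names)
    stop(errorCondition(sprintf("feature %s not present in references", fname),
                        class = c("eegentropy_key_error", "error")))
  ref_vals <- references$values[, fname]
  ref_labels <- references$labels
  trajectory <- vapply(record_stream, function(rec) {
    segs <- preprocess_record(rec, L_EEG = L_EEG, n_segments = n_segments, ...)
    fmv <- build_features(segs, config, channels = channel, variants = variant)
    mean(fmv$values[, 1])
  }, numeric(1))
  pooled <- c(ref_vals, trajectory)
  n_bins <- max(1L, ceiling(log2(length(ref_vals)) + 1))   # Sturges
  edges <- seq(min(pooled), max(pooled), length.out = n_bins + 1)
  if (edges[1] == edges[length(edges)])
    edges <- edges + seq(0, 1e-9, length.out = length(edges))
  hist_counts <- lapply(split(ref_vals, ref_labels), function(v) {
    idx <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
                n_bins)
    tabulate(idx, nbins = n_bins)
  })
  direction <- if (length(trajectory) < 2) character(0) else {
    d <- diff(trajectory)
    ifelse(d > 0, "increase", ifelse(d < 0, "decrease", "no change"))
  }
  list(feature = fname, trajectory = trajectory, direction = direction,
       bin_edges = edges, reference_hist = hist_counts,
       note = "direction flags indicate entropy change between visits, not a diagnosis")
}
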