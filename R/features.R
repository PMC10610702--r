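# Feature assembly: segments x (channel x variant x entropy-config) with
# stable provenance-bearing names "channel|variant|method|params".

feature_name <- function(channel, variant, cfg) {
  ps <- config_param_string(cfg)
  if (nzchar(ps)) paste(channel, variant, cfg$method, ps, sep = "|")
  else paste(channel, variant, cfg$method, sep = "|")
}

#' Build a per-segment entropy feature matrix
#'
#' For every segment and selected channel, the subband variants are
#' reconstructed from the segment itself (segment-local DWT), and each
#' requested entropy configuration is evaluated on each selected variant.
#' Row order follows the input segment order; column order is channel-major,
#' then variant, then configuration, and is fixed. Missing values (an
#' undefined sample entropy) abort assembly with an error naming the
#' offending segment, channel and variant rather than being imputed.
#'
#' @param segments List of segments from [preprocess_record()] or
#'   [segment_record()], all with the same `L_EEG`.
#' @param config One [entropy_config()] or a list of them.
#' @param channels Channel subset (default: all channels of the first
#'   segment).
#' @param variants Variant subset (default: all of [variant_names()]).
#' @param wavelet_name,levels DWT settings for variant reconstruction.
#' @return A `feature_matrix` object: numeric matrix `values` with named
#'   columns, plus per-row `labels`, `groups` (subject ids) and
#'   `segment_index`.
#' @export
build_features <- function(segments, config, channels = NULL, variants = NULL,
                           wavelet_name = "db4", levels = 4) {
  if (length(segments) == 0) abort_invalid("no segments supplied")
  configs <- if (inherits(config, "entropy_config")) list(config) else config
  if (length(configs) == 0) abort_invalid("no entropy configuration supplied")
  L <- unique(vapply(segments, function(s) s$L_EEG, numeric(1)))
  if (length(L) != 1) abort_invalid("all segments must share the same L_EEG")
  seg_channels <- segments[[1]]$channel_names
  if (is.null(channels)) channels <- seg_channels
  if (length(channels) == 0 || !all(channels %in% seg_channels))
    abort_invalid("channels must be a non-empty subset of the segment channels")
  if (is.null(variants)) variants <- variant_names()
  if (length(variants) == 0 || !all(variants %in% variant_names()))
    abort_invalid("variants must be a non-empty subset of the 9 variant names")
  cols <- as.vector(vapply(channels, function(ch)
    vapply(variants, function(v)
      vapply(configs, function(cfg) feature_name(ch, v, cfg), character(1)),
      character(length(configs))),
    character(length(variants) * length(configs))))
  values <- matrix(NA_real_, nrow = length(segments), ncol = length(cols),
                   dimnames = list(NULL, cols))
  need_variants <- !identical(variants, "O")
  for (si in seq_along(segments)) {
    seg <- segments[[si]]
    for (ch in channels) {
      x <- seg$channel_data[ch, ]
      vs <- if (need_variants)
        make_variants(x, wavelet_name, levels, fs = seg$fs)$variants
      else list(O = x)
      for (v in variants) {
        for (cfg in configs) {
          val <- withCallingHandlers(
            compute_entropy(vs[[v]], cfg),
            eegentropy_undefined_entropy = function(w) invokeRestart("muffleWarning"))
          if (is.na(val))
            stop(errorCondition(sprintf(
              "feature assembly failed: %s undefined on segment %d (subject %s), channel %s, variant %s",
              cfg$method, si, seg$subject_id, ch, v),
              class = c("eegentropy_assembly_error", "error")))
          values[si, feature_name(ch, v, cfg)] <- val
        }
      }
    }
  }
  feature_matrix(values,
                 labels = vapply(segments, function(s) s$label, character(1)),
                 groups = vapply(segments, function(s) s$subject_id, character(1)),
                 segment_index = vapply(segments, function(s) s$segment_index,
                                        numeric(1)))
}

#' Construct a feature matrix object
#'
#' @param values Numeric matrix with feature names as column names.
#' @param labels Per-row class labels.
#' @param groups Per-row subject identifiers (used for subject-level CV).
#' @param segment_index Per-row segment position within its subject.
#' @return A `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, groups = NULL, segment_index = NULL) {
  if (is.null(colnames(values))) abort_invalid("values must have column names")
  if (nrow(values) != length(labels))
    abort_invalid("labels must have one entry per row of values")
  structure(list(values = values, feature_names = colnames(values),
                 labels = as.character(labels),
                 groups = if (is.null(groups)) rep(NA_character_, nrow(values))
                          else as.character(groups),
                 segment_index = if (is.null(segment_index))
                   rep(NA_real_, nrow(values)) else segment_index),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d segments x %d features; classes: %s\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Select named feature columns
#'
#' @param fm A [feature_matrix()].
#' @param names Feature names to keep, in the requested order.
#' @return The column-subset feature matrix (rows, labels, groups
#'   unchanged).
#' @export
select_columns <- function(fm, names) {
  if (length(names) == 0) abort_invalid("names must be non-empty")
  missing <- setdiff(names, fm$feature_names)
  if (length(missing) > 0) {
    near <- unlist(lapply(missing, function(nm) {
      d <- utils::adist(nm, fm$feature_names)
      fm$feature_names[order(d)[seq_len(min(3, length(fm$feature_names)))]]
    }))
    stop(errorCondition(sprintf("unknown feature name(s): %s; near matches: %s",
                                paste(missing, collapse = ", "),
                                paste(unique(near), collapse = ", ")),
         class = c("eegentropy_key_error", "error")))
  }
  feature_matrix(fm$values[, names, drop = FALSE], fm$labels, fm$groups,
                 fm$segment_index)
}

#' Write / read a feature matrix as CSV
#'
#' The CSV has one row per segment: the feature columns (header = feature
#' names) followed by `label`, `subject` and `segment`. A JSON sidecar
#' stores the pipeline configuration hash.
#'
#' @param fm A [feature_matrix()].
#' @param path CSV output path.
#' @param config_hash Optional hash string recorded in the sidecar.
#' @return `path`, invisibly (writer); a [feature_matrix()] (reader).
#' @export
write_feature_csv <- function(fm, path, config_hash = NULL) {
  df <- as.data.frame(fm$values, check.names = FALSE)
  df$label <- fm$labels
  df$subject <- fm$groups
  df$segment <- fm$segment_index
  write.csv(df, path, row.names = FALSE)
  meta <- list(n_segments = nrow(fm$values), n_features = ncol(fm$values),
               config_hash = config_hash)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta_cols <- c("label", "subject", "segment")
  feat <- setdiff(colnames(df), meta_cols)
  feature_matrix(as.matrix(df[, feat, drop = FALSE]),
                 labels = df$label, groups = df$subject,
                 segment_index = df$segment)
}
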