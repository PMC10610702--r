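# Experiment orchestration: the per-method hyperparameter sweep, the
# per-variant and per-channel analyses, the single-feature grid, and the
# segment-length study. Every experiment is a pure function of (segments,
# config, seeds) and embeds a configuration hash in its report.

config_hash <- function(...) digest::digest(list(...), algo = "xxhash64")

experiment_report <- function(experiment_id, axis, results, seeds, hash) {
  structure(list(experiment_id = experiment_id, axis = axis,
                 results = results, seeds = seeds, config_hash = hash),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %s (axis: %s), %d result rows\n",
              x$experiment_id, x$axis, nrow(x$results)))
  invisible(x)
}

#' Write an experiment report as JSON (+ CSV of the result rows)
#'
#' Output is deterministic for fixed inputs and seeds, so reruns are
#' byte-identical.
#'
#' @param report An `experiment_report`.
#' @param json_path JSON output path.
#' @param csv_path Optional CSV path for the result table.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, csv_path = NULL) {
  jsonlite::write_json(
    list(experiment_id = report$experiment_id, axis = report$axis,
         results = report$results, seeds = report$seeds,
         config_hash = report$config_hash),
    json_path, auto_unbox = TRUE, null = "null", digits = NA, dataframe = "rows")
  if (!is.null(csv_path)) write.csv(report$results, csv_path, row.names = FALSE)
  invisible(json_path)
}

arkf_for <- function(fm, hyperparams, protocol) {
  stage2_arkf(fm, hyperparams, protocol)$A_RKF
}

#' Sweep entropy hyperparameter grids against classification accuracy
#'
#' For each method and each point of its hyperparameter grid, builds the
#' full channels-by-variants feature matrix from the supplied segments and
#' computes A_RKF with the given (or stage-1-selected) classifier settings.
#'
#' @param segments Preprocessed segments.
#' @param methods Entropy method names (default: all seven).
#' @param protocol A [cv_protocol()].
#' @param hyperparams Fixed classifier settings; if `NULL`, stage 1 runs per
#'   configuration (much slower).
#' @param grids Optional named list overriding [entropy_grid()] per method
#'   (e.g. restricted grids for quick looks).
#' @return An `experiment_report` whose rows are (method, params, A_RKF),
#'   plus a `best` attribute with the per-method argmax.
#' @export
run_hyperparameter_sweep <- function(segments, methods = ENTROPY_METHODS,
                                     protocol = cv_protocol(),
                                     hyperparams = list(kernel = "linear", C = 1,
                                                        gamma = NA),
                                     grids = NULL) {
  rows <- list()
  for (method in methods) {
    grid <- if (!is.null(grids) && method %in% names(grids)) grids[[method]]
            else entropy_grid(method)
    for (cfg in grid) {
      fm <- build_features(segments, cfg)
      hp <- if (is.null(hyperparams)) stage1_select(fm, protocol = protocol)
            else hyperparams
      rows[[length(rows) + 1]] <- data.frame(
        method = method, params = config_param_string(cfg),
        n_features = ncol(fm$values),
        A_RKF = arkf_for(fm, hp, protocol), stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  best <- do.call(rbind, lapply(split(results, results$method), function(d)
    d[which.max(d$A_RKF), ]))
  rep <- experiment_report(
    "hyperparameter_sweep", "entropy config", results,
    seeds = c(protocol$seed_stage1, protocol$seed_stage2),
    hash = config_hash("sweep", methods, protocol, hyperparams))
  rep$best <- best
  rep
}

#' Classification accuracy per signal variant
#'
#' One variant at a time, all channels (14 features per row with the full
#' montage).
#'
#' @param segments Preprocessed segments.
#' @param config A single [entropy_config()].
#' @param protocol,hyperparams As in [run_hyperparameter_sweep()].
#' @param fm Optional prebuilt full feature matrix for `config` (avoids
#'   recomputing it when several experiments share one cohort).
#' @return An `experiment_report` with one row per variant.
#' @export
run_variant_analysis <- function(segments, config, protocol = cv_protocol(),
                                 hyperparams = list(kernel = "linear", C = 1,
                                                    gamma = NA), fm = NULL) {
  if (is.null(fm)) fm <- build_features(segments, config)
  channels <- segments[[1]]$channel_names
  rows <- lapply(variant_names(), function(v) {
    cols <- vapply(channels, function(ch) feature_name(ch, v, config),
                   character(1))
    sub <- select_columns(fm, cols)
    data.frame(variant = v, n_features = ncol(sub$values),
               A_RKF = arkf_for(sub, hyperparams, protocol),
               stringsAsFactors = FALSE)
  })
  experiment_report("variant_analysis", "signal variant", do.call(rbind, rows),
                    seeds = c(protocol$seed_stage1, protocol$seed_stage2),
                    hash = config_hash("variant", config, protocol, hyperparams))
}

#' Classification accuracy per channel
#'
#' One channel at a time, all 9 variants (9 features per row).
#'
#' @inheritParams run_variant_analysis
#' @return An `experiment_report` with one row per channel.
#' @export
run_channel_analysis <- function(segments, config, protocol = cv_protocol(),
                                 hyperparams = list(kernel = "linear", C = 1,
                                                    gamma = NA), fm = NULL) {
  if (is.null(fm)) fm <- build_features(segments, config)
  channels <- segments[[1]]$channel_names
  rows <- lapply(channels, function(ch) {
    cols <- vapply(variant_names(), function(v) feature_name(ch, v, config),
                   character(1))
    sub <- select_columns(fm, cols)
    data.frame(channel = ch, n_features = ncol(sub$values),
               A_RKF = arkf_for(sub, hyperparams, protocol),
               stringsAsFactors = FALSE)
  })
  experiment_report("channel_analysis", "channel", do.call(rbind, rows),
                    seeds = c(protocol$seed_stage1, protocol$seed_stage2),
                    hash = config_hash("channel", config, protocol, hyperparams))
}

#' Single-feature accuracy grid
#'
#' A_RKF for every (channel, variant) pair on its own, with a top table
#' sorted by accuracy and per-variant mean accuracies.
#'
#' @inheritParams run_variant_analysis
#' @param top_n Rows of the leaderboard table (default 15).
#' @param fm Optional prebuilt feature matrix (see [run_variant_analysis()]).
#' @return An `experiment_report`; `results` has 126 rows with the full
#'   montage, plus attributes `top_table` and `variant_means`.
#' @export
run_single_feature_grid <- function(segments, config, protocol = cv_protocol(),
                                    hyperparams = list(kernel = "linear", C = 1,
                                                       gamma = NA),
                                    top_n = 15, fm = NULL) {
  if (is.null(fm)) fm <- build_features(segments, config)
  channels <- segments[[1]]$channel_names
  rows <- list()
  for (ch in channels) for (v in variant_names()) {
    sub <- select_columns(fm, feature_name(ch, v, config))
    rows[[length(rows) + 1]] <- data.frame(
      channel = ch, variant = v,
      A_RKF = arkf_for(sub, hyperparams, protocol), stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  rep <- experiment_report(
    "single_feature_grid", "single feature", results,
    seeds = c(protocol$seed_stage1, protocol$seed_stage2),
    hash = config_hash("single", config, protocol, hyperparams))
  rep$top_table <- head(results[order(-results$A_RKF), ], top_n)
  rep$variant_means <- vapply(split(results$A_RKF, results$variant), mean,
                              numeric(1))
  rep
}

#' Accuracy as a function of segment length
#'
#' Re-segments the raw records at each requested length, rebuilds features,
#' and evaluates each feature set on identical partitions (paired design:
#' the same protocol seeds are used for every length and set).
#'
#' @param records Raw [eeg_record()]s (the study re-runs preprocessing).
#' @param feature_sets Named list: each element is a character vector of
#'   feature names, or `NULL` for all features.
#' @param lengths Segment lengths in samples.
#' @param config A single [entropy_config()].
#' @param protocol,hyperparams As elsewhere.
#' @param n_segments Segments per record at each length.
#' @param ... Passed to [preprocess_record()].
#' @return An `experiment_report` with one row per (length, feature set).
#' @export
run_segment_length_study <- function(records, feature_sets = list(all = NULL),
                                     lengths = c(150, 500, 800, 1000),
                                     config = entropy_config("FuzzyEn", m = 1,
                                                             r = 0.15, r2 = 5),
                                     protocol = cv_protocol(),
                                     hyperparams = list(kernel = "linear", C = 1,
                                                        gamma = NA),
                                     n_segments = 5, ...) {
  rows <- list()
  for (L in lengths) {
    segments <- preprocess_cohort(records, L_EEG = L, n_segments = n_segments,
                                  ...)
    fm <- build_features(segments, config)
    for (set_name in names(feature_sets)) {
      set <- feature_sets[[set_name]]
      sub <- if (is.null(set)) fm else select_columns(fm, set)
      rows[[length(rows) + 1]] <- data.frame(
        L_EEG = L, feature_set = set_name, n_features = ncol(sub$values),
        A_RKF = arkf_for(sub, hyperparams, protocol), stringsAsFactors = FALSE)
    }
  }
  experiment_report("segment_length_study", "L_EEG", do.call(rbind, rows),
                    seeds = c(protocol$seed_stage1, protocol$seed_stage2),
                    hash = config_hash("seglen", feature_sets, lengths, config,
                                       protocol, hyperparams))
}
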