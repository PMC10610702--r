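# Cohort interchange: one CSV per subject (rows = samples, columns =
# channels, header of channel names) plus a JSON sidecar with label,
# sampling rate and seed provenance.

#' Write / read a cohort as per-subject CSV files
#'
#' @param records List of [eeg_record()]s.
#' @param dir Output directory (created if missing).
#' @param seeds Optional per-record seeds recorded in the sidecars.
#' @return Invisibly, the written file paths (writer); a list of
#'   [eeg_record()]s in file order (reader).
#' @export
write_cohort_csv <- function(records, dir, seeds = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    path <- file.path(dir, paste0(rec$subject_id, ".csv"))
    df <- as.data.frame(t(rec$data))
    colnames(df) <- rec$channel_names
    write.csv(df, path, row.names = FALSE)
    jsonlite::write_json(
      list(subject_id = rec$subject_id, label = rec$label, fs = rec$fs,
           seed = if (!is.null(seeds)) seeds[i],
           channel_names = rec$channel_names),
      file.path(dir, paste0(rec$subject_id, ".json")),
      auto_unbox = TRUE, null = "null", digits = NA)
    paths[i] <- path
  }
  invisible(paths)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  lapply(files, function(path) {
    meta_path <- sub("\\.csv$", ".json", path)
    if (!file.exists(meta_path))
      abort_invalid(sprintf("missing metadata sidecar for %s", path))
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    df <- read.csv(path, check.names = FALSE)
    eeg_record(t(as.matrix(df)), fs = meta$fs, subject_id = meta$subject_id,
               label = if (is.null(meta$label)) NA_character_ else meta$label,
               channel_names = colnames(df))
  })
}
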