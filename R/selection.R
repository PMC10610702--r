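# Greedy forward feature selection over the repeated K-fold accuracy
# criterion: step 1 keeps the single best feature; each later step tries
# every remaining feature appended to the current set and keeps the argmax.
# The search itself runs at a reduced repeat count for tractability; the
# reported curve can be re-evaluated at the full protocol afterwards.

#' Greedy forward feature selection on A_RKF
#'
#' @param fm A [feature_matrix()].
#' @param protocol A [cv_protocol()]; its `N_stage2` is the *final*
#'   evaluation budget.
#' @param hyperparams Fixed classifier hyperparameters (reused at every
#'   step; see [stage1_select()]).
#' @param max_k Maximum number of features to select.
#' @param search_N Stage-2 repeats used inside the search (default 5); the
#'   returned curve is re-evaluated at `protocol$N_stage2` when
#'   `re_evaluate` is `TRUE`.
#' @param re_evaluate Re-score each selected prefix at the full protocol.
#' @return A `selection_trace`: data frame `steps` with `feature`,
#'   `A_RKF` (search values) and, if re-evaluated, `A_RKF_full`.
#' @export
greedy_forward <- function(fm, protocol = cv_protocol(), hyperparams,
                           max_k = 10, search_N = 5, re_evaluate = TRUE) {
  stopifnot(max_k >= 1)
  if (max_k > length(fm$feature_names))
    abort_invalid("max_k exceeds the number of available features")
  search_protocol <- protocol
  search_protocol$N_stage2 <- search_N
  selected <- character(0)
  arkf <- numeric(0)
  remaining <- fm$feature_names
  for (step in seq_len(max_k)) {
    cand_acc <- vapply(remaining, function(f) {
      sub <- select_columns(fm, c(selected, f))
      stage2_arkf(sub, hyperparams, search_protocol)$A_RKF
    }, numeric(1))
    top <- names(cand_acc)[cand_acc == max(cand_acc)]
    best <- sort(top)[1]                           # ties: feature-name order
    selected <- c(selected, best)
    arkf <- c(arkf, max(cand_acc))
    remaining <- setdiff(remaining, best)
  }
  steps <- data.frame(step = seq_len(max_k), feature = selected,
                      A_RKF = arkf, stringsAsFactors = FALSE)
  if (re_evaluate)
    steps$A_RKF_full <- vapply(seq_len(max_k), function(k)
      stage2_arkf(select_columns(fm, selected[seq_len(k)]), hyperparams,
                  protocol)$A_RKF, numeric(1))
  structure(list(steps = steps, hyperparams = hyperparams,
                 protocol = protocol, search_N = search_N),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> %d steps; final A_RKF = %.4f\n",
              nrow(x$steps),
              x$steps[[if ("A_RKF_full" %in% names(x$steps)) "A_RKF_full"
                       else "A_RKF"]][nrow(x$steps)]))
  invisible(x)
}

#' Report the smallest feature set within tolerance of full accuracy
#'
#' @param trace A `selection_trace` from [greedy_forward()].
#' @param full_arkf A_RKF of the full feature set (same protocol).
#' @param tol Accuracy tolerance: the report returns the smallest `k` whose
#'   accuracy is at least `full_arkf - tol`.
#' @return List with `best_k`, `features` (the selected names), `arkf_at_k`
#'   and `reached` (`FALSE` when no prefix attains the target; `best_k` is
#'   then the full trace length).
#' @export
reduced_model_report <- function(trace, full_arkf, tol = 0.001) {
  stopifnot(nrow(trace$steps) >= 1)
  acc <- if ("A_RKF_full" %in% names(trace$steps)) trace$steps$A_RKF_full
         else trace$steps$A_RKF
  ok <- which(acc >= full_arkf - tol)
  if (length(ok) == 0) {
    list(best_k = nrow(trace$steps),
         features = trace$steps$feature, arkf_at_k = acc[nrow(trace$steps)],
         reached = FALSE)
  } else {
    k <- min(ok)
    list(best_k = k, features = trace$steps$feature[seq_len(k)],
         arkf_at_k = acc[k], reached = TRUE)
  }
}

#' Serialise a selection trace to CSV + JSON summary
#'
#' @param trace A `selection_trace`.
#' @param csv_path Per-step CSV output path.
#' @param json_path Optional JSON summary path.
#' @param config_hash Optional provenance hash.
#' @return `csv_path`, invisibly.
#' @export
write_selection_csv <- function(trace, csv_path, json_path = NULL,
                                config_hash = NULL) {
  write.csv(trace$steps, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(n_steps = nrow(trace$steps),
           features = trace$steps$feature,
           final_A_RKF = trace$steps[[ncol(trace$steps)]][nrow(trace$steps)],
           search_N = trace$search_N, config_hash = config_hash),
      json_path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(csv_path)
}
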