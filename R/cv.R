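# Two-stage repeated stratified K-fold protocol around the SVC.
# Stage 1 selects classifier hyperparameters on N_stage1 x K partitions;
# stage 2 re-estimates accuracy (A_RKF) on N_stage2 fresh partitions from a
# disjoint seed stream. Feature standardisation is fitted on training folds
# only, inside every fold.

#' Define a repeated K-fold evaluation protocol
#'
#' @param K Folds per partition (default 10).
#' @param N_stage1 Partitions used for hyperparameter selection.
#' @param N_stage2 Partitions used for the final accuracy estimate.
#' @param seed_stage1,seed_stage2 Distinct seeds for the two partition
#'   streams.
#' @param split_unit `"segment"` assigns segments to folds independently
#'   (the protocol this package models); `"subject"` keeps all segments of a
#'   subject in one fold, removing within-subject train/validation leakage.
#' @return A `cv_protocol`.
#' @export
cv_protocol <- function(K = 10, N_stage1 = 10, N_stage2 = 30,
                        seed_stage1 = 101L, seed_stage2 = 202L,
                        split_unit = c("segment", "subject")) {
  split_unit <- match.arg(split_unit)
  if (seed_stage1 == seed_stage2)
    abort_invalid("stage-1 and stage-2 seeds must differ (disjoint repeat streams)")
  structure(list(K = K, N_stage1 = N_stage1, N_stage2 = N_stage2,
                 seed_stage1 = as.integer(seed_stage1),
                 seed_stage2 = as.integer(seed_stage2),
                 split_unit = split_unit),
            class = "cv_protocol")
}

#' Default SVC hyperparameter grid
#'
#' Linear kernel with cost `C` in 0.1, 1, 10, 100, and RBF kernel crossed
#' with widths `"scale"`, 0.01, 0.1. Ordered so that stage-1 ties resolve
#' toward the simplest model (linear first, then smallest `C`).
#'
#' @return List of hyperparameter candidate lists.
#' @export
default_svc_grid <- function() {
  grid <- list()
  for (C in c(0.1, 1, 10, 100))
    grid[[length(grid) + 1]] <- list(kernel = "linear", C = C, gamma = NA)
  for (C in c(0.1, 1, 10, 100))
    for (g in list("scale", 0.01, 0.1))
      grid[[length(grid) + 1]] <- list(kernel = "rbf", C = C, gamma = g)
  grid
}

# one repeated family of stratified fold assignments
# returns a list of integer vectors (fold id per row), one per repeat
make_rkf_folds <- function(labels, K, N, seed, groups = NULL,
                           split_unit = "segment") {
  labels <- as.character(labels)
  n <- length(labels)
  withr::with_seed(seed, {
    lapply(seq_len(N), function(rep) {
      fold <- integer(n)
      if (split_unit == "subject") {
        if (is.null(groups) || anyNA(groups))
          abort_invalid("subject-level splitting requires per-row groups")
        subj <- unique(groups)
        slab <- labels[match(subj, groups)]
        sfold <- integer(length(subj))
        for (cl in unique(slab)) {
          idx <- sample(which(slab == cl))
          sfold[idx] <- rep_len(seq_len(K), length(idx))
        }
        fold <- sfold[match(groups, subj)]
      } else {
        for (cl in unique(labels)) {
          idx <- sample(which(labels == cl))
          fold[idx] <- rep_len(seq_len(K), length(idx))
        }
      }
      fold
    })
  })
}

# z-score train columns; apply train statistics to validation rows
fold_standardize <- function(train, valid) {
  mu <- colMeans(train)
  sdev <- apply(train, 2, sd)
  sdev[sdev == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sdev, "/"),
       valid = sweep(sweep(valid, 2, mu), 2, sdev, "/"),
       mu = mu, sd = sdev)
}

# run one repeated-K-fold pass; returns per-fold accuracies (and details)
run_rkf <- function(values, labels, folds, hyper, return_details = FALSE) {
  accs <- numeric(0)
  details <- list()
  for (rep_i in seq_along(folds)) {
    fold <- folds[[rep_i]]
    for (k in sort(unique(fold))) {
      tr <- fold != k
      if (length(unique(labels[tr])) < 2 || !any(!tr))
        stop(errorCondition(
          sprintf("degenerate fold %d in repeat %d: single-class training set",
                  k, rep_i),
          class = c("eegentropy_protocol_error", "error")))
      st <- fold_standardize(values[tr, , drop = FALSE],
                             values[!tr, , drop = FALSE])
      model <- svc_fit(st$train, labels[tr], kernel = hyper$kernel,
                       C = hyper$C,
                       gamma = if (is.null(hyper$gamma) || is.na(hyper$gamma[1]))
                         "scale" else hyper$gamma)
      pred <- predict(model, st$valid)
      accs <- c(accs, mean(pred == labels[!tr]))
      if (return_details)
        details[[length(details) + 1]] <-
          list(repeat_i = rep_i, fold = k, train_mu = st$mu, train_sd = st$sd)
    }
  }
  if (return_details) list(accs = accs, details = details) else list(accs = accs)
}

#' Stage 1: select SVC hyperparameters by repeated K-fold CV
#'
#' Every grid candidate is evaluated on the same `N_stage1 x K` stratified
#' partitions (one shared fold stream), with per-fold z-score feature
#' standardisation fitted on training folds only. The candidate with the
#' highest mean validation accuracy wins; ties resolve to the earliest grid
#' entry, i.e. the simplest model under [default_svc_grid()] ordering.
#'
#' @param fm A [feature_matrix()].
#' @param grid List of hyperparameter candidates.
#' @param protocol A [cv_protocol()].
#' @return The chosen candidate, with its stage-1 mean accuracy attached as
#'   `stage1_acc`.
#' @export
stage1_select <- function(fm, grid = default_svc_grid(),
                          protocol = cv_protocol()) {
  if (length(grid) == 0) abort_invalid("hyperparameter grid must be non-empty")
  check_min_class_size(fm, protocol$K)
  folds <- make_rkf_folds(fm$labels, protocol$K, protocol$N_stage1,
                          protocol$seed_stage1, fm$groups, protocol$split_unit)
  mean_acc <- vapply(grid, function(hyper)
    mean(run_rkf(fm$values, fm$labels, folds, hyper)$accs), numeric(1))
  best <- which.max(mean_acc)   # first maximum: grid order encodes tie-breaks
  chosen <- grid[[best]]
  chosen$stage1_acc <- mean_acc[best]
  chosen
}

check_min_class_size <- function(fm, K) {
  counts <- table(fm$labels)
  if (length(counts) != 2)
    stop(errorCondition("feature matrix must contain exactly two classes",
                        class = c("eegentropy_protocol_error", "error")))
  if (min(counts) < K)
    stop(errorCondition(sprintf(
      "smallest class has %d samples; need at least K = %d per class",
      min(counts), K),
      class = c("eegentropy_protocol_error", "error")))
}

#' Stage 2: estimate A_RKF with fixed hyperparameters
#'
#' Runs `N_stage2` fresh stratified K-fold partitions (seeded independently
#' of stage 1) and reports the mean validation accuracy `A_RKF` and its
#' complement `E_RKF = 1 - A_RKF`.
#'
#' @param fm A [feature_matrix()].
#' @param hyperparams A grid candidate, e.g. from [stage1_select()]. Must be
#'   fixed before seeing stage-2 partitions.
#' @param protocol A [cv_protocol()].
#' @param return_details If `TRUE`, also return per-fold training-fold
#'   standardisation statistics (used by leakage diagnostics).
#' @return A `cv_result` with `A_RKF`, `E_RKF`, `per_repeat_acc`,
#'   `per_fold_acc`, `chosen_hyperparams` and `protocol`.
#' @export
stage2_arkf <- function(fm, hyperparams, protocol = cv_protocol(),
                        return_details = FALSE) {
  check_min_class_size(fm, protocol$K)
  folds <- make_rkf_folds(fm$labels, protocol$K, protocol$N_stage2,
                          protocol$seed_stage2, fm$groups, protocol$split_unit)
  run <- run_rkf(fm$values, fm$labels, folds, hyperparams,
                 return_details = return_details)
  accs <- run$accs
  per_repeat <- colMeans(matrix(accs, ncol = protocol$N_stage2))
  res <- structure(list(A_RKF = mean(accs), E_RKF = 1 - mean(accs),
                        per_repeat_acc = per_repeat, per_fold_acc = accs,
                        chosen_hyperparams = hyperparams, protocol = protocol),
                   class = "cv_result")
  if (return_details) res$details <- run$details
  res
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> A_RKF = %.4f (E_RKF = %.4f) over %d folds; %s kernel, C = %g\n",
              x$A_RKF, x$E_RKF, length(x$per_fold_acc),
              x$chosen_hyperparams$kernel, x$chosen_hyperparams$C))
  invisible(x)
}

#' Serialise a CV result to JSON
#'
#' @param result A `cv_result`.
#' @param path Output path.
#' @param config_hash Optional provenance hash.
#' @return `path`, invisibly.
#' @export
write_cv_json <- function(result, path, config_hash = NULL) {
  out <- list(A_RKF = result$A_RKF, E_RKF = result$E_RKF,
              per_repeat_acc = result$per_repeat_acc,
              chosen_hyperparams = result$chosen_hyperparams[
                c("kernel", "C", "gamma")],
              protocol = unclass(result$protocol),
              config_hash = config_hash)
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
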