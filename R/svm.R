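# Support-vector classifier front-end over the C++ SMO solver. Binary
# classification only; labels are mapped to -1/+1 in sorted order.

rbf_kernel <- function(X, Y = NULL, gamma) {
  if (is.null(Y)) Y <- X
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

resolve_gamma <- function(gamma, X) {
  if (identical(gamma, "scale")) {
    v <- mean(apply(X, 2, function(col) mean((col - mean(col))^2)))
    if (v == 0) v <- 1
    1 / (ncol(X) * v)
  } else as.numeric(gamma)
}

#' Fit a C-support-vector classifier
#'
#' Binary SVC trained by sequential minimal optimisation with second-order
#' working-set selection on a precomputed kernel matrix. `gamma = "scale"`
#' resolves to `1 / (n_features * mean feature variance)` as in common
#' library defaults.
#'
#' @param X Numeric matrix, rows = samples.
#' @param y Two-class label vector.
#' @param kernel `"linear"` or `"rbf"`.
#' @param C Soft-margin cost.
#' @param gamma RBF width, or `"scale"`.
#' @param tol,max_iter Solver controls.
#' @return An `svc_model`.
#' @export
svc_fit <- function(X, y, kernel = c("linear", "rbf"), C = 1, gamma = "scale",
                    tol = 1e-3, max_iter = 20000) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  classes <- sort(unique(as.character(y)))
  if (length(classes) != 2)
    stop(errorCondition("svc_fit requires exactly two classes in y",
                        class = c("eegentropy_protocol_error", "error")))
  yy <- ifelse(as.character(y) == classes[2], 1, -1)
  g <- if (kernel == "rbf") resolve_gamma(gamma, X) else NA_real_
  K <- if (kernel == "linear") tcrossprod(X) else rbf_kernel(X, gamma = g)
  fit <- .smo_train(K, yy, C, tol, max_iter)
  coef <- fit$alpha * yy
  sv <- which(fit$alpha > 1e-12)
  structure(list(kernel = kernel, C = C, gamma = g, classes = classes,
                 X = X[sv, , drop = FALSE], coef = coef[sv], b = fit$b,
                 n_sv = length(sv), iterations = fit$iterations,
                 converged = fit$converged),
            class = "svc_model")
}

#' Predict classes with a fitted SVC
#'
#' @param object An `svc_model`.
#' @param newdata Numeric matrix of samples to classify.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.svc_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  Kp <- if (object$kernel == "linear") tcrossprod(newdata, object$X)
        else rbf_kernel(newdata, object$X, object$gamma)
  dec <- as.vector(Kp %*% object$coef) + object$b
  ifelse(dec >= 0, object$classes[2], object$classes[1])
}
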