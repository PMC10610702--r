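# Seven entropy estimators over lag-embedded template vectors. Heavy O(N^2)
# pair scans (SampEn, FuzzyEn, CoSiEn) run in C++; the rest are vectorised R.
# Degenerate inputs raise classed conditions; an undefined SampEn propagates
# as NA with a warning so feature assembly can fail loudly rather than impute.

embedding_matrix <- function(x, m, delay = 1) {
  n <- length(x)
  rows <- n - (m - 1) * delay
  if (rows < 1)
    abort_invalid(sprintf("series of length %d too short for m = %d, delay = %d",
                          n, m, delay))
  idx <- outer(seq_len(rows), (seq_len(m) - 1) * delay, "+")
  matrix(x[idx], nrow = rows)
}

# population standard deviation (divide by N), used for x-std tolerances
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Singular-value-decomposition entropy
#'
#' Shannon entropy (base 2) of the normalised singular values of the lag
#' embedding matrix, normalised by `log2(m)` to lie in `[0, 1]`. A constant
#' (rank-one) series scores 0; an all-zero series has no defined spectrum
#' and raises a degenerate-input error.
#'
#' @param x Numeric series.
#' @param m Embedding dimension.
#' @param delay Embedding lag in samples.
#' @return Value in `[0, 1]`.
#' @export
svd_entropy <- function(x, m = 3, delay = 1) {
  A <- embedding_matrix(x, m, delay)
  if (nrow(A) < 2) abort_invalid("need at least 2 template vectors")
  lam <- svd(A, nu = 0, nv = 0)$d
  tot <- sum(lam)
  if (tot == 0) abort_degenerate("all-zero series: singular values are all zero")
  p <- lam / tot
  p <- p[p > 0]
  -sum(p * log2(p)) / log2(m)
}

#' Permutation entropy
#'
#' Shannon entropy (base 2) of the empirical distribution of ordinal
#' patterns of the embedded templates, normalised by `log2(m!)`. Ties are
#' broken by stable index order.
#'
#' @inheritParams svd_entropy
#' @return Value in `[0, 1]`.
#' @export
perm_entropy <- function(x, m = 5, delay = 1) {
  A <- embedding_matrix(x, m, delay)
  pat <- apply(A, 1, function(r) paste(order(r), collapse = "."))
  p <- tabulate(factor(pat)) / length(pat)
  p <- p[p > 0]
  -sum(p * log2(p)) / log2(factorial(m))
}

#' Sample entropy
#'
#' `-ln(C(m+1, r) / C(m, r))` where `C(k, r)` is the proportion of ordered
#' template pairs (i != j) whose Chebyshev distance is at most
#' `r = r_factor * sd(x)` (population sd of the full input series). Both
#' proportions use all constructible templates of their length. When either
#' count is zero the entropy is undefined: the function returns `NA` with a
#' warning and downstream assembly treats the feature as missing.
#'
#' @param x Numeric series.
#' @param m Template length.
#' @param r_factor Tolerance as a fraction of the series standard deviation.
#' @return Non-negative value, or `NA` if undefined.
#' @export
samp_entropy <- function(x, m = 2, r_factor = 0.25) {
  n <- length(x)
  if (n < m + 2) abort_invalid(sprintf("need N >= m + 2 (N = %d, m = %d)", n, m))
  r <- r_factor * sd_pop(x)
  cc <- .sampen_counts(x, m, r)
  if (anyNA(cc) || cc[1] == 0 || cc[2] == 0) {
    warning(warningCondition(
      "sample entropy undefined: no template matches at this tolerance",
      class = "eegentropy_undefined_entropy"))
    return(NA_real_)
  }
  -log(cc[2] / cc[1])
}

#' Cosine-similarity entropy
#'
#' Binary Shannon entropy (base 2) of `B(m, r)`, the proportion of ordered
#' template pairs whose angular distance `acos(cosine similarity)/pi` is at
#' most the absolute tolerance `r`. Zero-norm templates are excluded from
#' pairing; fewer than two valid templates is a degenerate input.
#'
#' @param x Numeric series.
#' @param m Template length.
#' @param r Absolute angular tolerance in `[0, 1]`.
#' @return Value in `[0, 1]`.
#' @export
cosi_entropy <- function(x, m = 3, r = 0.05) {
  n <- length(x)
  if (n < m + 1) abort_invalid(sprintf("need N >= m + 1 (N = %d, m = %d)", n, m))
  out <- .cosien_b(x, m, r)
  if (is.na(out[1]))
    abort_degenerate("fewer than 2 non-zero-norm templates")
  b <- out[1]
  if (b <= 0 || b >= 1) return(0)
  -(b * log2(b) + (1 - b) * log2(1 - b))
}

#' Fuzzy entropy
#'
#' `ln(phi^m) - ln(phi^(m+1))` where `phi^k` averages, over ordered template
#' pairs, the fuzzy membership `exp(-d^r2 / r)` of the Chebyshev distance
#' `d` between mean-centred templates, with tolerance
#' `r = r_factor * sd(x)` and membership exponent `r2`. A constant series
#' scores 0 by convention (all centred templates coincide). For `m = 1` an
#' exact fast path is used (centred 2-templates reduce to a one-dimensional
#' problem).
#'
#' @param x Numeric series.
#' @param m Template length.
#' @param r_factor Tolerance as a fraction of the series standard deviation.
#' @param r2 Membership-function exponent.
#' @return Non-negative value.
#' @export
fuzzy_entropy <- function(x, m = 1, r_factor = 0.15, r2 = 5) {
  n <- length(x)
  if (n < m + 2) abort_invalid(sprintf("need N >= m + 2 (N = %d, m = %d)", n, m))
  s <- sd_pop(x)
  if (s == 0) return(0)         # constant series: identical templates
  r <- r_factor * s
  if (r <= 0) abort_degenerate("tolerance r must be positive")
  v <- if (m == 1) .fuzzyen_m1(x, r, r2) else .fuzzyen_direct(x, m, r, r2)
  if (is.na(v)) abort_degenerate("fuzzy entropy undefined: membership mean underflowed")
  v
}

#' Phase entropy
#'
#' Entropy of the angular distribution of the second-order difference plot.
#' Successive differences `Y = diff(x)[-1]`, `W = diff(x)[-last]` give point
#' angles `theta = atan2(Y, W)` mapped to `[0, 2pi)`; the circle is split
#' into `K` equal sectors, each sector accumulates its total angle mass, and
#' the normalised Shannon entropy of the resulting distribution is returned
#' (log base cancels; `0 log 0 = 0`). If every angle is exactly zero the
#' value is defined as 0 with a warning.
#'
#' @param x Numeric series (length at least 4).
#' @param K Number of angular sectors (at least 2).
#' @return Value in `[0, 1]`.
#' @export
phase_entropy <- function(x, K = 6) {
  n <- length(x)
  if (n < 4) abort_invalid("need N >= 4")
  if (K < 2) abort_invalid("need K >= 2")
  d <- diff(x)
  Y <- d[-1]; W <- d[-length(d)]
  theta <- atan2(Y, W) %% (2 * pi)
  sector <- pmin(floor(theta / (2 * pi / K)) + 1, K)
  S <- vapply(seq_len(K), function(i) sum(theta[sector == i]), numeric(1))
  tot <- sum(S)
  if (tot == 0) {
    warning(warningCondition("all slope angles are zero; phase entropy defined as 0",
                             class = "eegentropy_degenerate_value"))
    return(0)
  }
  p <- S / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(K)
}

#' Attention entropy
#'
#' Mean of the Shannon entropies (natural log) of the empirical
#' distributions of intervals between successive local extrema: max-to-max,
#' min-to-min, max-to-next-min and min-to-next-max. Local extrema are strict
#' (`x[i-1] < x[i] > x[i+1]` for a maximum). An empty interval set
#' contributes 0; a series with no local maximum or no local minimum (e.g. a
#' monotone ramp) is a degenerate input.
#'
#' @param x Numeric series.
#' @return Non-negative value.
#' @export
attn_entropy <- function(x) {
  n <- length(x)
  if (n < 3) abort_invalid("need N >= 3")
  core <- 2:(n - 1)
  is_max <- x[core] > x[core - 1] & x[core] > x[core + 1]
  is_min <- x[core] < x[core - 1] & x[core] < x[core + 1]
  pmax_ <- core[is_max]; pmin_ <- core[is_min]
  if (length(pmax_) == 0 || length(pmin_) == 0)
    abort_degenerate("no local extrema: attention entropy undefined for monotone series")
  shannon <- function(v) {
    if (length(v) == 0) return(0)
    p <- tabulate(factor(v)) / length(v)
    p <- p[p > 0]
    -sum(p * log(p))
  }
  cross_intervals <- function(from, to) {
    nxt <- to[findInterval(from, to) + 1L]   # first `to` strictly after `from`
    d <- nxt - from
    d[!is.na(d)]
  }
  mean(c(shannon(diff(pmax_)), shannon(diff(pmin_)),
         shannon(cross_intervals(pmax_, pmin_)),
         shannon(cross_intervals(pmin_, pmax_))))
}

ENTROPY_METHODS <- c("SVDEn", "PermEn", "SampEn", "CoSiEn",
                     "FuzzyEn", "PhaseEn", "AttnEn")

#' Entropy estimator configuration
#'
#' Bundles a method name and its hyperparameters. Parameter meanings:
#' `m` embedding/template order, `delay` lag in samples, `r` tolerance
#' (fraction of the series sd for SampEn/FuzzyEn, absolute angular distance
#' for CoSiEn), `r2` FuzzyEn membership exponent, `K` PhaseEn sector count.
#'
#' @param method One of `"SVDEn"`, `"PermEn"`, `"SampEn"`, `"CoSiEn"`,
#'   `"FuzzyEn"`, `"PhaseEn"`, `"AttnEn"`.
#' @param m,delay,r,r2,K Hyperparameters as applicable to `method`.
#' @return An `entropy_config` object.
#' @export
entropy_config <- function(method, m = NULL, delay = 1, r = NULL,
                           r2 = NULL, K = NULL) {
  if (!method %in% ENTROPY_METHODS)
    abort_invalid(sprintf("unknown entropy method '%s' (known: %s)",
                          method, paste(ENTROPY_METHODS, collapse = ", ")))
  structure(list(method = method, m = m, delay = delay, r = r, r2 = r2, K = K),
            class = "entropy_config")
}

#' @export
print.entropy_config <- function(x, ...) {
  cat(sprintf("<entropy_config> %s %s\n", x$method, config_param_string(x)))
  invisible(x)
}

# compact "m=1,r=0.15,r2=5" parameter string used in feature names
config_param_string <- function(cfg) {
  fmtnum <- function(v) sub("0+$", "", sub("\\.$", "", format(v, trim = TRUE)))
  parts <- switch(cfg$method,
    SVDEn = , PermEn = c(sprintf("m=%d", cfg$m), sprintf("delay=%d", cfg$delay)),
    SampEn = c(sprintf("m=%d", cfg$m), sprintf("r=%s", fmtnum(cfg$r))),
    CoSiEn = c(sprintf("m=%d", cfg$m), sprintf("r=%s", fmtnum(cfg$r))),
    FuzzyEn = c(sprintf("m=%d", cfg$m), sprintf("r=%s", fmtnum(cfg$r)),
                sprintf("r2=%d", cfg$r2)),
    PhaseEn = sprintf("K=%d", cfg$K),
    AttnEn = character(0))
  paste(parts, collapse = ",")
}

#' Evaluate an entropy configuration on a series
#'
#' @param x Numeric series.
#' @param config An [entropy_config()].
#' @return The entropy value.
#' @export
compute_entropy <- function(x, config) {
  switch(config$method,
    SVDEn = svd_entropy(x, config$m, config$delay),
    PermEn = perm_entropy(x, config$m, config$delay),
    SampEn = samp_entropy(x, config$m, config$r),
    CoSiEn = cosi_entropy(x, config$m, config$r),
    FuzzyEn = fuzzy_entropy(x, config$m, config$r, config$r2),
    PhaseEn = phase_entropy(x, config$K),
    AttnEn = attn_entropy(x))
}

#' Hyperparameter grid of an entropy method
#'
#' Full Cartesian grids: SVDEn/PermEn `m = 2..10` at `delay = 1`; SampEn
#' `m = 1..3` with `r = 0.05..0.5 x sd` in steps of 0.05; CoSiEn `m = 2..3`
#' with absolute `r` on the same lattice; FuzzyEn `m = 1..2`, the same `r`
#' lattice, and `r2 = 1..5`; PhaseEn `K = 2..10`; AttnEn a single
#' parameterless configuration.
#'
#' @param method Method name.
#' @return List of [entropy_config()]s.
#' @export
entropy_grid <- function(method) {
  r_lattice <- seq(0.05, 0.5, by = 0.05)
  grid <- switch(method,
    SVDEn = , PermEn = lapply(2:10, function(m) entropy_config(method, m = m)),
    SampEn = {
      g <- expand.grid(m = 1:3, r = r_lattice)
      lapply(seq_len(nrow(g)), function(i)
        entropy_config(method, m = g$m[i], r = g$r[i]))
    },
    CoSiEn = {
      g <- expand.grid(m = 2:3, r = r_lattice)
      lapply(seq_len(nrow(g)), function(i)
        entropy_config(method, m = g$m[i], r = g$r[i]))
    },
    FuzzyEn = {
      g <- expand.grid(m = 1:2, r = r_lattice, r2 = 1:5)
      lapply(seq_len(nrow(g)), function(i)
        entropy_config(method, m = g$m[i], r = g$r[i], r2 = g$r2[i]))
    },
    PhaseEn = lapply(2:10, function(K) entropy_config(method, K = K)),
    AttnEn = list(entropy_config("AttnEn")),
    abort_invalid(sprintf("unknown entropy method '%s'", method)))
  grid
}
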