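# Discrete wavelet transform (analysis/synthesis filter bank) with symmetric
# half-sample signal extension. Hand-rolled: no wavelet package is available
# in the target library. Conventions (downsampling phase, reconstruction
# crop) are pinned by the perfect-reconstruction and additivity tests.

# orthogonal wavelet decomposition low-pass filters
WT_FILTERS <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255092145, 0.22414386804185735,
          0.8365163037378079, 0.48296291314469025),
  db4 = c(-0.010597401784997278, 0.032883011666982945, 0.030841381835986965,
          -0.18703481171888114, -0.02798376941698385, 0.6308807679295904,
          0.7148465705525415, 0.23037781330885523)
)

wt_filters <- function(name) {
  dec_lo <- WT_FILTERS[[name]]
  if (is.null(dec_lo))
    abort_invalid(sprintf("unknown wavelet '%s' (available: %s)", name,
                          paste(names(WT_FILTERS), collapse = ", ")))
  g <- rev(dec_lo)
  dec_hi <- g * (-1)^(seq_along(g) - 1)
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rev(dec_lo), rec_hi = rev(dec_hi), L = length(dec_lo))
}

sym_ext <- function(x, e) {
  n <- length(x)
  left <- rev(x[seq_len(min(e, n))])
  while (length(left) < e) left <- c(rev(x)[seq_len(min(e - length(left), n))], left)
  right <- rev(x[seq(max(1, n - e + 1), n)])
  while (length(right) < e) right <- c(right, x[seq_len(min(e - length(right), n))])
  c(left, x, right)
}

wt_dwt <- function(x, flt) {
  L <- flt$L; n <- length(x)
  ext <- sym_ext(x, L - 1)
  outlen <- (n + L - 1) %/% 2
  idx <- (L + 1) + 2 * (seq_len(outlen) - 1)
  list(cA = .conv_full(ext, flt$dec_lo)[idx],
       cD = .conv_full(ext, flt$dec_hi)[idx])
}

wt_idwt <- function(cA, cD, n_out, flt) {
  L <- flt$L
  up <- function(cf) {
    u <- numeric(2 * length(cf) - 1)
    u[seq(1, length(u), 2)] <- cf
    u
  }
  y <- 0
  if (!is.null(cA)) y <- y + .conv_full(up(cA), flt$rec_lo)
  if (!is.null(cD)) y <- y + .conv_full(up(cD), flt$rec_hi)
  y[(L - 2) + seq_len(n_out)]
}

# multi-level analysis keeping the approximation at every level
wt_wavedec <- function(x, flt, levels) {
  cAs <- vector("list", levels); cDs <- vector("list", levels)
  lens <- integer(levels + 1)
  lens[1] <- length(x)
  cur <- x
  for (k in seq_len(levels)) {
    d <- wt_dwt(cur, flt)
    cAs[[k]] <- d$cA; cDs[[k]] <- d$cD
    cur <- d$cA
    lens[k + 1] <- length(cur)
  }
  list(cA = cAs, cD = cDs, lens = lens)
}

# reconstruct to level 0 from a single coefficient set at level `level`
wt_reconstruct_one <- function(coef, level, kind, lens, flt) {
  cur <- if (kind == "A") wt_idwt(coef, NULL, lens[level], flt)
         else wt_idwt(NULL, coef, lens[level], flt)
  lev <- level - 1
  while (lev >= 1) {
    cur <- wt_idwt(cur, NULL, lens[lev], flt)
    lev <- lev - 1
  }
  cur
}

#' Reconstruct the single-subband signal variants of a series
#'
#' Decomposes `x` with a `levels`-deep DWT and reconstructs, for each level
#' `k`, the signal obtained by keeping only the approximation (`cAk`) or
#' only the detail (`cDk`) coefficients of that level and zeroing everything
#' else. Together with the unchanged original `O` this yields the 9 signal
#' variants (at `levels = 4`) whose nominal bands at `fs = 128` are
#' O (0-64), cA1 (0-32), cA2 (0-16), cA3 (0-8), cA4 (0-4), cD1 (32-64),
#' cD2 (16-32), cD3 (8-16), cD4 (4-8) Hz.
#'
#' By construction `x = cA4 + cD4 + cD3 + cD2 + cD1` and
#' `cAk = cA(k+1) + cD(k+1)` to floating-point accuracy.
#'
#' @param x Numeric series.
#' @param wavelet_name Mother wavelet (default `"db4"`; `"haar"` and
#'   `"db2"` are accepted but the pipeline is validated for db4).
#' @param levels Decomposition depth (default 4).
#' @param fs Sampling rate used only to annotate nominal bands.
#' @return List with `variants` (named list of series, each `length(x)`)
#'   and `nominal_bands` (named list of `c(low, high)` Hz).
#' @export
make_variants <- function(x, wavelet_name = "db4", levels = 4, fs = 128) {
  flt <- wt_filters(wavelet_name)
  min_n <- 2^levels
  if (length(x) < flt$L * 2^(levels - 1))
    abort_invalid(sprintf(
      "series of length %d too short for %d decomposition levels (needs >= %d samples)",
      length(x), levels, flt$L * 2^(levels - 1)))
  dec <- wt_wavedec(x, flt, levels)
  variants <- list(O = x)
  for (k in seq_len(levels)) {
    variants[[paste0("cA", k)]] <-
      wt_reconstruct_one(dec$cA[[k]], k, "A", dec$lens, flt)
    variants[[paste0("cD", k)]] <-
      wt_reconstruct_one(dec$cD[[k]], k, "D", dec$lens, flt)
  }
  nyq <- fs / 2
  bands <- list(O = c(0, nyq))
  for (k in seq_len(levels)) {
    bands[[paste0("cA", k)]] <- c(0, nyq / 2^k)
    bands[[paste0("cD", k)]] <- c(nyq / 2^k, nyq / 2^(k - 1))
  }
  list(variants = variants, nominal_bands = bands)
}

#' Names of the 9 signal variants in canonical order
#' @return Character vector `O, cA1..cA4, cD1..cD4`.
#' @export
variant_names <- function() c("O", paste0("cA", 1:4), paste0("cD", 1:4))
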