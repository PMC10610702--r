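# Independent brute-force reference implementations used as oracles.
# Deliberately written against the formulas directly (explicit matrices,
# full pair enumeration, no code shared with the package internals).

o_embed <- function(x, m, delay = 1) {
  n <- length(x)
  rows <- n - (m - 1) * delay
  A <- matrix(0, rows, m)
  for (i in seq_len(rows)) A[i, ] <- x[i + (seq_len(m) - 1) * delay]
  A
}

o_svd <- function(x, m, delay = 1) {
  A <- o_embed(x, m, delay)
  lam <- svd(A)$d
  lam_bar <- lam / sum(lam)
  lam_bar <- lam_bar[lam_bar > 0]
  -sum(lam_bar * log2(lam_bar)) / log2(m)
}

o_perm <- function(x, m, delay = 1) {
  A <- o_embed(x, m, delay)
  keys <- apply(A, 1, function(r) paste(order(r), collapse = "-"))
  p <- as.vector(table(keys)) / length(keys)
  -sum(p * log2(p)) / log2(factorial(m))
}

# full pairwise Chebyshev distance matrix between template rows
o_cheb_matrix <- function(A) {
  D <- abs(outer(A[, 1], A[, 1], "-"))
  for (k in seq_len(ncol(A))[-1]) D <- pmax(D, abs(outer(A[, k], A[, k], "-")))
  D
}

o_chebyshev_pairs <- function(x, m, r) {
  # proportion of ordered pairs i != j with Chebyshev distance <= r
  A <- o_embed(x, m)
  nt <- nrow(A)
  D <- o_cheb_matrix(A)
  (sum(D <= r) - nt) / (nt * (nt - 1))   # diagonal is zero, always counted
}

o_samp <- function(x, m, r_factor) {
  r <- r_factor * sqrt(mean((x - mean(x))^2))
  cm <- o_chebyshev_pairs(x, m, r)
  cm1 <- o_chebyshev_pairs(x, m + 1, r)
  if (cm == 0 || cm1 == 0) return(NA_real_)
  -log(cm1 / cm)
}

o_fuzzy_phi <- function(x, m, r, r2) {
  A <- o_embed(x, m)
  A <- A - rowMeans(A)                      # mean-centred templates
  nt <- nrow(A)
  D <- o_cheb_matrix(A)
  S <- exp(-(D^r2) / r)
  (sum(S) - nt) / (nt * (nt - 1))   # diagonal distances are 0, membership 1
}

o_fuzzy <- function(x, m, r_factor, r2) {
  r <- r_factor * sqrt(mean((x - mean(x))^2))
  log(o_fuzzy_phi(x, m, r, r2)) - log(o_fuzzy_phi(x, m + 1, r, r2))
}

o_cosi <- function(x, m, r) {
  A <- o_embed(x, m)
  norms <- sqrt(rowSums(A^2))
  A <- A[norms > 0, , drop = FALSE]
  nt <- nrow(A)
  G <- tcrossprod(A)
  nrm <- sqrt(diag(G))
  CS <- G / outer(nrm, nrm)       # keep matrix shape: clamp in place
  CS[CS > 1] <- 1
  CS[CS < -1] <- -1
  hit <- acos(CS) / pi <= r
  b <- (sum(hit) - nt) / (nt * (nt - 1))   # diagonal angle is 0, always a hit
  if (b <= 0 || b >= 1) 0 else -(b * log2(b) + (1 - b) * log2(1 - b))
}

o_phase <- function(x, K) {
  n <- length(x)
  Y <- x[3:n] - x[2:(n - 1)]
  W <- x[2:(n - 1)] - x[1:(n - 2)]
  theta <- atan2(Y, W)
  theta[theta < 0] <- theta[theta < 0] + 2 * pi
  S <- numeric(K)
  for (j in seq_along(theta)) {
    i <- min(K, floor(theta[j] / (2 * pi / K)) + 1)
    S[i] <- S[i] + theta[j]
  }
  if (sum(S) == 0) return(0)
  p <- S / sum(S)
  p <- p[p > 0]
  -sum(p * log(p)) / log(K)
}

o_attn <- function(x) {
  n <- length(x)
  maxima <- c(); minima <- c()
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) maxima <- c(maxima, i)
    if (x[i] < x[i - 1] && x[i] < x[i + 1]) minima <- c(minima, i)
  }
  sh <- function(v) {
    if (length(v) == 0) return(0)
    p <- as.vector(table(v)) / length(v)
    -sum(p * log(p))
  }
  cross <- function(from, to) {
    out <- c()
    for (f in from) {
      nxt <- to[to > f]
      if (length(nxt) > 0) out <- c(out, min(nxt) - f)
    }
    out
  }
  mean(c(sh(diff(maxima)), sh(diff(minima)),
         sh(cross(maxima, minima)), sh(cross(minima, maxima))))
}

# Welch-style periodogram band power fraction oracle
o_band_fraction <- function(x, fs, band) {
  spec <- Mod(fft(x - mean(x)))^2
  n <- length(x)
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  in_band <- half & freqs >= band[1] & freqs < band[2]
  sum(spec[in_band]) / sum(spec[half])
}

# seeded test series generators
gen_gaussian <- function(n, seed) withr::with_seed(seed, rnorm(n))
gen_ar1 <- function(n, seed, phi = 0.7) withr::with_seed(seed, {
  x <- numeric(n)
  x[1] <- rnorm(1)
  for (i in 2:n) x[i] <- phi * x[i - 1] + rnorm(1)
  x
})
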