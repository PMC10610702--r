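# Butterworth IIR design (bilinear transform of the analog prototype) and
# zero-phase filtering. Hand-rolled because no DSP package is available;
# the design path mirrors the standard zpk -> bilinear -> polynomial route
# and is pinned by frequency-response tests.

poly_from_roots <- function(roots) {
  cf <- 1 + 0i
  for (r in roots) cf <- c(cf, 0) - c(0, r * cf)
  cf
}

#' Design a Butterworth filter
#'
#' Digital Butterworth low-pass or band-pass design via the bilinear
#' transform with frequency prewarping, returned as transfer-function
#' coefficients.
#'
#' @param order Filter order (the analog prototype order; a band-pass design
#'   doubles the polynomial order).
#' @param cutoff_hz One edge (low-pass) or `c(low, high)` (band-pass), Hz.
#' @param fs Sampling rate in Hz.
#' @param type `"low"` or `"band"`.
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
butter_design <- function(order, cutoff_hz, fs, type = c("band", "low")) {
  type <- match.arg(type)
  if (order < 1) abort_invalid("order must be at least 1")
  if (any(cutoff_hz <= 0) || any(cutoff_hz >= fs / 2))
    abort_invalid("cutoff frequencies must lie strictly inside (0, fs/2)")
  fs2 <- 2
  warp <- function(f) 2 * fs2 * tan(pi * (2 * f / fs) / fs2)
  k <- order
  p <- exp(1i * pi * (2 * seq_len(k) + k - 1) / (2 * k))  # LHP prototype poles
  if (type == "low") {
    w0 <- warp(cutoff_hz[1])
    p_a <- p * w0
    z_a <- complex(0)
    k_a <- w0^k
  } else {
    if (length(cutoff_hz) != 2 || cutoff_hz[1] >= cutoff_hz[2])
      abort_invalid("band-pass design needs cutoff_hz = c(low, high) with low < high")
    w1 <- warp(cutoff_hz[1]); w2 <- warp(cutoff_hz[2])
    bw <- w2 - w1; w0 <- sqrt(w1 * w2)
    p_lp <- p * bw / 2
    p_a <- c(p_lp + sqrt(p_lp^2 - w0^2), p_lp - sqrt(p_lp^2 - w0^2))
    z_a <- rep(0 + 0i, k)
    k_a <- bw^k
  }
  fs2x <- 2 * fs2
  z_d <- (fs2x + z_a) / (fs2x - z_a)
  p_d <- (fs2x + p_a) / (fs2x - p_a)
  z_d <- c(z_d, rep(-1 + 0i, length(p_a) - length(z_a)))
  k_d <- k_a * Re(prod(fs2x - z_a) / prod(fs2x - p_a))
  list(b = Re(k_d * poly_from_roots(z_d)), a = Re(poly_from_roots(p_d)))
}

#' Filter frequency response magnitude
#'
#' Evaluates `|B(e^{-i w}) / A(e^{-i w})|` analytically at the requested
#' frequencies. Used as an independent oracle on the time-domain filtering
#' path.
#'
#' @param ba List with `b`, `a` from [butter_design()].
#' @param f_hz Frequencies in Hz.
#' @param fs Sampling rate in Hz.
#' @return Magnitude response at `f_hz`.
#' @export
filter_response <- function(ba, f_hz, fs) {
  w <- 2 * pi * f_hz / fs
  ew <- function(cf) vapply(w, function(wi)
    sum(cf * exp(-1i * wi * (seq_along(cf) - 1))), complex(1))
  Mod(ew(ba$b) / ew(ba$a))
}

# steady-state initial conditions for a step of height 1 (lfilter_zi)
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  b <- c(b, numeric(nf - length(b))) / a[1]
  a <- c(a, numeric(nf - length(a))) / a[1]
  if (nf < 2) return(numeric(0))
  companion_t <- rbind(-a[2:nf], cbind(diag(nf - 2), numeric(nf - 2)))
  solve(diag(nf - 1) - t(companion_t), b[2:nf] - a[2:nf] * b[1])
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Applies the filter twice, forwards and backwards, with odd-symmetric edge
#' padding and steady-state initial conditions, so the net phase response is
#' zero and the magnitude response is squared.
#'
#' @param ba List with `b`, `a`.
#' @param x Numeric series.
#' @return Filtered series of the same length.
#' @export
filtfilt_ba <- function(ba, x) {
  b <- ba$b; a <- ba$a
  nf <- max(length(a), length(b))
  padlen <- 3 * nf
  n <- length(x)
  if (n <= padlen)
    abort_invalid(sprintf(
      "input length %d too short for zero-phase filtering (needs > %d samples)",
      n, padlen))
  bb <- c(b, numeric(nf - length(b))) / a[1]
  aa <- c(a, numeric(nf - length(a))) / a[1]
  zi <- lfilter_zi(bb, aa)
  ext <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  y <- .iir_filter(bb, aa, ext, zi * ext[1])
  y <- rev(.iir_filter(bb, aa, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}
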