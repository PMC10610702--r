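#' Define a spectral/irregularity class profile for simulated EEG
#'
#' A class profile states the relative power carried by each of the five
#' conventional EEG bands, how irregular the signal is, and its overall
#' amplitude. Each simulated channel is a weighted sum, per band, of
#' band-limited Gaussian noise (weight `irregularity`) and a narrowband
#' oscillator at the band centre (weight `1 - irregularity`), rescaled so
#' the channel standard deviation equals `amplitude_uV`.
#'
#' @param band_powers Named numeric vector of non-negative relative powers
#'   for `delta`, `theta`, `alpha`, `beta`, `gamma`. Normalised to sum to 1.
#' @param irregularity Fraction in `[0, 1]` of within-band power carried by
#'   broadband noise rather than narrowband oscillation. Higher values give
#'   more entropic signals.
#' @param amplitude_uV Target per-channel standard deviation in microvolts
#'   (default 15, keeping clean signals inside the 85 microvolt artifact
#'   threshold as in typical resting-state recordings).
#' @return An object of class `class_profile`.
#' @export
class_profile <- function(band_powers, irregularity, amplitude_uV = 15) {
  bn <- names(EEG_BANDS)
  if (is.null(names(band_powers)) || !all(bn %in% names(band_powers)))
    abort_invalid(paste("band_powers must be named with:", paste(bn, collapse = ", ")))
  bp <- as.numeric(band_powers[bn])
  if (any(bp < 0) || all(bp == 0))
    abort_invalid("band powers must be non-negative and not all zero")
  if (!is.numeric(irregularity) || irregularity < 0 || irregularity > 1)
    abort_invalid("irregularity must lie in [0, 1]")
  if (!is.numeric(amplitude_uV) || amplitude_uV <= 0)
    abort_invalid("amplitude_uV must be positive")
  structure(list(band_powers = setNames(bp / sum(bp), bn),
                 irregularity = irregularity,
                 amplitude_uV = amplitude_uV),
            class = "class_profile")
}

#' Default normal-control and parkinsonian class profiles
#'
#' The PD-like profile has elevated delta/theta relative power and higher
#' irregularity than the control profile, so that a low-frequency,
#' entropy-detectable class difference is recoverable by the downstream
#' pipeline. These are stated simulation conditions, not claims of clinical
#' realism.
#'
#' @return Named list with `NC` and `PD` `class_profile` objects.
#' @export
default_profiles <- function() {
  list(
    NC = class_profile(c(delta = 0.20, theta = 0.15, alpha = 0.35,
                         beta = 0.20, gamma = 0.10),
                       irregularity = 0.25, amplitude_uV = 15),
    PD = class_profile(c(delta = 0.40, theta = 0.25, alpha = 0.20,
                         beta = 0.10, gamma = 0.05),
                       irregularity = 0.70, amplitude_uV = 15)
  )
}

#' Construct an EEG record object
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param subject_id Identifier string.
#' @param label Class tag (e.g. `"NC"` or `"PD"`).
#' @param channel_names Character vector, one name per row of `data`.
#' @return An `eeg_record` object.
#' @export
eeg_record <- function(data, fs, subject_id = "S01", label = NA_character_,
                       channel_names = NULL) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1)
  if (is.null(channel_names))
    channel_names <- if (nrow(data) == 14) EEG_CHANNELS_14
                     else paste0("CH", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    abort_invalid("data must have exactly length(channel_names) rows")
  if (!is.numeric(fs) || fs <= 0) abort_invalid("fs must be positive")
  rownames(data) <- channel_names
  structure(list(subject_id = subject_id, label = label, data = data,
                 fs = fs, channel_names = channel_names),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %s label=%s: %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$label, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

# one band component: unit-sd band-limited noise or a centred oscillator
band_noise <- function(n, fs, band) {
  x <- rnorm(n)
  lo <- band[1]; hi <- min(band[2], fs / 2 * 0.98)
  ba <- if (lo <= 0) butter_design(4, hi, fs = fs, type = "low")
        else butter_design(4, c(lo, hi), fs = fs, type = "band")
  y <- filtfilt_ba(ba, x)
  s <- sd(y)
  if (s == 0) y else y / s
}

#' Simulate one subject's multichannel resting-state EEG
#'
#' Each channel is built per band as `sqrt(p_b) * (sqrt(irr) * noise_b +
#' sqrt(1 - irr) * osc_b)`, where `noise_b` is 4th-order Butterworth
#' band-limited unit-variance Gaussian noise, and `osc_b` a unit-variance
#' narrowband oscillation at the band centre with a random initial phase and
#' slow Brownian phase drift (about 1 s coherence time). The finite
#' coherence keeps the oscillator narrowband while making segments of one
#' record statistically exchangeable with segments of any other record of
#' the same profile. The channel series is then rescaled to the profile's
#' `amplitude_uV` standard deviation. Fully reproducible from `seed`.
#'
#' @param profile A [class_profile()].
#' @param duration_s Record duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param n_channels Number of channels.
#' @param seed Integer seed.
#' @param subject_id,label Metadata passed to [eeg_record()].
#' @param channel_names Optional channel names.
#' @param channel_profiles Optional named list (channel name -> profile)
#'   overriding `profile` on specific channels, e.g. to inject a class
#'   effect into selected electrodes only.
#' @return An [eeg_record()].
#' @export
generate_subject <- function(profile, duration_s = 300, fs = 128,
                             n_channels = 14, seed = 1L,
                             subject_id = "S01", label = NA_character_,
                             channel_names = NULL, channel_profiles = NULL) {
  if (duration_s <= 0 || fs <= 0 || n_channels <= 0)
    abort_invalid("duration_s, fs and n_channels must all be positive")
  n <- round(duration_s * fs)
  if (n < 2) abort_invalid("duration_s * fs must be at least 2 samples")
  if (is.null(channel_names))
    channel_names <- if (n_channels == 14) EEG_CHANNELS_14
                     else paste0("CH", seq_len(n_channels))
  t <- (seq_len(n) - 1) / fs
  centres <- vapply(EEG_BANDS, function(b) (b[1] + b[2]) / 2, numeric(1))
  data <- withr::with_seed(seed, {
    m <- matrix(0, n_channels, n)
    for (ch in seq_len(n_channels)) {
      prof <- profile
      cn <- channel_names[ch]
      if (!is.null(channel_profiles) && cn %in% names(channel_profiles))
        prof <- channel_profiles[[cn]]
      x <- numeric(n)
      for (b in names(EEG_BANDS)) {
        p <- prof$band_powers[[b]]
        if (p == 0) next
        irr <- prof$irregularity
        comp <- 0
        if (irr > 0) comp <- comp + sqrt(irr) * band_noise(n, fs, EEG_BANDS[[b]])
        if (irr < 1) {
          # narrowband oscillator: random initial phase plus slow Brownian
          # phase drift (~1 s coherence; linewidth << band width). Finite
          # coherence keeps segments of one record statistically
          # exchangeable instead of fingerprinting the subject.
          phase0 <- runif(1, 0, 2 * pi)
          drift <- cumsum(rnorm(n, sd = 1 / sqrt(fs)))
          osc <- sin(2 * pi * centres[[b]] * t + phase0 + drift)
          osc <- osc / sd(osc)
          comp <- comp + sqrt(1 - irr) * osc
        }
        x <- x + sqrt(p) * comp
      }
      s <- sd(x)
      m[ch, ] <- if (s > 0) x * (prof$amplitude_uV / s) else x
    }
    m
  })
  eeg_record(data, fs, subject_id = subject_id, label = label,
             channel_names = channel_names)
}

#' Simulate a labelled two-class cohort
#'
#' Generates `n_per_class` records per label with per-subject seeds derived
#' deterministically from `seed`.
#'
#' @param n_per_class Subjects per class.
#' @param profiles Named list of two [class_profile()]s; names are the class
#'   labels.
#' @param duration_s,fs,seed See [generate_subject()].
#' @param n_channels Channels per record.
#' @param channel_profiles Optional per-label list of channel-profile
#'   overrides (named list label -> (channel -> profile)).
#' @return List of [eeg_record()]s, interleaved by class.
#' @export
generate_cohort <- function(n_per_class, profiles = default_profiles(),
                            duration_s = 300, fs = 128, seed = 1L,
                            n_channels = 14, channel_profiles = NULL) {
  if (n_per_class < 1) abort_invalid("n_per_class must be at least 1")
  labels <- names(profiles)
  if (length(labels) != 2 || anyDuplicated(labels))
    abort_invalid("profiles must be a named list with two distinct labels")
  records <- list()
  k <- 0
  for (i in seq_len(n_per_class)) {
    for (lab in labels) {
      k <- k + 1
      records[[k]] <- generate_subject(
        profiles[[lab]], duration_s = duration_s, fs = fs,
        n_channels = n_channels, seed = derive_seed(seed, k),
        subject_id = sprintf("%s%02d", lab, i), label = lab,
        channel_profiles = if (!is.null(channel_profiles)) channel_profiles[[lab]])
    }
  }
  records
}

#' Inject transient high-amplitude artifacts into a record
#'
#' Adds short (0.2 s) raised-cosine pulses of magnitude `peak_uV` and random
#' sign at Poisson-distributed times on random channels, emulating ocular
#' artifacts for testing amplitude-threshold rejection.
#'
#' @param record An [eeg_record()].
#' @param rate_per_min Expected events per minute (0 leaves the record
#'   unchanged).
#' @param peak_uV Pulse peak amplitude in microvolts.
#' @param seed Integer seed.
#' @return The record with artifacts added.
#' @export
inject_artifacts <- function(record, rate_per_min, peak_uV = 120, seed = 1L) {
  if (peak_uV <= 0) abort_invalid("peak_uV must be positive")
  if (rate_per_min < 0) abort_invalid("rate_per_min must be non-negative")
  if (rate_per_min == 0) return(record)
  n <- ncol(record$data); fs <- record$fs
  width <- max(3L, round(0.2 * fs))          # samples, <= 0.25 s
  half <- width %/% 2
  withr::with_seed(seed, {
    n_events <- rpois(1, rate_per_min * n / fs / 60)
    if (n_events > 0) {
      centres <- sample.int(n, n_events, replace = TRUE)
      chans <- sample.int(nrow(record$data), n_events, replace = TRUE)
      signs <- sample(c(-1, 1), n_events, replace = TRUE)
      for (e in seq_len(n_events)) {
        idx <- (centres[e] - half):(centres[e] + half)
        keep <- idx >= 1 & idx <= n
        tau <- (idx[keep] - centres[e]) / half      # in [-1, 1]
        pulse <- signs[e] * peak_uV * 0.5 * (1 + cos(pi * tau))
        record$data[chans[e], idx[keep]] <-
          record$data[chans[e], idx[keep]] + pulse
      }
    }
  })
  record
}
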