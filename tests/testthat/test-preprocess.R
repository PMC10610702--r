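make_tone <- function(f_hz, fs = 128, n = 2560) sin(2 * pi * f_hz * (0:(n - 1)) / fs)

test_that("band-pass magnitude matches the analytic frequency response", {
  fs <- 128
  ba <- butter_design(5, c(0.5, 32), fs = fs, type = "band")
  rec <- eeg_record(matrix(make_tone(10), nrow = 1), fs)
  out <- bandpass_filter(rec)$data[1, ]
  # central amplitude vs analytic |H|^2 (zero-phase filtering squares it)
  core <- 500:2000
  amp <- max(abs(out[core]))
  expect_equal(amp, filter_response(ba, 10, fs)^2, tolerance = 0.05)
  expect_gt(amp, 0.95)                       # passband: within 5% of unity

  out50 <- bandpass_filter(eeg_record(matrix(make_tone(50), nrow = 1), fs))$data[1, ]
  expect_lt(sqrt(mean(out50[core]^2)) / sqrt(mean(make_tone(50)[core]^2)), 0.10)

  dc <- bandpass_filter(eeg_record(matrix(rep(100, 2560), nrow = 1), fs))$data[1, ]
  expect_lt(sqrt(mean(dc[core]^2)), 1)       # DC removed by the 0.5 Hz edge
})

test_that("filtering twice changes a passband tone by less than 1%", {
  fs <- 128
  rec <- eeg_record(matrix(make_tone(10), nrow = 1), fs)
  once <- bandpass_filter(rec)
  twice <- bandpass_filter(once)
  core <- 500:2000
  a1 <- max(abs(once$data[1, core])); a2 <- max(abs(twice$data[1, core]))
  expect_lt(abs(a2 - a1) / a1, 0.01)
})

test_that("filtering rejects records shorter than the padding requirement", {
  rec <- eeg_record(matrix(rnorm(20), nrow = 1), 128)
  expect_error(bandpass_filter(rec), class = "eegentropy_invalid_argument")
  expect_error(bandpass_filter(eeg_record(matrix(rnorm(500), nrow = 1), 128),
                               low_hz = 40, high_hz = 30),
               class = "eegentropy_invalid_argument")
})

test_that("segmentation is contiguous, exact and errors on shortage", {
  rec <- eeg_record(matrix(seq_len(38400), nrow = 1), 128)
  segs <- segment_record(rec, 1000, 5)
  expect_length(segs, 5)
  expect_equal(vapply(segs, function(s) s$segment_index, numeric(1)), 0:4)
  # concatenation identity over the first n*L samples
  expect_equal(as.vector(do.call(cbind, lapply(segs, function(s) s$channel_data))),
               1:5000, ignore_attr = TRUE)
  segs150 <- segment_record(rec, 150, 5)
  expect_equal(vapply(segs150, function(s) s$channel_data[1, 1], numeric(1)),
               c(0, 150, 300, 450, 600) + 1)
  short <- eeg_record(matrix(seq_len(4999), nrow = 1), 128)
  err <- tryCatch(segment_record(short, 1000, 5), condition = identity)
  expect_s3_class(err, "eegentropy_shortage")
  expect_match(conditionMessage(err), "1 more sample")
  expect_warning(segment_record(rec, 100, 2), "protocol range")
})

test_that("artifact rejection uses a strict threshold at segment level", {
  base <- matrix(0, 2, 300)
  rec <- eeg_record(base, 128, subject_id = "A")
  rec$data[2, 450 - 300] <- 0    # keep dims clear
  spike <- rec; spike$data[1, 100] <- 100
  segs <- suppressWarnings(segment_record(spike, 100, 3))
  out <- reject_artifacts(segs, 85)
  expect_equal(out$rejected_count, 1)
  expect_equal(vapply(out$kept, function(s) s$segment_index, numeric(1)), c(1, 2))

  boundary <- rec; boundary$data[1, 50] <- 85
  segs <- suppressWarnings(segment_record(boundary, 100, 3))
  expect_equal(reject_artifacts(segs, 85)$rejected_count, 0)  # 85.0 exactly kept

  zero_segs <- suppressWarnings(segment_record(rec, 100, 3))
  expect_equal(reject_artifacts(zero_segs, 85)$rejected_count, 0)
  # limiting thresholds
  expect_equal(reject_artifacts(segs, Inf)$rejected_count, 0)
  expect_equal(reject_artifacts(segs, 0)$rejected_count, 1)   # any non-zero segment
})

test_that("preprocess_record composes filter, segment, reject deterministically", {
  rec <- generate_subject(default_profiles()$NC, duration_s = 50, seed = 12,
                          label = "NC", subject_id = "NC01")
  segs <- preprocess_record(rec, L_EEG = 1000, n_segments = 5)
  expect_length(segs, 5)
  expect_true(all(vapply(segs, function(s) s$L_EEG == 1000, logical(1))))
  segs2 <- preprocess_record(rec, L_EEG = 1000, n_segments = 5)
  expect_identical(segs, segs2)
  # clip mode keeps all segments but bounds amplitudes
  spiked <- inject_artifacts(rec, rate_per_min = 30, peak_uV = 200, seed = 4)
  clipped <- preprocess_record(spiked, L_EEG = 1000, n_segments = 5,
                               artifact_mode = "clip")
  expect_lte(max(abs(do.call(cbind, lapply(clipped, function(s) s$channel_data)))), 85)
  expect_error(preprocess_record(rec, L_EEG = 1000, n_segments = 7),
               class = "eegentropy_shortage")
})
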