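test_that("generated records have the stated shape, montage and determinism", {
  prof <- default_profiles()$NC
  rec <- generate_subject(prof, duration_s = 10, fs = 128, seed = 5, label = "NC")
  expect_s3_class(rec, "eeg_record")
  expect_equal(dim(rec$data), c(14, 1280))
  expect_equal(rec$channel_names,
               c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1", "O2", "P8", "T8",
                 "FC6", "F4", "F8", "AF4"))
  expect_equal(sd(rec$data["T8", ]), prof$amplitude_uV, tolerance = 1e-6)
  rec2 <- generate_subject(prof, duration_s = 10, fs = 128, seed = 5, label = "NC")
  expect_identical(rec$data, rec2$data)
  rec3 <- generate_subject(prof, duration_s = 10, fs = 128, seed = 6, label = "NC")
  expect_false(identical(rec$data, rec3$data))
  expect_error(generate_subject(prof, duration_s = -1), class = "eegentropy_invalid_argument")
  expect_error(generate_subject(prof, n_channels = 0), class = "eegentropy_invalid_argument")
})

test_that("a pure-delta zero-irregularity profile concentrates spectral power below 4 Hz", {
  prof <- class_profile(c(delta = 1, theta = 0, alpha = 0, beta = 0, gamma = 0),
                        irregularity = 0, amplitude_uV = 15)
  rec <- generate_subject(prof, duration_s = 60, fs = 128, n_channels = 2, seed = 9)
  for (ch in 1:2)
    expect_gte(o_band_fraction(rec$data[ch, ], 128, c(0, 4)), 0.90)
})

test_that("realised band-power fractions track the profile", {
  prof <- default_profiles()$PD
  rec <- generate_subject(prof, duration_s = 300, fs = 128, n_channels = 2, seed = 31)
  for (band in names(eeg_bands())) {
    frac <- o_band_fraction(rec$data[1, ], 128, eeg_bands()[[band]])
    expect_lt(abs(frac - prof$band_powers[[band]]), 0.10)
  }
})

test_that("cohort generation yields n_per_class per label with distinct data", {
  cohort <- generate_cohort(20, duration_s = 2, seed = 3)
  expect_length(cohort, 40)
  labs <- vapply(cohort, function(r) r$label, character(1))
  expect_equal(as.vector(table(labs)), c(20, 20))
  expect_false(identical(cohort[[1]]$data, cohort[[3]]$data))
  # disjoint master seeds give disjoint subject data
  cohort2 <- generate_cohort(2, duration_s = 2, seed = 4)
  expect_false(identical(cohort[[1]]$data, cohort2[[1]]$data))
  expect_error(generate_cohort(0), class = "eegentropy_invalid_argument")
})

test_that("channel-restricted profiles only alter the targeted channels", {
  profs <- default_profiles()
  base <- generate_subject(profs$NC, duration_s = 5, seed = 77)
  mod <- generate_subject(profs$NC, duration_s = 5, seed = 77,
                          channel_profiles = list(P8 = profs$PD, F8 = profs$PD))
  same <- setdiff(base$channel_names, c("P8", "F8"))
  expect_identical(base$data[same, ], mod$data[same, ])
  expect_false(identical(base$data["P8", ], mod$data["P8", ]))
})

test_that("artifact injection is seeded, thresholded and optional", {
  rec <- generate_subject(default_profiles()$NC, duration_s = 60, seed = 2)
  expect_identical(inject_artifacts(rec, rate_per_min = 0), rec)
  art1 <- inject_artifacts(rec, rate_per_min = 6, peak_uV = 120, seed = 8)
  art2 <- inject_artifacts(rec, rate_per_min = 6, peak_uV = 120, seed = 8)
  expect_identical(art1$data, art2$data)
  expect_gt(max(abs(art1$data)), 85)        # peak 120 pulses cross the threshold
  expect_error(inject_artifacts(rec, 1, peak_uV = -5),
               class = "eegentropy_invalid_argument")
})

test_that("CSV cohort round-trips through the writer and reader", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(1, duration_s = 2, seed = 1)
  write_cohort_csv(cohort, dir, seeds = c(11L, 12L))
  back <- read_cohort_csv(dir)
  expect_length(back, 2)
  ids <- vapply(back, function(r) r$subject_id, character(1))
  for (rec in cohort) {
    b <- back[[match(rec$subject_id, ids)]]
    expect_equal(b$data, rec$data, tolerance = 1e-9, ignore_attr = TRUE)
    expect_identical(b$label, rec$label)
    expect_identical(b$channel_names, rec$channel_names)
  }
})

test_that("EDF round-trip preserves signals to quantisation accuracy", {
  path <- withr::local_tempfile(fileext = ".edf")
  rec <- generate_subject(default_profiles()$PD, duration_s = 3, seed = 6,
                          label = "PD", subject_id = "PD01")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_identical(back$channel_names, rec$channel_names)
  expect_identical(back$label, "PD")
  expect_equal(back$fs, 128)
  quant <- 2 * max(1, ceiling(max(abs(rec$data)))) / 65535
  expect_lt(max(abs(back$data - rec$data)), quant)
})
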