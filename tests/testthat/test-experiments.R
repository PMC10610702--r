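# Experiment orchestration on micro cohorts: report shapes, reproducibility,
# and the monitoring contract. Effect-recovery at scale lives in
# test-acceptance.R.

micro_protocol <- function() cv_protocol(N_stage1 = 2, N_stage2 = 2)

test_that("the hyperparameter sweep enumerates grids and is reproducible", {
  segs <- micro_segments()
  grids <- list(FuzzyEn = list(fuzzy_cfg()),
                PhaseEn = entropy_grid("PhaseEn")[1:2])
  rep1 <- run_hyperparameter_sweep(segs, c("AttnEn", "FuzzyEn", "PhaseEn"),
                                   micro_protocol(), grids = grids)
  expect_equal(nrow(rep1$results), 1 + 1 + 2)  # AttnEn has exactly one point
  expect_equal(sum(rep1$results$method == "AttnEn"), 1)
  expect_true(all(rep1$results$n_features == 126))
  rep2 <- run_hyperparameter_sweep(segs, c("AttnEn", "FuzzyEn", "PhaseEn"),
                                   micro_protocol(), grids = grids)
  expect_identical(rep1$results, rep2$results)
  expect_identical(rep1$config_hash, rep2$config_hash)
})

test_that("variant and channel analyses have the documented shapes", {
  segs <- micro_segments()
  fm <- build_features(segs, fuzzy_cfg())
  vrep <- run_variant_analysis(segs, fuzzy_cfg(), micro_protocol(), fm = fm)
  expect_equal(nrow(vrep$results), 9)
  expect_setequal(vrep$results$variant, variant_names())
  expect_true(all(vrep$results$n_features == 14))
  crep <- run_channel_analysis(segs, fuzzy_cfg(), micro_protocol(), fm = fm)
  expect_equal(nrow(crep$results), 14)
  expect_true(all(crep$results$n_features == 9))
})

test_that("the single-feature grid covers 126 cells with a sorted top table", {
  segs <- micro_segments()
  fm <- build_features(segs, fuzzy_cfg())
  rep <- run_single_feature_grid(segs, fuzzy_cfg(), micro_protocol(), fm = fm)
  expect_equal(nrow(rep$results), 126)
  expect_equal(nrow(rep$top_table), 15)
  expect_true(all(diff(rep$top_table$A_RKF) <= 0))
  expect_length(rep$variant_means, 9)
  expect_true(all(rep$results$A_RKF >= 0 & rep$results$A_RKF <= 1))
})

test_that("the segment-length study pairs feature sets on identical partitions", {
  cohort <- micro_cohort()
  cfg <- fuzzy_cfg()
  sets <- list(all = NULL,
               pair = c("T8|cA3|FuzzyEn|m=1,r=0.15,r2=5",
                        "P8|cA4|FuzzyEn|m=1,r=0.15,r2=5"))
  rep <- run_segment_length_study(cohort, sets, lengths = c(500, 1000),
                                  config = cfg, protocol = micro_protocol())
  expect_equal(nrow(rep$results), 4)          # 2 lengths x 2 sets
  expect_equal(sort(unique(rep$results$L_EEG)), c(500, 1000))
  expect_equal(unname(rep$results$n_features[rep$results$feature_set == "pair"]),
               c(2, 2))
})

test_that("experiment reports serialise byte-identically under fixed seeds", {
  segs <- micro_segments()
  fm <- build_features(segs, fuzzy_cfg())
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.json"); p2 <- file.path(dir, "b.json")
  write_report(run_variant_analysis(segs, fuzzy_cfg(), micro_protocol(), fm = fm), p1)
  write_report(run_variant_analysis(segs, fuzzy_cfg(), micro_protocol(), fm = fm), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("monitoring reports shared-bin histograms and change flags", {
  refs <- build_features(micro_segments(), fuzzy_cfg(),
                         channels = "T8", variants = "cA3")
  visit <- micro_cohort()[[1]]
  out <- monitor_subject(list(visit, visit), "T8", "cA3", fuzzy_cfg(), refs,
                         L_EEG = 1000, n_segments = 5)
  expect_length(out$trajectory, 2)
  expect_identical(out$direction, "no change")   # identical visits
  expect_length(out$reference_hist, 2)
  expect_equal(length(out$reference_hist[[1]]), length(out$bin_edges) - 1)
  expect_identical(lengths(out$reference_hist)[[1]],
                   lengths(out$reference_hist)[[2]])  # shared bins across classes
  expect_error(monitor_subject(list(visit), "T8", "cD9", fuzzy_cfg(), refs),
               class = "eegentropy_key_error")
})

test_that("visits morphing toward the disease profile track the disease reference", {
  profs <- default_profiles()
  refs <- build_features(micro_segments(), fuzzy_cfg(),
                         channels = "T8", variants = "cA3")
  # disease direction in feature space, from the labelled references
  fname <- "T8|cA3|FuzzyEn|m=1,r=0.15,r2=5"
  ref_mean <- tapply(refs$values[, fname], refs$labels, mean)
  expected_flag <- if (ref_mean[["PD"]] > ref_mean[["NC"]]) "increase" else "decrease"
  # three visits interpolating the control profile toward the disease profile
  mix <- function(a) class_profile(
    (1 - a) * profs$NC$band_powers + a * profs$PD$band_powers,
    (1 - a) * profs$NC$irregularity + a * profs$PD$irregularity, 15)
  visits <- lapply(c(0, 0.5, 1), function(a)
    generate_subject(mix(a), duration_s = 45, seed = 300 + round(10 * a),
                     label = "NC"))
  out <- monitor_subject(visits, "T8", "cA3", fuzzy_cfg(), refs,
                         L_EEG = 1000, n_segments = 5)
  expect_identical(out$direction, rep(expected_flag, 2))
  # the final visit sits closer to the disease reference than the first
  expect_lt(abs(out$trajectory[3] - ref_mean[["PD"]]),
            abs(out$trajectory[1] - ref_mean[["PD"]]))
})
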