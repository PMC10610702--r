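# Shared micro-fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# tiny two-class cohort: 3 subjects/class, 45 s, separable by design
micro_cohort <- function() fixture("micro_cohort", function()
  generate_cohort(3, default_profiles(), duration_s = 45, fs = 128, seed = 20260917))

micro_segments <- function() fixture("micro_segments", function()
  preprocess_cohort(micro_cohort(), L_EEG = 1000, n_segments = 5))

fuzzy_cfg <- function() entropy_config("FuzzyEn", m = 1, r = 0.15, r2 = 5)

# direct synthetic feature matrix: n_inf informative + n_noise noise features
synth_feature_matrix <- function(n_subjects_per_class = 20, n_segments = 5,
                                 n_inf = 5, n_noise = 121, effect = 2.5,
                                 seed = 1) {
  withr::with_seed(seed, {
    n <- n_subjects_per_class * 2 * n_segments
    block_labels <- rep(c("NC", "PD"), n_subjects_per_class)
    block_ids <- sprintf("%s%02d", block_labels,
                         rep(seq_len(n_subjects_per_class), each = 2))
    labels <- rep(block_labels, each = n_segments)
    groups <- rep(block_ids, each = n_segments)
    shift <- ifelse(labels == "PD", effect, 0)
    inf <- matrix(rnorm(n * n_inf), n, n_inf) + shift
    noise <- matrix(rnorm(n * n_noise), n, n_noise)
    values <- cbind(inf, noise)
    colnames(values) <- c(sprintf("INF%02d|O|FuzzyEn|m=1,r=0.15,r2=5", seq_len(n_inf)),
                          sprintf("NOISE%03d|O|FuzzyEn|m=1,r=0.15,r2=5",
                                  seq_len(n_noise)))
    feature_matrix(values, labels, groups,
                   segment_index = rep(seq_len(n_segments) - 1,
                                       n_subjects_per_class * 2))
  })
}
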