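# Identity cases, degenerate contracts and small-scale oracle agreement for
# the seven estimators. The full 100-series oracle-equivalence sweep lives in
# test-acceptance.R.

test_that("closed-form identity cases hold", {
  const <- rep(3.7, 50)
  expect_equal(svd_entropy(const, m = 3), 0)
  expect_equal(samp_entropy(const, m = 2, r_factor = 0.2), 0)
  expect_equal(fuzzy_entropy(const, m = 1, r_factor = 0.15, r2 = 5), 0)
  ramp <- as.numeric(1:60)
  expect_equal(perm_entropy(ramp, m = 4), 0)
  expect_equal(phase_entropy(ramp, K = 6), 0)
  zig <- c(rep(c(1, -1), 30), 1)   # odd length: both ordinal patterns equally frequent
  expect_equal(perm_entropy(zig, m = 2), 1)
  expect_equal(attn_entropy(zig), 0)
})

test_that("degenerate inputs raise the documented conditions", {
  expect_error(svd_entropy(numeric(40), m = 3),
               class = "eegentropy_degenerate_input")
  expect_error(attn_entropy(as.numeric(1:50)),
               class = "eegentropy_degenerate_input")
  expect_error(cosi_entropy(numeric(30), m = 3, r = 0.1),
               class = "eegentropy_degenerate_input")
  # ramp with vanishing tolerance: no template matches -> NA + warning
  expect_warning(v <- samp_entropy(as.numeric(1:40), m = 2, r_factor = 1e-12),
                 class = "eegentropy_undefined_entropy")
  expect_true(is.na(v))
  # one step then flat: every slope angle is exactly zero
  expect_warning(v <- phase_entropy(c(0, 1, 1, 1, 1, 1), K = 4),
                 class = "eegentropy_degenerate_value")
  expect_equal(v, 0)
})

test_that("each estimator matches its brute-force oracle on seeded noise", {
  x <- gen_gaussian(200, 42)
  expect_equal(svd_entropy(x, m = 3), o_svd(x, 3), tolerance = 1e-9)
  expect_equal(perm_entropy(x, m = 5), o_perm(x, 5), tolerance = 1e-12)
  expect_equal(samp_entropy(x, m = 2, r_factor = 0.25), o_samp(x, 2, 0.25),
               tolerance = 1e-12)
  expect_equal(cosi_entropy(x, m = 3, r = 0.05), o_cosi(x, 3, 0.05),
               tolerance = 1e-12)
  expect_equal(fuzzy_entropy(x, m = 1, r_factor = 0.15, r2 = 5),
               o_fuzzy(x, 1, 0.15, 5), tolerance = 1e-12)
  expect_equal(fuzzy_entropy(x, m = 2, r_factor = 0.3, r2 = 2),
               o_fuzzy(x, 2, 0.3, 2), tolerance = 1e-12)
  expect_equal(phase_entropy(x, K = 6), o_phase(x, 6), tolerance = 1e-12)
  expect_equal(attn_entropy(x), o_attn(x), tolerance = 1e-12)
})

test_that("the m = 1 fuzzy fast path agrees with the direct implementation", {
  for (seed in 1:5) {
    x <- gen_ar1(400, seed)
    expect_equal(fuzzy_entropy(x, m = 1, r_factor = 0.15, r2 = 5),
                 o_fuzzy(x, 1, 0.15, 5), tolerance = 1e-12)
    expect_equal(fuzzy_entropy(x, m = 1, r_factor = 0.4, r2 = 1),
                 o_fuzzy(x, 1, 0.4, 1), tolerance = 1e-12)
  }
})

test_that("fuzzy entropy is scale-invariant in the documented sense", {
  x <- gen_gaussian(300, 9)
  # r2 = 1: d and r both scale linearly, so any positive rescaling cancels
  expect_equal(fuzzy_entropy(5 * x, m = 2, r_factor = 0.2, r2 = 1),
               fuzzy_entropy(x, m = 2, r_factor = 0.2, r2 = 1),
               tolerance = 1e-9)
  # r2 != 1: equality holds after rescaling both inputs to unit sd
  u <- x / sd(x); w <- (3 * x) / sd(3 * x)
  expect_equal(fuzzy_entropy(u, m = 1, r_factor = 0.15, r2 = 5),
               fuzzy_entropy(w, m = 1, r_factor = 0.15, r2 = 5),
               tolerance = 1e-9)
})

test_that("normalised measures stay in [0, 1] across input families", {
  for (seed in 1:10) {
    x <- if (seed %% 2) gen_gaussian(150, seed) else gen_ar1(300, seed)
    for (v in c(svd_entropy(x, 4), perm_entropy(x, 3), phase_entropy(x, 8),
                cosi_entropy(x, 2, 0.3))) {
      expect_gte(v, 0); expect_lte(v, 1)
    }
  }
})

test_that("white noise scores higher complexity than a pure tone", {
  t <- (0:999) / 128
  sine <- sin(2 * pi * 10 * t)
  fuz_n <- perm_n <- samp_n <- numeric(20)
  fuz_s <- perm_s <- samp_s <- numeric(20)
  for (s in 1:20) {
    noise <- gen_gaussian(1000, 500 + s)
    fuz_n[s] <- fuzzy_entropy(noise); fuz_s[s] <- fuzzy_entropy(sine)
    perm_n[s] <- perm_entropy(noise); perm_s[s] <- perm_entropy(sine)
    samp_n[s] <- samp_entropy(noise); samp_s[s] <- samp_entropy(sine)
  }
  expect_gt(mean(fuz_n), mean(fuz_s))
  expect_gt(mean(perm_n), mean(perm_s))
  expect_gt(mean(samp_n), mean(samp_s))
})

test_that("fuzzy entropy rises monotonically with added noise", {
  t <- (0:999) / 128
  sine <- sin(2 * pi * 10 * t)
  sigmas <- c(0, 0.1, 0.3, 1.0)
  means <- vapply(sigmas, function(sg)
    mean(vapply(1:20, function(s)
      fuzzy_entropy(sine + sg * gen_gaussian(1000, 900 + s)), numeric(1))),
    numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("hyperparameter grids enumerate the documented lattices", {
  expect_length(entropy_grid("FuzzyEn"), 100)   # 2 x 10 x 5
  rs <- unique(vapply(entropy_grid("FuzzyEn"), function(c) c$r, numeric(1)))
  expect_equal(sort(rs), seq(0.05, 0.5, by = 0.05))
  expect_length(entropy_grid("PhaseEn"), 9)
  expect_equal(vapply(entropy_grid("PhaseEn"), function(c) c$K, numeric(1)), 2:10)
  expect_length(entropy_grid("AttnEn"), 1)
  expect_length(entropy_grid("SVDEn"), 9)
  expect_length(entropy_grid("PermEn"), 9)
  expect_length(entropy_grid("SampEn"), 30)
  expect_length(entropy_grid("CoSiEn"), 20)
  expect_error(entropy_grid("BubbleEn"), class = "eegentropy_invalid_argument")
})
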