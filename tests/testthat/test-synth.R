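test_that("the generator is bit-identical under a fixed seed", {
  cfg <- synth_config(duration = 2, seed = 42)
  p1 <- generate_eeg_pair(cfg)
  p2 <- generate_eeg_pair(cfg)
  expect_identical(p1$ch1, p2$ch1)
  expect_identical(p1$ch2, p2$ch2)
  expect_identical(p1$a, p2$a)
})

test_that("a shared source only (a = 1) makes the channels identical with
           unit coherence", {
  pair <- const_pair(1, duration = 2, seed = 7)
  expect_identical(pair$ch1, pair$ch2)
  expect_equal(pair_coh_series(pair), rep(1, 2))
})

test_that("independent channels (a = 0) stay below the small-sample
           coherence bias ceiling", {
  pair <- const_pair(0, duration = 200, seed = 8)
  expect_lt(mean(pair_coh_series(pair)), 0.45)
})

test_that("band coherence estimated with many segments recovers the a^4
           ground truth of the mixing model", {
  for (a in c(0.5, 0.8)) {
    est <- vapply(1:8, function(i) {
      pair <- const_pair(a, duration = 60, seed = 3000 + i)
      msc_spectrum(eeg_window(pair$ch1, pair$ch2, 500),
                   seg_len = 250)$coh_beta
    }, numeric(1))
    se <- stats::sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - a^4), 3 * se + 0.01)
  }
})

test_that("regressing the estimate on a^4 over a grid of mixing levels
           gives slope near one", {
  grid <- c(0.3, 0.5, 0.7, 0.9)
  est <- vapply(seq_along(grid), function(i) {
    pair <- const_pair(grid[i], duration = 60, seed = 4000 + i)
    msc_spectrum(eeg_window(pair$ch1, pair$ch2, 500), seg_len = 250)$coh_beta
  }, numeric(1))
  slope <- stats::coef(stats::lm(est ~ I(grid^4)))[2]
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.2)
})

test_that("without drift the per-second coherence series has no linear
           trend", {
  pair <- const_pair(0.8, duration = 180, seed = 9)
  cs <- pair_coh_series(pair)
  fit <- summary(stats::lm(cs ~ seq_along(cs)))
  expect_gt(stats::coef(fit)[2, "Pr(>|t|)"], 0.01)
})

test_that("mixing configurations leaving [0, 1] are rejected", {
  expect_error(synth_config(duration = 2, mixing_mean = 0.9,
                            drift_amplitude = 0.2), "\\[0, 1\\]")
  expect_error(synth_config(duration = 0.5), "at least 1 second")
})

test_that("MEP draws follow the coherence-dependent dispersion model", {
  # degenerate noise: amplitude is exactly mu at any coherence
  m0 <- mep_model(mu = 2, sigma_max = 0, sigma_min = 0, seed = 1)
  expect_equal(simulate_mep(0.3, m0, n = 5), rep(2, 5))

  # dispersion shrinks with coherence: CV at c = 0.9 < CV at c = 0.3
  m <- mep_model(mu = 1, sigma_max = 0.6, sigma_min = 0.1)
  cv <- function(c, seed) {
    x <- simulate_mep(c, mep_model(seed = seed), n = 10000)
    stats::sd(x) / mean(x)
  }
  expect_lt(cv(0.9, 11), cv(0.3, 11))

  # law of large numbers at sigma = 0.2 (c chosen so sigma(c) = 0.2)
  c02 <- (0.6 - 0.2) / (0.6 - 0.1)
  x <- simulate_mep(c02, mep_model(seed = 12), n = 10000)
  expect_lt(abs(mean(x) - 1), 3 * 0.2 / sqrt(10000))

  expect_error(simulate_mep(1.2, m), "\\[0, 1\\]")
  expect_error(simulate_mep(-0.1, m), "\\[0, 1\\]")
})

test_that("draws are truncated at zero so amplitudes are magnitudes", {
  m <- mep_model(mu = 0.1, sigma_max = 5, sigma_min = 5, seed = 3)
  expect_true(all(simulate_mep(0.5, m, n = 1000) >= 0))
})
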