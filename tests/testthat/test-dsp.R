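test_that("bandpass filter passes the band and attenuates outside it", {
  fs <- 500
  t <- (0:4999) / fs

  expect_equal(bandpass_filter(rep(0, 500), fs), rep(0, 500))

  # steady-state amplitude from the second half of a 10-s sine
  amp <- function(f) {
    y <- bandpass_filter(sin(2 * pi * f * t), fs)
    sqrt(2 * mean(y[2501:5000]^2))
  }
  expect_lt(abs(amp(10) - 1), 0.05)
  # stopband: below the closed-form analog Butterworth response at 60 Hz
  expect_lt(amp(60), butter_bandpass_gain(60, 1, 30, order = 4))
})

test_that("bandpass filter rejects bad inputs by name", {
  expect_error(bandpass_filter(c(1, NA, 3, rep(0, 50)), 500), "finite")
  expect_error(bandpass_filter(rnorm(100), 500, low = 1, high = 300),
               "Nyquist")
  expect_error(bandpass_filter(rnorm(100), 500, low = 40, high = 30),
               "low < high")
  expect_error(bandpass_filter(rnorm(10), 500), "shorter")
})

test_that("identical channels give unit coherence at every bin", {
  set.seed(101)
  x <- rnorm(500)
  spec <- msc_spectrum(eeg_window(x, x, 500))
  expect_true(all(abs(spec$msc - 1) < 1e-9))
  expect_equal(spec$coh_beta, 1)
})

test_that("independent channels show the known small-sample coherence bias,
           shrinking with the number of averaging segments", {
  set.seed(102)
  m3 <- m7 <- numeric(100)
  for (i in 1:100) {
    w <- eeg_window(rnorm(500), rnorm(500), 500)
    m3[i] <- msc_spectrum(w, seg_len = 250)$coh_beta  # 3 segments
    m7[i] <- msc_spectrum(w, seg_len = 125)$coh_beta  # 7 segments
  }
  expect_lt(mean(m3), 0.5)
  expect_lt(mean(m7), mean(m3))
})

test_that("Welch coherence matches the brute-force DFT oracle bin-for-bin", {
  set.seed(103)
  for (i in 1:20) {
    n <- sample(400:1000, 1)
    pair <- const_pair(runif(1, 0.3, 0.95), duration = 2, seed = 1000 + i)
    x <- pair$ch1[1:n]
    y <- pair$ch2[1:n]
    spec <- msc_spectrum(eeg_window(x, y, 500), seg_len = 250)
    expect_lt(max(abs(spec$msc - brute_msc(x, y, seg_len = 250))), 1e-10)
  }
})

test_that("coherence is symmetric, scale invariant, and bounded", {
  set.seed(104)
  for (i in 1:10) {
    pair <- const_pair(runif(1, 0, 1), duration = 1, seed = 2000 + i)
    w12 <- eeg_window(pair$ch1, pair$ch2, 500)
    w21 <- eeg_window(pair$ch2, pair$ch1, 500)
    s12 <- msc_spectrum(w12)
    expect_equal(s12$msc, msc_spectrum(w21)$msc, tolerance = 1e-12)
    k <- runif(1, 0.1, 100)
    ws <- eeg_window(k * pair$ch1, pair$ch2, 500)
    expect_equal(msc_spectrum(ws)$msc, s12$msc, tolerance = 1e-9)
    expect_true(all(s12$msc >= 0 & s12$msc <= 1 + 1e-12))
  }
})

test_that("degenerate spectra are refused with informative errors", {
  set.seed(105)
  x <- rnorm(500)
  w <- eeg_window(x, rnorm(500), 500)
  expect_error(msc_spectrum(w, seg_len = 500), "single segment")
  expect_error(msc_spectrum(eeg_window(x, rep(1, 500), 500)),
               "zero-variance")
  expect_error(eeg_window(x, rnorm(400), 500), "identical length")
  expect_error(eeg_window(x, c(rnorm(499), Inf), 500), "non-finite")
})

test_that("band-mean coherence averages exactly the in-band bins", {
  freqs <- seq(0, 250, by = 2)
  expect_equal(coh_beta(list(freqs = freqs, msc = rep(0.5, 126))), 0.5)

  in_band <- freqs >= 14 & freqs <= 30
  expect_equal(sum(in_band), 9L)   # nine bins at 2 Hz spacing
  expect_equal(coh_beta(list(freqs = freqs, msc = as.numeric(in_band))), 1)

  # ramp spectrum: hand-enumerated mean of bins 8..16 of 126
  ramp <- seq_along(freqs) / length(freqs)
  expect_equal(coh_beta(list(freqs = freqs, msc = ramp)),
               mean((8:16) / 126))

  expect_error(coh_beta(list(freqs = c(0, 40), msc = c(0, 0))), "no frequency bins")
  expect_error(coh_beta(list(freqs = c(0, 10), msc = c(0, 0))), "cover")
})
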