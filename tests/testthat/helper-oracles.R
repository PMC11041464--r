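# Independent oracles used by the tests. These deliberately avoid the
# package's own computation paths: the coherence oracle forms segment
# DFTs by explicit matrix multiplication, the filter oracle is the
# closed-form analog Butterworth magnitude response, and the F-test
# oracle evaluates the regularized incomplete beta function by Lentz's
# continued fraction.

# Brute-force Welch magnitude-squared coherence, one-sided bins.
brute_msc <- function(ch1, ch2, seg_len = 250, overlap = 0.5,
                      taper = "hann", detrend = TRUE) {
  step <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  starts <- seq(1L, length(ch1) - seg_len + 1L, by = step)
  nb <- floor(seg_len / 2) + 1L
  w <- switch(taper,
              hann = 0.5 - 0.5 * cos(2 * pi * (0:(seg_len - 1)) / (seg_len - 1)),
              hamming = 0.54 - 0.46 * cos(2 * pi * (0:(seg_len - 1)) / (seg_len - 1)),
              rect = rep(1, seg_len))
  dft <- exp(-2i * pi * outer(0:(nb - 1), 0:(seg_len - 1)) / seg_len)
  pxx <- pyy <- numeric(nb)
  pxy <- complex(nb)
  for (s in starts) {
    x <- ch1[s:(s + seg_len - 1L)]
    y <- ch2[s:(s + seg_len - 1L)]
    if (detrend) {
      x <- x - mean(x)
      y <- y - mean(y)
    }
    X <- as.vector(dft %*% (x * w))
    Y <- as.vector(dft %*% (y * w))
    pxx <- pxx + Mod(X)^2
    pyy <- pyy + Mod(Y)^2
    pxy <- pxy + X * Conj(Y)
  }
  den <- pxx * pyy
  ifelse(den > 0, Mod(pxy)^2 / den, 0)
}

# Closed-form magnitude response of an analog Butterworth bandpass built
# from an order-`order` lowpass prototype.
butter_bandpass_gain <- function(f, low, high, order = 4) {
  omega <- (f^2 - low * high) / (f * (high - low))
  1 / sqrt(1 + omega^(2 * order))
}

# Regularized incomplete beta function I_x(a, b), Lentz continued
# fraction (independent of stats::pbeta / stats::pf).
betacf <- function(x, a, b, itmax = 300L, eps = 3e-14) {
  fpmin <- 1e-300
  qab <- a + b; qap <- a + 1; qam <- a - 1
  cc <- 1
  d <- 1 - qab * x / qap
  if (abs(d) < fpmin) d <- fpmin
  d <- 1 / d
  h <- d
  for (m in seq_len(itmax)) {
    m2 <- 2 * m
    aa <- m * (b - m) * x / ((qam + m2) * (a + m2))
    d <- 1 + aa * d; if (abs(d) < fpmin) d <- fpmin
    cc <- 1 + aa / cc; if (abs(cc) < fpmin) cc <- fpmin
    d <- 1 / d
    h <- h * d * cc
    aa <- -(a + m) * (qab + m) * x / ((a + m2) * (qap + m2))
    d <- 1 + aa * d; if (abs(d) < fpmin) d <- fpmin
    cc <- 1 + aa / cc; if (abs(cc) < fpmin) cc <- fpmin
    d <- 1 / d
    del <- d * cc
    h <- h * del
    if (abs(del - 1) < eps) break
  }
  h
}

inc_beta_reg <- function(x, a, b) {
  if (x <= 0) return(0)
  if (x >= 1) return(1)
  bt <- exp(lgamma(a + b) - lgamma(a) - lgamma(b) +
              a * log(x) + b * log1p(-x))
  if (x < (a + 1) / (a + b + 2)) bt * betacf(x, a, b) / a
  else 1 - bt * betacf(1 - x, b, a) / b
}

# Lower-tail F cdf through the incomplete beta.
pf_oracle <- function(f, df1, df2) {
  inc_beta_reg(df1 * f / (df1 * f + df2), df1 / 2, df2 / 2)
}

# Two-sided variance-ratio p-value through the oracle cdf.
f_p_oracle <- function(f, df1, df2) {
  lo <- pf_oracle(f, df1, df2)
  min(1, 2 * min(lo, 1 - lo))
}
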