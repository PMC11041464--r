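#' Configuration of the synthetic two-channel EEG generator
#'
#' The generator emulates a resting, eyes-open two-channel recording with
#' controllable inter-channel band coherence. Both channels share a
#' common source \eqn{s(t)} mixed with independent channel noises:
#' \deqn{ch_i(t) = a(t)\,s(t) + \sqrt{1 - a(t)^2}\; n_i(t)}
#' with \eqn{s}, \eqn{n_1}, \eqn{n_2} mutually independent and identically
#' spectrally shaped (pink background plus band-limited alpha and beta
#' components). Under equal shaping the true magnitude-squared coherence
#' of the pair is \eqn{a(t)^4} at every frequency, which provides an
#' exact ground truth for validating the coherence estimator.
#'
#' The mixing coefficient drifts slowly and deterministically,
#' \eqn{a(t) = a_0 + A \sin(2\pi t / T)}, emulating the slow waxing and
#' waning of inter-hemispheric coupling over a session; the default
#' \eqn{a_0 = 0.8}, \eqn{A = 0.15}, \eqn{T = 40} s keeps the true band
#' coherence roughly between 0.18 and 0.81 with excursions above and
#' below a typical calibrated trigger threshold every period.
#'
#' @param duration Record length in seconds (at least 1).
#' @param fs Sampling rate (Hz).
#' @param mixing_mean Mean mixing coefficient \eqn{a_0 \in [0, 1]}.
#' @param drift_amplitude Amplitude \eqn{A} of the sinusoidal drift of
#'   \eqn{a(t)}; \code{mixing_mean} plus/minus \code{drift_amplitude}
#'   must stay inside \code{[0, 1]}. Set to 0 for a stationary record.
#' @param drift_period Drift period \eqn{T} in seconds.
#' @param alpha_power,beta_power,pink_power Relative powers of the 8-13 Hz
#'   alpha component, the 14-30 Hz beta component, and the pink (1/f)
#'   background, applied identically to the source and both noises.
#' @param seed Integer seed; a fixed seed makes the record bit-identical.
#'   \code{NULL} draws from the current RNG state.
#' @return A list of class \code{"synth_config"}.
#' @export
synth_config <- function(duration, fs = 500, mixing_mean = 0.8,
                         drift_amplitude = 0.15, drift_period = 40,
                         alpha_power = 1, beta_power = 1, pink_power = 1,
                         seed = NULL) {
  stopifnot(length(duration) == 1L, is.finite(duration),
            length(fs) == 1L, fs > 0, drift_period > 0,
            alpha_power >= 0, beta_power >= 0, pink_power >= 0)
  if (duration < 1)
    stop("duration must be at least 1 second", call. = FALSE)
  if (mixing_mean - abs(drift_amplitude) < 0 ||
      mixing_mean + abs(drift_amplitude) > 1)
    stop("mixing coefficient must stay inside [0, 1]: require ",
         "0 <= mixing_mean +/- drift_amplitude <= 1", call. = FALSE)
  structure(list(duration = duration, fs = fs, mixing_mean = mixing_mean,
                 drift_amplitude = drift_amplitude,
                 drift_period = drift_period, alpha_power = alpha_power,
                 beta_power = beta_power, pink_power = pink_power,
                 seed = seed),
            class = "synth_config")
}

# Pink (1/f) noise via frequency-domain shaping of white Gaussian noise.
# The amplitude scale is 1/sqrt(max(f, 1 Hz)); the shaping vector is real
# and even in frequency so the inverse transform is real. Normalized by
# the deterministic root-mean-square of the shaping vector so the output
# has unit variance in expectation.
pink_noise <- function(n, fs) {
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)                 # two-sided |f|
  s <- 1 / sqrt(pmax(f, 1))
  s[1] <- 0                            # no DC
  s <- s / sqrt(mean(s^2))
  Re(stats::fft(stats::fft(stats::rnorm(n)) * s, inverse = TRUE)) / n
}

# Energy of a filter's impulse response = white-noise power gain; used to
# normalize band-limited components deterministically (no per-realization
# empirical scaling, which would perturb the equal-shaping guarantee).
filter_power_gain <- function(fs, low, high, order = 4, n = 4096) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  h <- as.numeric(signal::filter(bf, c(1, rep(0, n - 1))))
  sum(h^2)
}

# One spectrally shaped source: pink + alpha-band + beta-band components,
# weights fixed by the config. Identical shaping across calls (for the
# shared source and both noises) is what makes the pair's true MSC equal
# a(t)^4 exactly.
shaped_source <- function(n, cfg) {
  fs <- cfg$fs
  ga <- filter_power_gain(fs, 8, 13)
  gb <- filter_power_gain(fs, 14, 30)
  x <- sqrt(cfg$pink_power) * pink_noise(n, fs)
  if (cfg$alpha_power > 0)
    x <- x + sqrt(cfg$alpha_power / ga) *
      as.numeric(signal::filter(signal::butter(4, c(8, 13) / (fs / 2), "pass"),
                                stats::rnorm(n)))
  if (cfg$beta_power > 0)
    x <- x + sqrt(cfg$beta_power / gb) *
      as.numeric(signal::filter(signal::butter(4, c(14, 30) / (fs / 2), "pass"),
                                stats::rnorm(n)))
  x
}

#' Generate a synthetic two-channel EEG record with known coherence
#'
#' Draws the shared source and the two channel noises, builds the mixing
#' trace \eqn{a(t)}, and mixes. See [synth_config()] for the model. The
#' record is bit-identical under a fixed \code{seed}.
#'
#' @param cfg A [synth_config()].
#' @return A list of class \code{"eeg_pair"} with elements \code{ch1},
#'   \code{ch2} (amplitude vectors), \code{a} (the ground-truth mixing
#'   trace, per sample), \code{fs}, and \code{duration}. The true
#'   magnitude-squared coherence at time \eqn{t} is \code{a[t]^4}.
#' @export
#' @examples
#' pair <- generate_eeg_pair(synth_config(duration = 2, seed = 1))
#' str(pair$ch1[1:5])
generate_eeg_pair <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  gen <- function() {
    n <- round(cfg$fs * cfg$duration)
    t <- (seq_len(n) - 1L) / cfg$fs
    a <- cfg$mixing_mean +
      cfg$drift_amplitude * sin(2 * pi * t / cfg$drift_period)
    if (any(a < 0 | a > 1))
      stop("mixing trace leaves [0, 1]", call. = FALSE)
    s  <- shaped_source(n, cfg)
    n1 <- shaped_source(n, cfg)
    n2 <- shaped_source(n, cfg)
    b <- sqrt(1 - a^2)
    structure(list(ch1 = a * s + b * n1, ch2 = a * s + b * n2,
                   a = a, fs = cfg$fs, duration = cfg$duration),
              class = "eeg_pair")
  }
  if (is.null(cfg$seed)) gen() else withr::with_seed(cfg$seed, gen())
}

#' @export
print.eeg_pair <- function(x, ...) {
  cat(sprintf("<eeg_pair> %g s @ %g Hz, mixing a(t) in [%.3f, %.3f]\n",
              x$duration, x$fs, min(x$a), max(x$a)))
  invisible(x)
}

#' Coherence-dependent MEP amplitude model
#'
#' Encodes the working hypothesis of coherence-gated stimulation: the
#' trial-to-trial dispersion of the motor-evoked-potential amplitude
#' shrinks as the beta-band coherence at stimulation time grows. The
#' relative dispersion interpolates linearly between \code{sigma_max}
#' (at coherence 0) and \code{sigma_min} (at coherence 1); only the
#' direction of the effect is constrained by the underlying physiology,
#' so the linear form is the simplest monotone choice.
#'
#' @param mu Baseline MEP amplitude (mV), positive.
#' @param sigma_max Relative dispersion at coherence 0.
#' @param sigma_min Relative dispersion at coherence 1;
#'   \code{0 <= sigma_min <= sigma_max}.
#' @param seed Optional integer seed making draws reproducible; with
#'   \code{NULL}, draws consume the current RNG stream (as inside a
#'   seeded session).
#' @return A list of class \code{"mep_model"}.
#' @export
mep_model <- function(mu = 1.0, sigma_max = 0.6, sigma_min = 0.1,
                      seed = NULL) {
  stopifnot(length(mu) == 1L, mu > 0)
  if (!(sigma_min >= 0 && sigma_min <= sigma_max))
    stop("require 0 <= sigma_min <= sigma_max", call. = FALSE)
  structure(list(mu = mu, sigma_max = sigma_max, sigma_min = sigma_min,
                 seed = seed),
            class = "mep_model")
}

#' Simulate motor-evoked-potential amplitudes
#'
#' Draws \eqn{A = \mu (1 + \varepsilon)} with
#' \eqn{\varepsilon \sim N(0, \sigma(c)^2)} and
#' \eqn{\sigma(c) = \sigma_{max} - (\sigma_{max} - \sigma_{min})\, c},
#' where \eqn{c} is the band coherence at stimulation time. Negative
#' draws are truncated at 0 (amplitudes are magnitudes).
#'
#' @param c Coherence value(s) in \code{[0, 1]}. If a vector, one draw is
#'   made per element and \code{n} is ignored.
#' @param model A [mep_model()].
#' @param n Number of draws when \code{c} is scalar.
#' @return Numeric vector of amplitudes (mV).
#' @export
#' @examples
#' simulate_mep(0.9, mep_model(seed = 1), n = 3)
simulate_mep <- function(c, model, n = 1L) {
  stopifnot(inherits(model, "mep_model"))
  if (!is.numeric(c) || any(!is.finite(c)) || any(c < 0 | c > 1))
    stop("coherence values must lie in [0, 1]", call. = FALSE)
  if (length(c) > 1L) n <- length(c)
  sigma <- model$sigma_max - (model$sigma_max - model$sigma_min) * c
  draw <- function() pmax(0, model$mu * (1 + stats::rnorm(n) * sigma))
  if (is.null(model$seed)) draw() else withr::with_seed(model$seed, draw())
}
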