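#' DSP parameter set for the per-second coherence analysis
#'
#' Bundles every spectral-analysis parameter used throughout the package:
#' the sampling rate, the analysis band whose mean coherence forms the
#' trigger statistic, the front-end bandpass filter, and the Welch
#' segmentation of each one-second analysis window.
#'
#' The defaults implement per-second analysis at 500 Hz: each 500-sample
#' window is split into three half-overlapping 250-sample Hann-tapered
#' segments, giving 2 Hz bin spacing and nine bins inside the 14-30 Hz
#' beta band (14, 16, ..., 30 Hz). Three segments is the minimum giving a
#' non-degenerate magnitude-squared coherence at a 1-s analysis cadence.
#'
#' @param fs Sampling rate in Hz.
#' @param band Two-element numeric, the analysis band (Hz), endpoints
#'   inclusive. Defaults to the beta band, 14-30 Hz.
#' @param filter_band Two-element numeric, passband of the front-end
#'   Butterworth bandpass filter (Hz).
#' @param filter_order Order of the Butterworth lowpass prototype; the
#'   bandpass transfer function has twice this order.
#' @param seg_len Welch segment length in samples.
#' @param overlap Fractional overlap between consecutive segments, in
#'   \code{[0, 1)}.
#' @param taper Segment taper: one of \code{"hann"}, \code{"hamming"},
#'   \code{"rect"}.
#' @param detrend Logical; remove each segment's mean before tapering.
#'   Suppresses DC leakage that the 1 Hz highpass edge does not fully
#'   remove.
#' @param zero_phase Logical; if \code{TRUE}, filter forward-backward
#'   (zero phase). The default is causal filtering, as in an online
#'   system.
#' @return A list of class \code{"dsp_params"}.
#' @export
#' @examples
#' dsp <- dsp_params()
#' dsp$seg_len
dsp_params <- function(fs = 500, band = c(14, 30), filter_band = c(1, 30),
                       filter_order = 4, seg_len = 250, overlap = 0.5,
                       taper = c("hann", "hamming", "rect"),
                       detrend = TRUE, zero_phase = FALSE) {
  taper <- match.arg(taper)
  stopifnot(length(fs) == 1L, fs > 0, length(band) == 2L,
            length(filter_band) == 2L, length(seg_len) == 1L,
            seg_len >= 2, length(overlap) == 1L,
            overlap >= 0, overlap < 1)
  if (band[1] >= band[2])
    stop("analysis band must satisfy low < high", call. = FALSE)
  if (fs <= 2 * band[2])
    stop("sampling rate must exceed twice the upper analysis-band edge ",
         "(Nyquist must cover the band)", call. = FALSE)
  if (filter_band[1] <= 0 || filter_band[1] >= filter_band[2] ||
      filter_band[2] >= fs / 2)
    stop("filter band must satisfy 0 < low < high < fs/2", call. = FALSE)
  if (filter_order < 1)
    stop("filter_order must be >= 1", call. = FALSE)
  structure(list(fs = fs, band = band, filter_band = filter_band,
                 filter_order = filter_order, seg_len = seg_len,
                 overlap = overlap, taper = taper, detrend = detrend,
                 zero_phase = zero_phase),
            class = "dsp_params")
}

#' Two-channel EEG analysis window
#'
#' The unit of per-second analysis: a fixed-duration block of two
#' simultaneously sampled channels with sampling-rate metadata.
#'
#' @param ch1,ch2 Numeric amplitude vectors (microvolts), equal length.
#' @param fs Sampling rate in Hz.
#' @param t_start Start time of the window (s), for bookkeeping.
#' @return A list of class \code{"eeg_window"}.
#' @export
eeg_window <- function(ch1, ch2, fs, t_start = 0) {
  ch1 <- as.numeric(ch1)
  ch2 <- as.numeric(ch2)
  if (length(ch1) != length(ch2))
    stop("both channels must have identical length", call. = FALSE)
  if (length(ch1) < 2L)
    stop("window too short", call. = FALSE)
  if (!all(is.finite(ch1)) || !all(is.finite(ch2)))
    stop("non-finite samples in EEG window", call. = FALSE)
  stopifnot(length(fs) == 1L, fs > 0)
  structure(list(ch1 = ch1, ch2 = ch2, fs = fs, t_start = t_start),
            class = "eeg_window")
}

#' @export
print.eeg_window <- function(x, ...) {
  cat(sprintf("<eeg_window> %d samples @ %g Hz (%.3f s) starting at t = %g s\n",
              length(x$ch1), x$fs, length(x$ch1) / x$fs, x$t_start))
  invisible(x)
}

#' Butterworth bandpass filter for a streaming biosignal
#'
#' Applies the front-end bandpass used before coherence analysis. The
#' filter is a Butterworth bandpass built from an order-\code{order}
#' lowpass prototype (so the bandpass transfer function has order
#' \code{2 * order}); the default 1-30 Hz band removes drift and
#' restricts the signal to the analyzed frequencies.
#'
#' @param x Numeric amplitude vector.
#' @param fs Sampling rate (Hz).
#' @param low,high Passband edges (Hz); must satisfy
#'   \code{0 < low < high < fs/2}.
#' @param order Lowpass-prototype order, at least 1.
#' @param zero_phase If \code{TRUE}, filter forward-backward
#'   (\code{signal::filtfilt}); default is causal (\code{signal::filter}),
#'   matching online operation.
#' @return Filtered vector of identical length.
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 1, by = 1 / 500))
#' y <- bandpass_filter(x, fs = 500)
bandpass_filter <- function(x, fs, low = 1, high = 30, order = 4,
                            zero_phase = FALSE) {
  x <- as.numeric(x)
  if (!all(is.finite(x)))
    stop("non-finite samples: the filter input must be finite", call. = FALSE)
  if (!(low > 0 && low < high))
    stop("cutoffs must satisfy 0 < low < high", call. = FALSE)
  if (high >= fs / 2)
    stop("upper cutoff must lie below the Nyquist frequency fs/2",
         call. = FALSE)
  if (order < 1) stop("order must be >= 1", call. = FALSE)
  if (length(x) <= 3 * order)
    stop("input shorter than 3 x filter order", call. = FALSE)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  if (zero_phase) as.numeric(signal::filtfilt(bf, x))
  else as.numeric(signal::filter(bf, x))
}

# Symmetric taper window of length n.
taper_window <- function(n, type) {
  k <- seq_len(n) - 1L
  switch(type,
         hann    = 0.5 - 0.5 * cos(2 * pi * k / (n - 1)),
         hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1)),
         rect    = rep(1, n),
         stop("unknown taper: ", type, call. = FALSE))
}

# Welch auto-/cross-spectra for a batch of equal-length windows.
#
# ch1, ch2: full-length signals; win_starts: 1-based start index of each
# analysis window; win_len: window length in samples. Each window is cut
# into K segments of seg_len samples at the given fractional overlap;
# segments are (optionally) mean-removed, tapered, DFT'd, and the
# periodograms averaged within each window. Returns one-sided spectra:
# a list with freqs (Hz), and nb x nwin matrices pxx, pyy (real) and pxy
# (complex), where nb = floor(seg_len/2) + 1.
welch_csd_batch <- function(ch1, ch2, fs, win_starts, win_len,
                            seg_len, overlap, taper, detrend) {
  step <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  seg_offsets <- seq(0L, win_len - seg_len, by = step)
  K <- length(seg_offsets)
  if (K < 2L)
    stop("Welch segmentation yields a single segment, for which the ",
         "magnitude-squared coherence is identically 1; use a shorter ",
         "seg_len or larger window", call. = FALSE)
  nwin <- length(win_starts)
  starts <- rep(win_starts, each = K) + rep(seg_offsets, times = nwin)
  idx <- outer(seq_len(seg_len) - 1L, starts, "+")
  m1 <- matrix(ch1[idx], nrow = seg_len)
  m2 <- matrix(ch2[idx], nrow = seg_len)
  if (detrend) {
    m1 <- sweep(m1, 2L, colMeans(m1))
    m2 <- sweep(m2, 2L, colMeans(m2))
  }
  w <- taper_window(seg_len, taper)
  F1 <- stats::mvfft(m1 * w)
  F2 <- stats::mvfft(m2 * w)
  nb <- floor(seg_len / 2) + 1L
  F1 <- F1[seq_len(nb), , drop = FALSE]
  F2 <- F2[seq_len(nb), , drop = FALSE]
  # average periodograms within each window (groups of K consecutive cols)
  grp_mean <- function(m) {
    a <- array(m, dim = c(nb, K, nwin))
    colMeans(aperm(a, c(2L, 1L, 3L)))          # -> nb x nwin
  }
  list(freqs = (seq_len(nb) - 1L) * fs / seg_len,
       pxx = grp_mean(Re(F1)^2 + Im(F1)^2),
       pyy = grp_mean(Re(F2)^2 + Im(F2)^2),
       pxy = grp_mean(F1 * Conj(F2)),
       n_segments = K)
}

#' Magnitude-squared coherence spectrum of a two-channel window
#'
#' Welch estimate of the magnitude-squared coherence (MSC)
#' \deqn{C_{xy}(f) = \frac{|P_{xy}(f)|^2}{P_{xx}(f)\,P_{yy}(f)}}
#' where \eqn{P_{xx}}, \eqn{P_{yy}} are the segment-averaged auto power
#' spectral densities of the two channels and \eqn{P_{xy}} the averaged
#' cross-spectral density. At least two averaging segments are required:
#' with a single segment the estimator is identically 1 regardless of the
#' signals and is refused.
#'
#' The returned object also carries \code{coh_beta}, the arithmetic mean
#' of the MSC over bins inside the analysis band (see [coh_beta()]).
#'
#' @param w An [eeg_window()].
#' @param seg_len Segment length in samples.
#' @param overlap Fractional segment overlap in \code{[0, 1)}.
#' @param taper Taper name (see [dsp_params()]).
#' @param detrend Remove each segment's mean before tapering.
#' @param band Analysis band (Hz) for the scalar summary.
#' @return A list of class \code{"coherence_spectrum"} with elements
#'   \code{freqs}, \code{msc}, \code{coh_beta}, \code{band},
#'   \code{n_segments}.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(500)
#' w <- eeg_window(x, x, fs = 500)
#' spec <- msc_spectrum(w)          # identical channels: MSC = 1 everywhere
#' spec$coh_beta
msc_spectrum <- function(w, seg_len = 250, overlap = 0.5,
                         taper = "hann", detrend = TRUE,
                         band = c(14, 30)) {
  stopifnot(inherits(w, "eeg_window"))
  n <- length(w$ch1)
  if (seg_len > n)
    stop("seg_len exceeds window length", call. = FALSE)
  if (stats::var(w$ch1) == 0 || stats::var(w$ch2) == 0)
    stop("zero-variance channel: auto power spectral density vanishes and ",
         "the coherence quotient is undefined", call. = FALSE)
  sp <- welch_csd_batch(w$ch1, w$ch2, w$fs, win_starts = 1L, win_len = n,
                        seg_len = seg_len, overlap = overlap,
                        taper = taper, detrend = detrend)
  den <- sp$pxx[, 1L] * sp$pyy[, 1L]
  num <- Re(sp$pxy[, 1L])^2 + Im(sp$pxy[, 1L])^2
  msc <- ifelse(den > 0, num / den, 0)
  out <- structure(list(freqs = sp$freqs, msc = as.numeric(msc),
                        coh_beta = NA_real_, band = band,
                        n_segments = sp$n_segments),
                   class = "coherence_spectrum")
  out$coh_beta <- coh_beta(out)
  out
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf(
    "<coherence_spectrum> %d bins, %g-%g Hz (df = %g Hz), %d segments\n",
    length(x$freqs), min(x$freqs), max(x$freqs),
    if (length(x$freqs) > 1) x$freqs[2] - x$freqs[1] else NA_real_,
    x$n_segments))
  cat(sprintf("  Coh(beta) over [%g, %g] Hz = %.4f\n",
              x$band[1], x$band[2], x$coh_beta))
  invisible(x)
}

#' Band-mean coherence, Coh(beta)
#'
#' The scalar trigger statistic: the arithmetic mean of the
#' magnitude-squared coherence over the frequency bins lying inside the
#' analysis band, endpoints inclusive. With the default 2 Hz resolution
#' and 14-30 Hz band this averages nine bins.
#'
#' @param spec A \code{"coherence_spectrum"}, or a list with numeric
#'   \code{freqs} and \code{msc}.
#' @param band Band edges (Hz); defaults to the spectrum's own band if
#'   present, else 14-30 Hz.
#' @return Scalar in \code{[0, 1]}.
#' @export
coh_beta <- function(spec, band = NULL) {
  if (is.null(band)) band <- if (!is.null(spec$band)) spec$band else c(14, 30)
  freqs <- spec$freqs
  msc <- spec$msc
  stopifnot(length(freqs) == length(msc))
  if (min(freqs) > band[1] || max(freqs) < band[2])
    stop("spectrum does not cover the analysis band [", band[1], ", ",
         band[2], "] Hz", call. = FALSE)
  eps <- 1e-9
  in_band <- freqs >= band[1] - eps & freqs <= band[2] + eps
  if (!any(in_band))
    stop("no frequency bins inside the analysis band: spectral resolution ",
         "too coarse", call. = FALSE)
  mean(msc[in_band])
}

# Per-second Coh(beta) series over consecutive non-overlapping 1-s windows
# of two already-filtered full-length channels. Used by the calibration
# fragmenter and the session runner. Vectorized over all windows.
coh_series <- function(ch1, ch2, dsp = dsp_params()) {
  stopifnot(length(ch1) == length(ch2))
  fs <- dsp$fs
  nwin <- floor(length(ch1) / fs)
  if (nwin < 1L) stop("fewer than one full second of samples", call. = FALSE)
  used <- nwin * fs
  v1 <- stats::var(ch1[seq_len(used)])
  v2 <- stats::var(ch2[seq_len(used)])
  if (v1 == 0 || v2 == 0)
    stop("zero-variance channel", call. = FALSE)
  sp <- welch_csd_batch(ch1, ch2, fs,
                        win_starts = (seq_len(nwin) - 1L) * fs + 1L,
                        win_len = fs, seg_len = dsp$seg_len,
                        overlap = dsp$overlap, taper = dsp$taper,
                        detrend = dsp$detrend)
  eps <- 1e-9
  in_band <- sp$freqs >= dsp$band[1] - eps & sp$freqs <= dsp$band[2] + eps
  if (!any(in_band))
    stop("no frequency bins inside the analysis band", call. = FALSE)
  den <- sp$pxx * sp$pyy
  num <- Re(sp$pxy)^2 + Im(sp$pxy)^2
  msc <- ifelse(den > 0, num / den, 0)
  # the estimator lies in [0, 1] mathematically; clip rounding epsilon so
  # downstream [0, 1] contracts (trigger comparison) hold exactly
  pmin(1, pmax(0, colMeans(msc[in_band, , drop = FALSE])))
}
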