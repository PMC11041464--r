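#' Per-second coherence series of a baseline recording
#'
#' Partitions an already-filtered two-channel recording into consecutive,
#' non-overlapping 1-second fragments and returns one band-mean coherence
#' value per fragment, in temporal order. A 180-s baseline therefore
#' yields exactly 180 values.
#'
#' @param ch1,ch2 Filtered amplitude vectors of equal length; the length
#'   must be an integer multiple of the sampling rate.
#' @param dsp A [dsp_params()].
#' @return Numeric vector of Coh(beta) values, one per second.
#' @export
fragment_coh_series <- function(ch1, ch2, dsp = dsp_params()) {
  if (length(ch1) != length(ch2))
    stop("channels must have identical length", call. = FALSE)
  if (length(ch1) %% dsp$fs != 0)
    stop("recording length must be an integer multiple of the sampling ",
         "rate (whole seconds)", call. = FALSE)
  coh_series(ch1, ch2, dsp)
}

#' Trigger threshold from a baseline coherence series
#'
#' Returns the \code{target_count}-th largest value of the series, so
#' that (for distinct values) exactly \code{target_count} fragments
#' satisfy \code{value >= threshold}. This is the order-statistic reading
#' of "a threshold under which the trigger fires \code{target_count}
#' times during the baseline". With ties, at least \code{target_count}
#' fragments qualify and the returned threshold is the smallest such
#' order statistic (ties resolve toward more crossings, matching the
#' \code{>=} trigger condition).
#'
#' @param values Numeric coherence series.
#' @param target_count Desired number of baseline crossings (default 6,
#'   i.e. one trigger per 30 s over a 180-s baseline).
#' @return Scalar threshold.
#' @export
#' @examples
#' select_threshold(c(.2, .9, .5, .7, .8, .4, .6, .3), target_count = 3)
select_threshold <- function(values, target_count = 6L) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  if (target_count < 1L)
    stop("target_count must be at least 1", call. = FALSE)
  if (target_count > length(values))
    stop("target_count exceeds the number of baseline fragments",
         call. = FALSE)
  sort(values, decreasing = TRUE)[target_count]
}

#' Calibrate the trigger threshold from a raw baseline recording
#'
#' Runs the full pre-session procedure: bandpass-filter the raw
#' two-channel baseline, fragment it into 1-second windows, compute the
#' per-fragment band coherence, and select the initial trigger threshold
#' as the \code{target_count}-th largest fragment value.
#'
#' @param ch1,ch2 Raw amplitude vectors (whole seconds).
#' @param dsp A [dsp_params()].
#' @param target_count Desired baseline crossing count (default 6).
#' @return A list of class \code{"calibration_result"}: fragment_values,
#'   initial_threshold, target_count, baseline_duration (s), n_crossings
#'   (fragments at or above the threshold).
#' @export
calibrate <- function(ch1, ch2, dsp = dsp_params(), target_count = 6L) {
  f1 <- bandpass_filter(ch1, dsp$fs, dsp$filter_band[1], dsp$filter_band[2],
                        dsp$filter_order, dsp$zero_phase)
  f2 <- bandpass_filter(ch2, dsp$fs, dsp$filter_band[1], dsp$filter_band[2],
                        dsp$filter_order, dsp$zero_phase)
  values <- fragment_coh_series(f1, f2, dsp)
  thr <- select_threshold(values, target_count)
  structure(list(fragment_values = values,
                 initial_threshold = thr,
                 target_count = as.integer(target_count),
                 baseline_duration = length(values),
                 n_crossings = sum(values >= thr)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> %d s baseline, threshold %.4f (%d of %d fragments at or above)\n",
    x$baseline_duration, x$initial_threshold, x$n_crossings,
    length(x$fragment_values)))
  invisible(x)
}

#' Predicted session time from a calibration
#'
#' By construction of the threshold, triggers occur on average once every
#' \code{baseline_duration / target_count} seconds (30 s at the
#' defaults), so a session of \code{n_stimuli} stimuli is predicted to
#' take \code{n_stimuli} such intervals plus a small fixed per-stimulus
#' overhead (default one 1-s analysis tick).
#'
#' @param cal A [calibrate()] result, or a list with
#'   \code{baseline_duration} and \code{target_count}.
#' @param n_stimuli Number of stimuli planned.
#' @param overhead Per-stimulus overhead in seconds.
#' @return Predicted session duration in seconds.
#' @export
predict_session_time <- function(cal, n_stimuli = 10L, overhead = 1) {
  stopifnot(n_stimuli >= 0)
  if (cal$target_count < 1L)
    stop("target_count must be at least 1", call. = FALSE)
  n_stimuli * (cal$baseline_duration / cal$target_count) +
    n_stimuli * overhead
}
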